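#' @title Lifetime reproductive success and co-residence model
#' @description
#' Lifetime reproductive success (LRS) is the number of an individual's
#' offspring that survived their first year. Parent-offspring co-residence
#' is the number of days, within the offspring's first `cap_days` (default
#' 1461, four years), on which parent and offspring were both alive and
#' members of the same group.
#'
#' The model is a Poisson log-link GLMM: `lrs ~ sex + z(father_cores) +
#' z(log(mother_cores))` with random intercepts for mother, sire, cohort
#' and birth group, and random slopes of father co-residence within cohort
#' and within birth group (no slope-intercept correlations). Diagnostics:
#' likelihood-ratio test against the random-effects-only null, Pearson
#' dispersion, variance inflation factors from the fixed-effects-only
#' linear model, and leave-one-level-out stability of the fixed
#' estimates.
#' @name lrs_pipeline
NULL

#' Lifetime reproductive success of one subject
#'
#' @param subject_id subject.
#' @param offspring individual table rows whose `mother_id` or `sire_id`
#'   is the subject.
#' @param survival_days first-year survival threshold (default 365).
#' @return integer count of offspring that reached `survival_days` (a
#'   missing death day counts as survival — censored alive).
#' @export
compute_lrs <- function(subject_id, offspring, survival_days = 365) {
  off <- offspring[
    (!is.na(offspring$mother_id) & offspring$mother_id == subject_id) |
      (!is.na(offspring$sire_id) & offspring$sire_id == subject_id), ,
    drop = FALSE]
  if (!nrow(off)) return(0L)
  surv <- is.na(off$death_day) |
    (off$death_day - off$birth_day) >= survival_days
  sum(surv)
}

#' Parent-offspring co-residence days
#'
#' Days in `[birth, birth + cap_days)` on which offspring and parent were
#' both alive and members of the same group, computed by half-open
#' interval intersection over the membership tables.
#'
#' @param offspring,parent single rows of the individual table.
#' @param memberships membership table.
#' @param cap_days co-residence window length (default 1461).
#' @return integer day count in `[0, cap_days]`.
#' @export
co_residence_days <- function(offspring, parent, memberships,
                              cap_days = 1461) {
  b <- offspring$birth_day[1]
  win <- c(b, b + cap_days)
  clip <- function(ind, lo, hi) {
    # alive interval clipped to [lo, hi)
    s <- max(lo, ind$birth_day[1])
    e <- min(hi, if (is.na(ind$death_day[1])) hi else ind$death_day[1])
    c(s, e)
  }
  ao <- clip(offspring, win[1], win[2])
  ap <- clip(parent, win[1], win[2])
  lo <- max(ao[1], ap[1]); hi <- min(ao[2], ap[2])
  if (lo >= hi) return(0L)
  mo <- memberships[memberships$id == offspring$id[1], , drop = FALSE]
  mp <- memberships[memberships$id == parent$id[1], , drop = FALSE]
  if (!nrow(mo) || !nrow(mp)) {
    warning("no membership data for '",
            if (!nrow(mo)) offspring$id[1] else parent$id[1], "'")
    return(0L)
  }
  tot <- 0L
  for (g in intersect(unique(mo$group), unique(mp$group))) {
    og <- mo[mo$group == g, , drop = FALSE]
    pg <- mp[mp$group == g, , drop = FALSE]
    for (i in seq_len(nrow(og))) {
      s1 <- max(og$start_day[i], lo); e1 <- min(og$end_day[i], hi)
      if (s1 >= e1) next
      tot <- tot +
        .ck_interval_intersection(s1, e1, pmax(pg$start_day, lo),
                                  pmin(pg$end_day, hi))
    }
  }
  as.integer(tot)
}

#' Build the LRS record table from demography
#'
#' @param subjects individual table rows of the study subjects (need
#'   `mother_id` and `sire_id`).
#' @param individuals full individual table (offspring lookup and parent
#'   rows).
#' @param memberships membership table.
#' @param survival_days,cap_days thresholds.
#' @return validated `lrs` table.
#' @export
build_lrs_table <- function(subjects, individuals, memberships,
                            survival_days = 365, cap_days = 1461) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, , drop = FALSE]
    mother <- individuals[individuals$id == s$mother_id[1], , drop = FALSE]
    father <- individuals[individuals$id == s$sire_id[1], , drop = FALSE]
    data.frame(
      id = s$id, sex = s$sex,
      lrs = compute_lrs(s$id, individuals, survival_days),
      father_cores_days = if (nrow(father)) {
        co_residence_days(s, father, memberships, cap_days)
      } else 0L,
      mother_cores_days = if (nrow(mother)) {
        co_residence_days(s, mother, memberships, cap_days)
      } else 0L,
      mother_id = s$mother_id, sire_id = s$sire_id,
      cohort = s$cohort, birth_group = s$natal_group,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "natal_group"] <- "birth_group"
  validate_table(out, "lrs")
}

#' Transform the co-residence covariates
#'
#' Mother co-residence is log-transformed then z-transformed; father
#' co-residence is z-transformed. z uses the sample mean and SD over the
#' included records.
#'
#' @param records `lrs` table.
#' @return `records` with columns `father_z` and `mother_logz` appended.
#' @export
transform_covariates <- function(records) {
  if (any(records$mother_cores_days <= 0)) {
    stop("zero mother co-residence for id(s): ",
         paste(records$id[records$mother_cores_days <= 0], collapse = ", "),
         call. = FALSE)
  }
  z <- function(x) (x - mean(x)) / stats::sd(x)
  records$father_z <- z(records$father_cores_days)
  records$mother_logz <- z(log(records$mother_cores_days))
  records
}

.ck_glmm_formula <- function(random_slopes = TRUE, drop = character(0)) {
  re <- c(mother_id = "(1 | mother_id)", sire_id = "(1 | sire_id)",
          cohort = "(1 | cohort)", birth_group = "(1 | birth_group)")
  sl <- c(cohort = "(0 + father_z | cohort)",
          birth_group = "(0 + father_z | birth_group)")
  re <- re[setdiff(names(re), drop)]
  sl <- if (random_slopes) sl[setdiff(names(sl), drop)] else character(0)
  list(full = stats::as.formula(paste(
         c("lrs ~ sex + father_z + mother_logz", re, sl), collapse = " + ")),
       null = stats::as.formula(paste(
         c("lrs ~ 1", re, sl), collapse = " + ")))
}

#' Fit the Poisson mixed model for LRS
#'
#' Fixed effects: sex, z-transformed father co-residence, log-then-z
#' mother co-residence. Random intercepts: mother, sire, cohort, birth
#' group. Random slopes of father co-residence within cohort and birth
#' group, without slope-intercept correlation. Random factors with fewer
#' than 2 levels are dropped with a warning. Fitted by Laplace
#' approximation via [lme4::glmer()].
#'
#' @param records output of [transform_covariates()].
#' @param random_slopes include the two random slopes (default TRUE).
#' @return list of class `lrs_glmm`: `fit`, `null_fit`, `fixed`
#'   (estimate/SE/z/p table), `loglik`, `records`, `dropped`.
#' @export
fit_lrs_glmm <- function(records, random_slopes = TRUE) {
  for (f in c("mother_id", "sire_id", "cohort", "birth_group", "sex")) {
    records[[f]] <- factor(records[[f]])
  }
  drop <- c("mother_id", "sire_id", "cohort", "birth_group")[
    vapply(records[c("mother_id", "sire_id", "cohort", "birth_group")],
           nlevels, integer(1)) < 2]
  if (length(drop)) {
    warning("random factor(s) with < 2 levels dropped: ",
            paste(drop, collapse = ", "))
  }
  fml <- .ck_glmm_formula(random_slopes, drop)
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = TRUE)
  fit <- suppressMessages(
    lme4::glmer(fml$full, data = records, family = stats::poisson(),
                control = ctrl))
  null_fit <- suppressMessages(
    lme4::glmer(fml$null, data = records, family = stats::poisson(),
                control = ctrl))
  cf <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      z = cf[, 3], p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(fit = fit, null_fit = null_fit, fixed = fixed,
                 loglik = as.numeric(stats::logLik(fit)),
                 records = records, dropped = drop,
                 random_slopes = random_slopes),
            class = "lrs_glmm")
}

#' @export
print.lrs_glmm <- function(x, ...) {
  cat("Poisson GLMM for lifetime reproductive success\n")
  print(x$fixed, digits = 3)
  lrt <- lrt_full_vs_null(x)
  cat(sprintf("Full vs null: chisq = %.3f, df = %d, p = %.3f\n",
              lrt$stat, lrt$df, lrt$p))
  invisible(x)
}

#' Likelihood-ratio test of the full model against the null
#'
#' Null = the same random structure with all fixed effects removed. The
#' chi-square reference is standard but approximate in the presence of
#' random effects (boundary caveat).
#'
#' @param model an `lrs_glmm` object.
#' @return list with `stat`, `df`, `p`.
#' @export
lrt_full_vs_null <- function(model) {
  ll_f <- as.numeric(stats::logLik(model$fit))
  ll_n <- as.numeric(stats::logLik(model$null_fit))
  stat <- 2 * (ll_f - ll_n)
  if (stat < -1e-6) warning("negative LRT statistic: convergence suspect")
  stat <- max(stat, 0)
  df <- length(lme4::fixef(model$fit)) - length(lme4::fixef(model$null_fit))
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Pearson dispersion parameter
#'
#' `sum(((y - mu) / sqrt(mu))^2) / (n - p)` with `p` the number of fixed
#' effects; values near 1 indicate equidispersion, well below 1 (as in
#' sparse LRS data) underdispersion.
#'
#' @param model an `lrs_glmm` object, or any fit exposing `fitted()`.
#' @param y optional response vector (defaults to the model's).
#' @return dispersion estimate.
#' @export
dispersion_parameter <- function(model, y = NULL) {
  fit <- if (inherits(model, "lrs_glmm")) model$fit else model
  mu <- stats::fitted(fit)
  if (any(mu <= 0)) stop("non-positive fitted mean", call. = FALSE)
  if (is.null(y)) {
    y <- if (inherits(model, "lrs_glmm")) model$records$lrs
         else stats::model.response(stats::model.frame(fit))
  }
  pearson <- (y - mu) / sqrt(mu)
  p_fixed <- if (inherits(model, "lrs_glmm")) {
    length(lme4::fixef(fit))
  } else length(stats::coef(fit))
  sum(pearson^2) / (length(y) - p_fixed)
}

#' Variance inflation factors from the fixed-effects design
#'
#' For each fixed-effect column, `VIF = 1 / (1 - R^2)` where `R^2` comes
#' from an ordinary linear regression of that column on the other columns
#' (random effects excluded). Perfect collinearity reports `Inf`.
#'
#' @param design data.frame or matrix of fixed-effect columns (no
#'   intercept).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.data.frame(design)
  X[] <- lapply(X, function(col) if (is.factor(col) || is.character(col)) {
    as.numeric(factor(col))
  } else as.numeric(col))
  if (ncol(X) < 2) stop("need >= 2 fixed effects", call. = FALSE)
  out <- numeric(ncol(X))
  names(out) <- names(X)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Leave-one-level-out stability of the fixed estimates
#'
#' Refits the model once per level of each random factor with that level's
#' records removed, and reports the range of each fixed-effect estimate
#' across refits. Failed refits are flagged, not fatal.
#'
#' @param model an `lrs_glmm` object.
#' @param factors random factors whose levels are left out (default all
#'   four; restrict for large level counts).
#' @return list with `estimates` (matrix refits x terms), `range`
#'   (min/max per term), `failed` (character vector of skipped levels).
#' @export
stability_check <- function(model,
                            factors = c("mother_id", "sire_id", "cohort",
                                        "birth_group")) {
  recs <- model$records
  factors <- setdiff(intersect(factors,
                               c("mother_id", "sire_id", "cohort",
                                 "birth_group")),
                     model$dropped)
  terms <- model$fixed$term
  est <- list(); failed <- character(0)
  for (f in factors) {
    for (lev in levels(recs[[f]])) {
      sub <- recs[recs[[f]] != lev, , drop = FALSE]
      sub[] <- lapply(sub, function(col) if (is.factor(col)) droplevels(col)
                      else col)
      tag <- paste0(f, ":", lev)
      res <- tryCatch(
        suppressWarnings(fit_lrs_glmm(sub, model$random_slopes)),
        error = function(e) NULL)
      if (is.null(res) || !setequal(res$fixed$term, terms)) {
        failed <- c(failed, tag)
      } else {
        est[[tag]] <- res$fixed$estimate[match(terms, res$fixed$term)]
      }
    }
  }
  mat <- do.call(rbind, est)
  colnames(mat) <- terms
  rng <- apply(mat, 2, range)
  rownames(rng) <- c("min", "max")
  list(estimates = mat, range = rng, failed = failed)
}
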