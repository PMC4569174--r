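#' @title Correlation screen and Fisher's omnibus test
#' @description
#' Each fitness proxy is screened against each of the five predictors by a
#' Spearman rank correlation, separately per focal sex. Because the five
#' p-values per (proxy, sex) set are not independent, the set is combined
#' by Fisher's omnibus statistic `X = -2 * sum(ln p)` (chi-square with
#' `2k` df under independence) and calibrated by permutation: the response
#' is shuffled across focals while the predictor matrix stays intact,
#' preserving inter-predictor dependence, and the omnibus statistic is
#' recomputed for each shuffle.
#' @name assoc_stats
NULL

# mid-ranks without R's rank() — used by internals; rank() would be fine
# but keeping one code path makes the permutation pass identical
.ck_midrank <- function(x) rank(x, ties.method = "average")

# two-sided p for Spearman rho via the t approximation, clamped away from 0
.ck_spearman_p <- function(rho, n) {
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  pmin(pmax(p, 1e-300), 1)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-rank (ties averaged) Pearson correlation of ranks, after pairwise
#' deletion of missing values. The two-sided p-value uses
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, `n`. A constant vector yields `rho = NA`
#'   with a warning.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  rx <- .ck_midrank(x); ry <- .ck_midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = .ck_spearman_p(rho, n), n = n)
}

#' Fisher's omnibus statistic
#'
#' @param p_values vector of k p-values in (0, 1].
#' @return list with `X = -2 * sum(ln p)` and `df = 2k`.
#' @export
fot_statistic <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values", call. = FALSE)
  if (any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  list(X = -2 * sum(log(p_values)), df = 2L * length(p_values))
}

#' Analytic p-value for a Fisher omnibus statistic
#' @param X omnibus statistic.
#' @param df degrees of freedom (`2k`).
#' @return chi-square upper-tail probability.
#' @export
fot_analytic_p <- function(X, df) {
  stats::pchisq(X, df = df, lower.tail = FALSE)
}

# rho of one (possibly permuted) response rank column against a
# standardized rank matrix: internals of the permutation pass
.ck_rho_block <- function(yr_std, P_std) {
  drop(crossprod(P_std, yr_std))
}

#' Permutation-calibrated Fisher omnibus test
#'
#' Computes the observed omnibus statistic from the Spearman p-values of
#' `response` against each predictor column, then shuffles the response
#' across rows `n_perm` times (predictor matrix intact), recomputing the
#' statistic each time. The permutation p-value uses the add-one rule
#' `(1 + #\{X_perm >= X_obs\}) / (n_perm + 1)`.
#'
#' @param response numeric response vector.
#' @param predictors numeric matrix or data.frame, one column per
#'   predictor, rows aligned with `response`.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the shuffles.
#' @return list with `X`, `df`, `p_analytic`, `p_permutation`, `n_perm`,
#'   `rho` and `p` (per-predictor observed values), `n`.
#' @export
fot_permutation <- function(response, predictors, n_perm = 1000,
                            seed = NULL) {
  P <- as.matrix(predictors)
  stopifnot(length(response) == nrow(P))
  keep <- stats::complete.cases(cbind(response, P))
  y <- response[keep]; P <- P[keep, , drop = FALSE]
  n <- length(y); k <- ncol(P)
  if (n < 3) stop("too few complete rows for any correlation", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  PR <- apply(P, 2, .ck_midrank)
  sds <- apply(PR, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column", call. = FALSE)
  P_std <- scale(PR) / sqrt(n - 1)           # unit-norm centered columns
  yr <- .ck_midrank(y)
  if (stats::sd(yr) == 0) stop("constant response", call. = FALSE)
  std <- function(v) (v - mean(v)) / (stats::sd(v) * sqrt(n - 1))
  rho0 <- .ck_rho_block(std(yr), P_std)
  p0 <- .ck_spearman_p(rho0, n)
  fo <- fot_statistic(p0)
  x_perm <- numeric(n_perm)
  if (n_perm > 0) {
    # shuffling y permutes its ranks, so no re-ranking is needed
    Y <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) Y[, j] <- std(sample(yr))
    rho_mat <- crossprod(P_std, Y)           # k x n_perm
    p_mat <- .ck_spearman_p(rho_mat, n)
    x_perm <- -2 * colSums(log(p_mat))
  }
  p_perm <- (1 + sum(x_perm >= fo$X)) / (n_perm + 1)
  list(X = fo$X, df = fo$df, p_analytic = fot_analytic_p(fo$X, fo$df),
       p_permutation = p_perm, n_perm = n_perm,
       rho = rho0, p = p0, n = n)
}

#' Significance label used in reports
#' @param p p-value.
#' @return `"significant"` (p <= 0.05), `"trend"` (0.05 < p <= 0.1) or
#'   `""`.
#' @export
sig_label <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.05, "significant", ifelse(p <= 0.1, "trend", "")))
}

#' Correlation screen over predictors, responses and sexes
#'
#' For each response column and sex, reports the five Spearman
#' correlations plus one permutation-calibrated Fisher omnibus row,
#' mirroring the usual layout of such screens (response, predictor, sex,
#' n, rho, p, label).
#'
#' @param predictor_table output of [build_predictor_table()].
#' @param responses data.frame with `focal_id` plus one numeric column per
#'   response (e.g. `gain_p1`, `gain_p2`, `qi`, `tv`).
#' @param sex named character vector: sex (`"female"`/`"male"`) per
#'   focal id.
#' @param n_perm,seed permutation settings.
#' @param predictors which predictor columns to screen.
#' @return long data.frame; omnibus rows carry `predictor == "FOT"` with
#'   the statistic in `rho`-adjacent columns `fot_X`, `fot_df`,
#'   `fot_p_analytic`, and `p` = permutation p.
#' @export
screen_correlations <- function(predictor_table, responses, sex,
                                n_perm = 1000, seed = 1,
                                predictors = c("mean_male_affil",
                                               "mean_paternal_affil",
                                               "focal_rank",
                                               "weighted_affil",
                                               "evenness")) {
  resp_cols <- setdiff(names(responses), "focal_id")
  out <- list()
  set.seed(seed)
  for (rc in resp_cols) {
    for (sx in c("male", "female")) {
      ids <- predictor_table$focal_id[
        sex[predictor_table$focal_id] == sx]
      ids <- intersect(ids, responses$focal_id)
      y <- responses[[rc]][match(ids, responses$focal_id)]
      keep <- !is.na(y)
      ids <- ids[keep]; y <- y[keep]
      if (length(ids) < 3) next
      P <- predictor_table[match(ids, predictor_table$focal_id), predictors,
                           drop = FALSE]
      pv <- numeric(0)
      for (pc in predictors) {
        x <- P[[pc]]
        ok <- !is.na(x)
        if (sum(ok) < 3 || stats::sd(x[ok]) == 0 ||
            stats::sd(y[ok]) == 0) {
          res <- list(rho = NA_real_, p = NA_real_, n = sum(ok))
        } else {
          res <- spearman(x, y)
        }
        pv <- c(pv, res$p)
        out[[length(out) + 1]] <- data.frame(
          response = rc, predictor = pc, sex = sx, n = res$n,
          rho = res$rho, p = res$p, label = sig_label(res$p),
          fot_X = NA_real_, fot_df = NA_integer_,
          fot_p_analytic = NA_real_, stringsAsFactors = FALSE)
      }
      cc <- stats::complete.cases(cbind(y, P))
      if (sum(cc) >= 3) {
        fp <- fot_permutation(y[cc], P[cc, , drop = FALSE], n_perm = n_perm)
        out[[length(out) + 1]] <- data.frame(
          response = rc, predictor = "FOT", sex = sx, n = sum(cc),
          rho = NA_real_, p = fp$p_permutation,
          label = sig_label(fp$p_permutation), fot_X = fp$X,
          fot_df = fp$df, fot_p_analytic = fp$p_analytic,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
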