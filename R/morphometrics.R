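#' @title Growth normalization and morphometric indices
#' @description
#' Focal subjects are weighed at trapping occasions whose ages vary by up
#' to three months, so body masses are normalized to standard ages before
#' computing mass gain. Per analysis period, three growth candidates are
#' least-squares fitted with age in days as predictor — linear
#' (`bm ~ age`), squared (`bm ~ age + age^2`) and logarithmic
#' (`bm ~ ln(age)`) — sexes pooled, and the candidate with the lowest AIC
#' is kept. Each individual's residual is treated as its fixed deviation
#' from the normal growth curve: the normalized mass at a standard age is
#' the fitted value at that age plus the individual's residual.
#'
#' Body fat is proxied by the Quetelet index `QI = BM / CRL^2 * 1000`
#' (kg, cm). Testis volume uses the printed ellipsoid form
#' `(4/3) * pi * L * W^2` (mm) divided by the body mass on the measuring
#' day; length and width are each the mean of both testes and of
#' triplicate measurements.
#' @name morphometrics
NULL

# least-squares AIC with the Gaussian variance profiled out; the additive
# constant cancels between candidates
.ck_ls_aic <- function(rss, n, n_coef) {
  n * log(rss / n) + 2 * (n_coef + 1)
}

#' Fit the three growth candidates and select by AIC
#'
#' @param measurements data.frame with columns `id`, `age_days` (> 0) and
#'   `bm_kg`; at least 4 rows.
#' @return a `growth_fit` object: `candidate` (one of `"linear"`,
#'   `"squared"`, `"logarithmic"`), `coefficients`, `aic` (named vector
#'   over all candidates), `data` (the measurements with a `resid`
#'   column), and `fitted_at(age_days)`.
#' @export
fit_growth_candidates <- function(measurements) {
  m <- measurements
  stopifnot(all(c("id", "age_days", "bm_kg") %in% names(m)))
  if (nrow(m) < 4) stop("need at least 4 measurement points", call. = FALSE)
  if (any(m$age_days <= 0)) {
    stop("ages must be > 0 (logarithmic candidate)", call. = FALSE)
  }
  n <- nrow(m)
  fits <- list(
    linear = stats::lm(bm_kg ~ age_days, data = m),
    squared = stats::lm(bm_kg ~ age_days + I(age_days^2), data = m),
    logarithmic = stats::lm(bm_kg ~ log(age_days), data = m)
  )
  aic <- vapply(fits, function(f) {
    .ck_ls_aic(sum(stats::residuals(f)^2), n, length(stats::coef(f)))
  }, numeric(1))
  best <- names(which.min(aic))
  fit <- fits[[best]]
  m$resid <- unname(stats::residuals(fit))
  fitted_at <- switch(
    best,
    linear = {
      b <- stats::coef(fit); function(a) b[[1]] + b[[2]] * a
    },
    squared = {
      b <- stats::coef(fit); function(a) b[[1]] + b[[2]] * a + b[[3]] * a^2
    },
    logarithmic = {
      b <- stats::coef(fit); function(a) b[[1]] + b[[2]] * log(a)
    }
  )
  structure(list(candidate = best, coefficients = stats::coef(fit),
                 aic = aic, model = fit, data = m, fitted_at = fitted_at),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth fit: ", x$candidate, " (AIC ",
      paste(sprintf("%s=%.2f", names(x$aic), x$aic), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Normalize body masses to a standard age
#'
#' For each individual with a measurement inside `occasion_window` (age
#' range of the trapping occasion), the normalized mass is
#' `fitted_at(standard_age_day) + residual` of that measurement. An
#' individual measured exactly at the standard age gets back its observed
#' mass.
#'
#' @param fit a [fit_growth_candidates()] result.
#' @param standard_age_day the standard age (days) to normalize to.
#' @param occasion_window age range `c(lo, hi)` selecting the occasion's
#'   measurements; default covers all fitted points.
#' @return data.frame (`id`, `standard_age_day`, `normalized_bm_kg`).
#' @export
normalize_mass <- function(fit, standard_age_day,
                           occasion_window = c(-Inf, Inf)) {
  d <- fit$data
  d <- d[d$age_days >= occasion_window[1] &
           d$age_days <= occasion_window[2], , drop = FALSE]
  if (anyDuplicated(d$id)) {
    stop("more than one measurement per id in the occasion window",
         call. = FALSE)
  }
  base <- fit$fitted_at(standard_age_day)
  data.frame(id = d$id,
             standard_age_day = rep(as.integer(standard_age_day), nrow(d)),
             normalized_bm_kg = base + d$resid, stringsAsFactors = FALSE)
}

#' Mass gain between two normalized masses
#'
#' @param norm_start,norm_end [normalize_mass()] outputs for the period's
#'   start and end standard ages.
#' @return data.frame (`id`, `gain_kg`); ids missing either endpoint are
#'   dropped, negative gains are kept but flagged with a warning.
#' @export
mass_gain <- function(norm_start, norm_end) {
  ids <- intersect(norm_start$id, norm_end$id)
  g <- norm_end$normalized_bm_kg[match(ids, norm_end$id)] -
    norm_start$normalized_bm_kg[match(ids, norm_start$id)]
  if (any(g < 0)) {
    warning(sum(g < 0), " individual(s) with negative mass gain")
  }
  data.frame(id = ids, gain_kg = g, stringsAsFactors = FALSE)
}

#' Quetelet index (ponderal index, proxy for body fat)
#'
#' `QI = BM / CRL^2 * 1000` with body mass in kg and crown-rump length in
#' cm.
#' @param bm_kg body mass (kg), > 0.
#' @param crl_cm crown-rump length (cm), > 0.
#' @return QI (vectorized).
#' @export
quetelet_index <- function(bm_kg, crl_cm) {
  if (any(!is.na(bm_kg) & bm_kg <= 0) || any(!is.na(crl_cm) & crl_cm <= 0)) {
    stop("bm_kg and crl_cm must be > 0", call. = FALSE)
  }
  bm_kg / (crl_cm * crl_cm) * 1000
}

#' Body-mass-corrected testis volume
#'
#' `(4/3) * pi * L * W^2 / BM`, with `L` and `W` the mean length and width
#' of both testes (mm; triplicate measurements averaged upstream) and `BM`
#' the body mass (kg) on the measuring day. The ellipsoid form is applied
#' exactly as conventionally printed for this index.
#' @param testis_len_mm mean testis length (mm), > 0.
#' @param testis_wid_mm mean testis width (mm), > 0.
#' @param bm_kg body mass (kg), > 0.
#' @return volume index (mm^3 per kg), vectorized.
#' @export
testis_volume <- function(testis_len_mm, testis_wid_mm, bm_kg) {
  ok <- function(x) !any(!is.na(x) & x <= 0)
  if (!ok(testis_len_mm) || !ok(testis_wid_mm) || !ok(bm_kg)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  (4 / 3) * pi * testis_len_mm * testis_wid_mm^2 / bm_kg
}
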