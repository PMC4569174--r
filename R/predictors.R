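#' @title Five predictors of male-immature affiliation
#' @description
#' For each focal subject and age window the screen uses five predictors:
#' mean male-focal affiliation (events per protocol day), mean paternal
#' affiliation (events with the sire per protocol day), mean focal rank
#' (daily standardized rank averaged over the window), rank-weighted
#' male-focal affiliation (each event weighted by the partner's
#' standardized male rank that day), and the evenness of the affiliation
#' distribution across adult-male partners (Shannon entropy divided by its
#' maximum over the available partner pool).
#'
#' "Per day" denominates by protocol days — days the focal was actually
#' observed under the standard protocol — not calendar days.
#' @name predictors
NULL

.ck_protocol_days <- function(protocols, focal, window) {
  d <- protocols$day[protocols$focal_id == focal]
  sort(unique(d[d >= window[1] & d < window[2]]))
}

.ck_focal_events <- function(events, focal, window) {
  events[events$focal_id == focal & events$day >= window[1] &
           events$day < window[2], , drop = FALSE]
}

#' Mean male-focal affiliation rate
#'
#' Count of the focal's affiliative events with any adult male inside the
#' window, divided by the focal's number of protocol days in the window.
#'
#' @param events affiliation-event table.
#' @param protocols protocol table.
#' @param focal focal id.
#' @param window absolute day interval `c(start, end)`, half-open.
#' @return events per protocol day, or `NA` (with a warning) when the
#'   focal has no protocol days in the window.
#' @export
mean_male_affiliation <- function(events, protocols, focal, window) {
  pd <- .ck_protocol_days(protocols, focal, window)
  if (!length(pd)) {
    warning("focal '", focal, "' has no protocol days in window")
    return(NA_real_)
  }
  nrow(.ck_focal_events(events, focal, window)) / length(pd)
}

#' Mean paternal affiliation rate
#'
#' As [mean_male_affiliation()] restricted to events whose partner is the
#' focal's sire. Unknown sire yields `NA`.
#' @inheritParams mean_male_affiliation
#' @param sire_id the focal's assigned sire, or `NA`.
#' @return events with the sire per protocol day, or `NA`.
#' @export
mean_paternal_affiliation <- function(events, protocols, focal, sire_id,
                                      window) {
  if (is.null(sire_id) || is.na(sire_id)) return(NA_real_)
  pd <- .ck_protocol_days(protocols, focal, window)
  if (!length(pd)) {
    warning("focal '", focal, "' has no protocol days in window")
    return(NA_real_)
  }
  ev <- .ck_focal_events(events, focal, window)
  sum(ev$partner_id == sire_id) / length(pd)
}

#' Mean focal rank over a window
#'
#' Arithmetic mean of the focal's daily standardized ranks (female/immature
#' hierarchy) over the days with rank entries inside the window.
#' @param ranks rank-series table.
#' @inheritParams mean_male_affiliation
#' @return mean rank in `[0, 1]`, or `NA` when no entries fall in the
#'   window.
#' @export
mean_focal_rank <- function(ranks, focal, window) {
  r <- ranks$rank[ranks$id == focal & ranks$day >= window[1] &
                    ranks$day < window[2]]
  if (!length(r)) return(NA_real_)
  mean(r)
}

#' Rank-weighted male-focal affiliation rate
#'
#' Each affiliative event contributes the partner's standardized male rank
#' on the event day; the sum is divided by the focal's protocol days in
#' the window. High values mean frequent affiliation with high-ranking
#' males; low values mean little affiliation or affiliation with
#' low-ranking males.
#'
#' @param ranks male-hierarchy rank-series table.
#' @inheritParams mean_male_affiliation
#' @return rank-weighted events per protocol day, or `NA` with no protocol
#'   days.
#' @export
rank_weighted_affiliation <- function(events, protocols, ranks, focal,
                                      window) {
  pd <- .ck_protocol_days(protocols, focal, window)
  if (!length(pd)) {
    warning("focal '", focal, "' has no protocol days in window")
    return(NA_real_)
  }
  ev <- .ck_focal_events(events, focal, window)
  if (!nrow(ev)) return(0)
  mr <- ranks[ranks$hierarchy == "male", , drop = FALSE]
  key_ev <- paste(ev$partner_id, ev$day)
  key_rk <- paste(mr$id, mr$day)
  m <- match(key_ev, key_rk)
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stop("partner '", ev$partner_id[i], "' has no male rank on day ",
         ev$day[i], call. = FALSE)
  }
  sum(mr$rank[m]) / length(pd)
}

#' Evenness of the affiliation distribution across male partners
#'
#' Shannon entropy of the focal's per-partner event proportions divided by
#' its maximum `ln(S)`, where `S` is the number of adult males available
#' to the focal in the window (the partner pool), not just the partners it
#' interacted with. 1 means affiliation spread uniformly over every
#' available male; 0 means all events with a single partner. Undefined
#' (`NA`) with zero events or a single-male pool.
#'
#' @param events affiliation-event table.
#' @param focal focal id.
#' @param available_partners ids of adult males present in the window.
#' @param window absolute day interval `c(start, end)`, half-open.
#' @return evenness in `[0, 1]`, or `NA`.
#' @export
affiliation_evenness <- function(events, focal, available_partners,
                                 window = c(-Inf, Inf)) {
  if (!length(available_partners)) {
    stop("available_partners is empty", call. = FALSE)
  }
  ev <- .ck_focal_events(events, focal, window)
  outside <- setdiff(unique(ev$partner_id), available_partners)
  if (length(outside)) {
    stop("event partner(s) outside available pool: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  s <- length(unique(available_partners))
  if (s == 1 || !nrow(ev)) return(NA_real_)
  cnt <- table(ev$partner_id)
  p <- as.numeric(cnt) / sum(cnt)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Build the per-focal predictor table
#'
#' One row per focal with all five predictors for the given age window
#' (relative to each focal's birth), plus bookkeeping counts.
#'
#' @param events affiliation-event table.
#' @param protocols protocol table.
#' @param ranks rank-series table holding both hierarchies.
#' @param individuals individual table (source of birth days and sires).
#' @param memberships membership table (partner-pool derivation).
#' @param focal_ids focal subjects to include.
#' @param window age window in days since birth, half-open (default
#'   infancy, `c(0, 365)`).
#' @param male_ids ids regarded as adult males; defaults to all ids seen in
#'   the male rank series.
#' @param group group whose membership defines the partner pool; defaults
#'   to each focal's natal group.
#' @return data.frame with columns `focal_id`, `window_start`,
#'   `window_end`, `mean_male_affil`, `mean_paternal_affil`, `focal_rank`,
#'   `weighted_affil`, `evenness`, `n_protocol_days`, `n_partners`.
#' @export
build_predictor_table <- function(events, protocols, ranks, individuals,
                                  memberships, focal_ids,
                                  window = c(0L, 365L), male_ids = NULL,
                                  group = NULL) {
  if (is.null(male_ids)) {
    male_ids <- unique(ranks$id[ranks$hierarchy == "male"])
  }
  rows <- lapply(focal_ids, function(f) {
    ind <- individuals[individuals$id == f, , drop = FALSE]
    if (!nrow(ind)) stop("unknown focal '", f, "'", call. = FALSE)
    birth <- ind$birth_day[1]
    w <- c(birth + window[1], birth + window[2])
    # follow-up ends at death/removal: protocol records already encode it
    grp <- if (is.null(group)) ind$natal_group[1] else group
    pool <- male_ids[vapply(male_ids, function(m) {
      mm <- memberships[memberships$id == m & memberships$group == grp, ,
                        drop = FALSE]
      nrow(mm) > 0 &&
        .ck_interval_intersection(mm$start_day, mm$end_day, w[1], w[2]) > 0
    }, logical(1))]
    pd <- .ck_protocol_days(protocols, f, w)
    ev <- .ck_focal_events(events, f, w)
    data.frame(
      focal_id = f,
      window_start = window[1], window_end = window[2],
      mean_male_affil = mean_male_affiliation(events, protocols, f, w),
      mean_paternal_affil =
        mean_paternal_affiliation(events, protocols, f, ind$sire_id[1], w),
      focal_rank = mean_focal_rank(
        ranks[ranks$hierarchy == "female_immature", , drop = FALSE], f, w),
      weighted_affil =
        rank_weighted_affiliation(events, protocols, ranks, f, w),
      evenness = if (length(pool)) {
        affiliation_evenness(events, f, pool, w)
      } else NA_real_,
      n_protocol_days = length(pd),
      n_partners = length(unique(ev$partner_id)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
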