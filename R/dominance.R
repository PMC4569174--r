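#' @title Daily dominance hierarchies
#' @description
#' Adult-male ranks come from Elo ratings updated by each dyadic agonistic
#' outcome; female and immature ranks come from a maintained adult-female
#' ordering with matrilineal rank inheritance (offspring directly below
#' their mother, youngest first). Both hierarchies are recomputed daily to
#' absorb births, deaths and migrations and standardized per day to
#' `[0, 1]` (lowest- to highest-ranking).
#' @name dominance
NULL

#' Create an Elo rating state
#'
#' @param start_rating rating assigned to an individual on first
#'   appearance (default 1000).
#' @param k maximum points exchanged per interaction (default 100).
#' @return an `elo_state` object.
#' @export
elo_state <- function(start_rating = 1000, k = 100) {
  stopifnot(is.finite(start_rating), is.finite(k), k > 0)
  structure(list(ratings = numeric(0), start_rating = start_rating, k = k),
            class = "elo_state")
}

#' Apply one agonistic outcome to an Elo state
#'
#' The winner gains `k * (1 - E)` points and the loser loses the same
#' amount, where `E = 1 / (1 + 10^((R_loser - R_winner)/400))` is the
#' winner's expected score before the event. Unknown ids are initialized
#' at the start rating first. The update is zero-sum.
#'
#' @param state an [elo_state()].
#' @param winner_id,loser_id contestant ids; must differ.
#' @return the updated `elo_state`.
#' @export
elo_update <- function(state, winner_id, loser_id) {
  if (identical(winner_id, loser_id)) {
    stop("winner_id equals loser_id ('", winner_id, "')", call. = FALSE)
  }
  r <- state$ratings
  for (id in c(winner_id, loser_id)) {
    if (is.na(match(id, names(r)))) r[id] <- state$start_rating
  }
  e <- 1 / (1 + 10^((r[[loser_id]] - r[[winner_id]]) / 400))
  delta <- state$k * (1 - e)
  r[winner_id] <- r[[winner_id]] + delta
  r[loser_id] <- r[[loser_id]] - delta
  state$ratings <- r
  state
}

#' Standardize a dominance ordering to [0, 1]
#'
#' Position `i` of `n` (highest first) maps to `(n - i) / (n - 1)`, so the
#' top individual scores 1 and the bottom 0. A singleton hierarchy maps to
#' `singleton` (default 1).
#'
#' @param ordering character vector of ids, highest-ranking first, no
#'   duplicates.
#' @param singleton value assigned when `length(ordering) == 1`.
#' @return named numeric vector of standardized ranks.
#' @export
standardize_ranks <- function(ordering, singleton = 1) {
  if (!length(ordering)) stop("empty ordering", call. = FALSE)
  if (anyDuplicated(ordering)) {
    stop("duplicate ids in ordering: ",
         paste(unique(ordering[duplicated(ordering)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(ordering)
  v <- if (n == 1) singleton else (n - seq_len(n)) / (n - 1)
  stats::setNames(v, ordering)
}

#' Daily standardized Elo ranks for adult males
#'
#' Processes agonistic events in day order (within a day, in input order),
#' then, for each roster day, orders the males present that day by their
#' current rating (ties broken by id for determinism) and standardizes to
#' `[0, 1]`. Males present but never observed fighting sit at the start
#' rating.
#'
#' @param events agonistic-event table (`day`, `winner_id`, `loser_id`),
#'   sorted by day.
#' @param roster data.frame (`day`, `id`) giving the adult males present
#'   each day; must cover every event participant on the event's day.
#' @param k,start_rating Elo parameters.
#' @return a `rank_series` data.frame (`id`, `day`, `hierarchy`, `rank`)
#'   with `hierarchy == "male"`.
#' @export
male_daily_ranks <- function(events, roster, k = 100, start_rating = 1000) {
  if (is.unsorted(events$day)) {
    stop("events must be sorted by day", call. = FALSE)
  }
  days <- sort(unique(roster$day))
  # fast path: ratings kept in a named vector, events grouped by day
  ratings <- stats::setNames(rep(start_rating, 0), character(0))
  ev_by_day <- if (nrow(events)) split(seq_len(nrow(events)), events$day)
               else list()
  out <- vector("list", length(days))
  for (di in seq_along(days)) {
    d <- days[di]
    present <- roster$id[roster$day == d]
    idx <- ev_by_day[[as.character(d)]]
    if (!is.null(idx)) {
      for (i in idx) {
        w <- events$winner_id[i]; l <- events$loser_id[i]
        if (!(w %in% present) || !(l %in% present)) {
          stop("event on day ", d, " involves '",
               if (!(w %in% present)) w else l,
               "' who is absent from that day's roster", call. = FALSE)
        }
        if (is.na(ratings[w])) ratings[w] <- start_rating
        if (is.na(ratings[l])) ratings[l] <- start_rating
        e <- 1 / (1 + 10^((ratings[[l]] - ratings[[w]]) / 400))
        delta <- k * (1 - e)
        ratings[w] <- ratings[[w]] + delta
        ratings[l] <- ratings[[l]] - delta
      }
    }
    rp <- ratings[present]
    rp[is.na(rp)] <- start_rating
    names(rp) <- present
    ord <- present[order(-rp, present)]
    sr <- standardize_ranks(ord)
    out[[di]] <- data.frame(id = names(sr), day = d, hierarchy = "male",
                            rank = unname(sr), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Daily standardized ranks for females and immatures
#'
#' The adult-female hierarchy is a maintained input ordering (highest
#' first). Each day, every living immature whose mother is in the ordering
#' is inserted directly below its mother, youngest sibling first (inverse
#' birth order). The daily ordering is then restricted to individuals
#' alive and members of `group` that day and standardized to `[0, 1]`.
#'
#' @param order character vector of adult-female ids, highest-ranking
#'   first.
#' @param individuals individual table (needs `id`, `birth_day`,
#'   `death_day`, `mother_id`).
#' @param memberships membership table.
#' @param days integer vector of days to compute.
#' @param group group label whose members are ranked.
#' @return a `rank_series` data.frame with `hierarchy ==
#'   "female_immature"`.
#' @export
female_immature_daily_ranks <- function(order, individuals, memberships,
                                        days, group) {
  imm <- individuals[!is.na(individuals$mother_id) &
                       !(individuals$id %in% order), , drop = FALSE]
  unknown <- setdiff(imm$mother_id, order)
  if (length(unknown)) {
    bad <- imm$id[imm$mother_id %in% unknown]
    stop("immature(s) with mother not in the female order: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  info <- individuals[match(c(order, imm$id), individuals$id), , drop = FALSE]
  rownames(info) <- info$id
  all_ids <- c(order, imm$id)
  # precompute per-id alive interval and membership spells in `group`
  mem <- memberships[memberships$group == group &
                       memberships$id %in% all_ids, , drop = FALSE]
  mem_by_id <- split(mem[c("start_day", "end_day")], mem$id)
  alive_on <- function(id, d) {
    b <- info[id, "birth_day"]; dd <- info[id, "death_day"]
    !is.na(b) && d >= b && (is.na(dd) || d < dd)
  }
  member_on <- function(id, d) {
    m <- mem_by_id[[id]]
    !is.null(m) && any(d >= m$start_day & d < m$end_day)
  }
  # offspring of each mother sorted youngest first (descending birth day)
  kids <- split(imm$id, imm$mother_id)
  kids <- lapply(kids, function(ids) {
    ids[order(-individuals$birth_day[match(ids, individuals$id)], ids)]
  })
  out <- vector("list", length(days))
  for (di in seq_along(days)) {
    d <- days[di]
    ordering <- character(0)
    for (f in order) {
      if (alive_on(f, d) && member_on(f, d)) ordering <- c(ordering, f)
      for (kid in kids[[f]]) {
        if (alive_on(kid, d) && member_on(kid, d)) {
          ordering <- c(ordering, kid)
        }
      }
    }
    if (!length(ordering)) next
    sr <- standardize_ranks(ordering)
    out[[di]] <- data.frame(id = names(sr), day = d,
                            hierarchy = "female_immature",
                            rank = unname(sr), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id = character(0), day = integer(0),
                      hierarchy = character(0), rank = numeric(0))
  }
  res
}
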