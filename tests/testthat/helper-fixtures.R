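# shared fixtures: a scaled-down simulation config and brute-force oracles

tiny_sim_cfg <- function() {
  list(n_focals = 10L, n_focal_females = 5L,
       n_adult_males = 12L, n_adult_females = 10L,
       span_days = 420L, birth_spread_days = 40L,
       agonistic_per_day = 3,
       protocols_per_week = 2,
       lrs = list(n_subjects = 40L, n_females = 15L, n_cohorts = 4L,
                  n_groups = 3L, n_mothers = 20L, n_sires = 12L))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_sim_cfg(), seed = 42)
    cache
  }
})

# full-size default simulation (55 focals, 1552 days), built once
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(list(), seed = 1)
    cache
  }
})

# brute-force mid-rank Spearman: ranks by counting, Pearson by sums
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# day-by-day co-residence enumeration
oracle_co_residence <- function(offspring, parent, memberships, cap_days) {
  b <- offspring$birth_day[1]
  days <- b:(b + cap_days - 1)
  alive <- function(ind, d) {
    d >= ind$birth_day[1] &
      (is.na(ind$death_day[1]) | d < ind$death_day[1])
  }
  in_grp <- function(id, d) {
    m <- memberships[memberships$id == id, , drop = FALSE]
    g <- character(0)
    for (i in seq_len(nrow(m))) {
      if (d >= m$start_day[i] && d < m$end_day[i]) g <- c(g, m$group[i])
    }
    g
  }
  n <- 0L
  for (d in days) {
    if (!alive(offspring, d) || !alive(parent, d)) next
    if (length(intersect(in_grp(offspring$id[1], d),
                         in_grp(parent$id[1], d)))) {
      n <- n + 1L
    }
  }
  n
}

# exhaustive Mendelian mismatch oracle for one trio at one locus:
# compatible iff some (maternal, paternal) allele pair equals the
# offspring's unordered pair
oracle_locus_mismatch <- function(off, mom, cand) {
  for (m in mom) {
    for (f in cand) {
      if (identical(sort(c(m, f)), sort(off))) return(FALSE)
    }
  }
  TRUE
}

make_individual <- function(id, sex = "female", birth_day = 0L,
                            death_day = NA_integer_,
                            mother_id = NA_character_,
                            sire_id = NA_character_,
                            cohort = NA_character_, natal_group = "R") {
  data.frame(id = id, sex = sex, birth_day = as.integer(birth_day),
             death_day = as.integer(death_day), mother_id = mother_id,
             sire_id = sire_id, cohort = cohort, natal_group = natal_group,
             stringsAsFactors = FALSE)
}
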