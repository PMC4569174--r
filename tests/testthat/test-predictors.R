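mk_protocols <- function(focal, days) {
  data.frame(protocol_id = sprintf("p%s%d", focal, days), focal_id = focal,
             day = days, duration_min = 20, stringsAsFactors = FALSE)
}
mk_events <- function(focal, days, partners) {
  data.frame(day = days, protocol_id = sprintf("p%s%d", focal, days),
             focal_id = focal, partner_id = partners,
             stringsAsFactors = FALSE)
}

test_that("affiliation rates denominate by protocol days", {
  pro <- mk_protocols("f", c(1, 3, 5, 7, 9))
  ev <- mk_events("f", rep(c(1, 3), 5), rep("m1", 10))
  expect_equal(mean_male_affiliation(ev, pro, "f", c(0, 10)), 2.0)
  expect_equal(mean_male_affiliation(ev[0, ], mk_protocols("f", 1:8), "f",
                                     c(0, 10)), 0.0)
  expect_warning(r <- mean_male_affiliation(ev, pro, "f", c(100, 200)),
                 "no protocol days")
  expect_true(is.na(r))
})

test_that("paternal rate is the sire-restricted rate", {
  pro <- mk_protocols("f", c(1, 2, 3))
  ev <- mk_events("f", rep(1, 6), rep("dad", 6))
  expect_equal(mean_paternal_affiliation(ev, pro, "f", "dad", c(0, 10)), 2.0)
  expect_equal(mean_paternal_affiliation(ev, pro, "f", "other", c(0, 10)), 0)
  expect_true(is.na(mean_paternal_affiliation(ev, pro, "f", NA, c(0, 10))))
})

test_that("mean focal rank averages daily entries in the window", {
  rk <- data.frame(id = "f", day = 0:9, hierarchy = "female_immature",
                   rank = c(rep(0, 5), rep(1, 5)))
  expect_equal(mean_focal_rank(rk, "f", c(0, 10)), 0.5)
  expect_equal(mean_focal_rank(rk, "f", c(0, 5)), 0)
  # enumeration oracle on an explicit day list
  set.seed(5)
  rk2 <- data.frame(id = "f", day = sample(0:100, 40),
                    hierarchy = "female_immature", rank = runif(40))
  w <- c(20, 70)
  manual <- mean(rk2$rank[rk2$day >= 20 & rk2$day < 70])
  expect_equal(mean_focal_rank(rk2, "f", w), manual)
  expect_true(is.na(mean_focal_rank(rk2, "ghost", w)))
})

test_that("rank-weighted affiliation sums partner ranks per protocol day", {
  pro <- mk_protocols("f", c(1, 2))
  ev <- mk_events("f", c(1, 1, 2), c("hi", "hi", "lo"))
  rk <- data.frame(id = c("hi", "lo", "hi", "lo"), day = c(1, 1, 2, 2),
                   hierarchy = "male", rank = c(0.9, 0.1, 0.9, 0.1))
  expect_equal(rank_weighted_affiliation(ev, pro, rk, "f", c(0, 10)),
               (0.9 + 0.9 + 0.1) / 2)
  rk0 <- transform(rk, rank = 0)
  expect_equal(rank_weighted_affiliation(ev, pro, rk0, "f", c(0, 10)), 0)
  rk1 <- transform(rk, rank = 1)
  expect_equal(rank_weighted_affiliation(ev, pro, rk1, "f", c(0, 10)),
               mean_male_affiliation(ev, pro, "f", c(0, 10)))
  expect_error(
    rank_weighted_affiliation(ev, pro, rk[rk$day == 1, ], "f", c(0, 10)),
    "no male rank on day 2")
})

test_that("evenness is normalized Shannon entropy over the partner pool", {
  ev <- mk_events("f", 1:15, rep(c("a", "b", "c"), each = 5))
  expect_equal(affiliation_evenness(ev, "f", c("a", "b", "c")), 1.0)
  ev1 <- mk_events("f", 1:7, rep("a", 7))
  expect_equal(affiliation_evenness(ev1, "f", c("a", "b", "c", "d")), 0.0)
  ev2 <- mk_events("f", 1:10, rep(c("a", "b"), c(9, 1)))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(affiliation_evenness(ev2, "f", c("a", "b", "c", "d")),
               h / log(4))
  expect_true(is.na(affiliation_evenness(ev1, "f", "a")))         # S = 1
  expect_true(is.na(affiliation_evenness(ev1[0, ], "f", c("a", "b"))))
  expect_error(affiliation_evenness(ev1, "f", c("b", "c")), "outside")
})

test_that("evenness is invariant to relabeling and count scaling", {
  ev <- mk_events("f", 1:12, rep(c("a", "b", "c"), c(6, 4, 2)))
  pool <- c("a", "b", "c", "d", "e")
  base <- affiliation_evenness(ev, "f", pool)
  relab <- ev; relab$partner_id <- chartr("abc", "xyz", relab$partner_id)
  expect_equal(affiliation_evenness(relab, "f", c("x", "y", "z", "d", "e")),
               base)
  tripled <- do.call(rbind, replicate(3, ev, simplify = FALSE))
  tripled$day <- seq_len(nrow(tripled))
  expect_equal(affiliation_evenness(tripled, "f", pool), base)
})

test_that("predictor invariants hold on the synthetic cohort", {
  sim <- tiny_sim()
  males <- tiny_sim()$truth$population$males$id
  roster <- expand.grid(day = 0:(max(sim$protocols$day)), id = males,
                        stringsAsFactors = FALSE)
  ranks <- rbind(
    male_daily_ranks(sim$agonistic, roster),
    female_immature_daily_ranks(
      sim$female_order$id[order(sim$female_order$position)],
      sim$individuals, sim$memberships,
      days = sort(unique(sim$protocols$day)), group = "R"))
  focals <- sim$individuals$id[!is.na(sim$individuals$cohort)]
  tab <- suppressWarnings(build_predictor_table(
    sim$affiliation, sim$protocols, ranks, sim$individuals,
    sim$memberships, focals, window = c(0L, 365L), male_ids = males,
    group = "R"))
  expect_equal(nrow(tab), length(focals))
  ok <- !is.na(tab$mean_male_affil)
  expect_true(all(tab$weighted_affil[ok] <= tab$mean_male_affil[ok] + 1e-12))
  expect_true(all(tab$mean_paternal_affil[ok] <=
                    tab$mean_male_affil[ok] + 1e-12))
  expect_true(all(tab$evenness >= 0 & tab$evenness <= 1, na.rm = TRUE))

  # order invariance of input event rows
  shuf <- sim$affiliation[sample(nrow(sim$affiliation)), ]
  tab2 <- suppressWarnings(build_predictor_table(
    shuf, sim$protocols, ranks, sim$individuals, sim$memberships, focals,
    window = c(0L, 365L), male_ids = males, group = "R"))
  expect_equal(tab2, tab)
})

test_that("window truncation equals manual subsetting", {
  sim <- tiny_sim()
  f <- sim$individuals$id[!is.na(sim$individuals$cohort)][1]
  birth <- sim$individuals$birth_day[sim$individuals$id == f]
  w <- c(birth, birth + 200L)
  manual_ev <- sim$affiliation[sim$affiliation$focal_id == f &
                                 sim$affiliation$day >= w[1] &
                                 sim$affiliation$day < w[2], ]
  manual_pd <- unique(sim$protocols$day[sim$protocols$focal_id == f &
                                          sim$protocols$day >= w[1] &
                                          sim$protocols$day < w[2]])
  expect_equal(mean_male_affiliation(sim$affiliation, sim$protocols, f, w),
               nrow(manual_ev) / length(manual_pd))
})

test_that("simulated affiliation rate honors the configured 1.78/day", {
  sim <- tiny_sim()
  rate <- nrow(sim$affiliation) / nrow(sim$protocols)
  # dominant error: lognormal per-focal rate deviation (sd 0.15) over 10
  # focals -> SE ~ 1.78 * 0.15 / sqrt(10); Poisson noise is second order
  se <- 1.78 * 0.15 / sqrt(10) + sqrt(1.78 / nrow(sim$protocols))
  expect_lt(abs(rate - 1.78), 3 * se)
})
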