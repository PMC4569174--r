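test_that("compute_lrs counts offspring surviving the first year", {
  off <- rbind(
    make_individual("o1", birth_day = 0, death_day = 400, mother_id = "mum"),
    make_individual("o2", birth_day = 0, death_day = 200, mother_id = "mum"),
    make_individual("o3", birth_day = 0, death_day = 366, mother_id = "mum"))
  expect_equal(compute_lrs("mum", off), 2L)
  expect_equal(compute_lrs("nobody", off), 0L)
  censored <- off; censored$death_day <- NA_integer_
  expect_equal(compute_lrs("mum", censored), 3L)
  # sire links count too
  off$sire_id <- "dad"
  expect_equal(compute_lrs("dad", off), 2L)
})

test_that("co_residence_days is the half-open interval intersection", {
  kid <- make_individual("kid", birth_day = 0)
  dad <- make_individual("dad", "male", birth_day = -3000)
  mem <- data.frame(id = c("kid", "dad"), group = "R",
                    start_day = c(0L, -500L), end_day = c(3000L, 500L),
                    stringsAsFactors = FALSE)
  expect_equal(co_residence_days(kid, dad, mem), 500L)
  mem$end_day[2] <- 3000L
  expect_equal(co_residence_days(kid, dad, mem), 1461L)  # cap
  dad_dead <- dad; dad_dead$death_day <- 0L
  expect_equal(co_residence_days(kid, dad_dead, mem), 0L)
  expect_warning(
    z <- co_residence_days(kid, dad, mem[mem$id == "kid", , drop = FALSE]),
    "no membership")
  expect_equal(z, 0L)
})

test_that("co-residence agrees with day-by-day enumeration (random demographies)", {
  set.seed(18)
  for (i in 1:60) {
    kid <- make_individual("kid", birth_day = sample(0:100, 1),
                           death_day = sample(c(NA, 300:900), 1))
    dad <- make_individual("dad", "male", birth_day = -2000,
                           death_day = sample(c(NA, 200:1600), 1))
    nk <- sample(1:2, 1); nd <- sample(1:3, 1)
    ks <- sort(sample(0:1500, nk)); ds <- sort(sample(-200:1500, nd))
    mem <- rbind(
      data.frame(id = "kid", group = sample(c("R", "S"), nk, TRUE),
                 start_day = as.integer(ks),
                 end_day = as.integer(ks + sample(50:700, nk, TRUE))),
      data.frame(id = "dad", group = sample(c("R", "S"), nd, TRUE),
                 start_day = as.integer(ds),
                 end_day = as.integer(ds + sample(50:700, nd, TRUE))))
    # keep intervals per id non-overlapping
    for (id in c("kid", "dad")) {
      rows <- which(mem$id == id)
      for (j in rows[-1]) {
        prev <- rows[which(rows == j) - 1]
        if (mem$start_day[j] < mem$end_day[prev]) {
          mem$start_day[j] <- mem$end_day[prev]
        }
        if (mem$start_day[j] >= mem$end_day[j]) {
          mem$end_day[j] <- mem$start_day[j] + 1L
        }
      }
    }
    cap <- sample(c(365L, 1461L), 1)
    got <- co_residence_days(kid, dad, mem, cap_days = cap)
    expect_identical(got, oracle_co_residence(kid, dad, mem, cap),
                     info = i)
  }
})

test_that("covariate transforms are z and log-then-z", {
  rec <- data.frame(id = c("a", "b", "c"),
                    father_cores_days = c(1, 2, 3),
                    mother_cores_days = c(500, 1000, 1461))
  tr <- transform_covariates(rec)
  expect_equal(tr$father_z, c(-1, 0, 1))
  expect_equal(mean(tr$mother_logz), 0, tolerance = 1e-12)
  expect_equal(sd(tr$mother_logz), 1, tolerance = 1e-12)
  expect_equal(tr$mother_logz,
               (log(rec$mother_cores_days) - mean(log(rec$mother_cores_days))) /
                 sd(log(rec$mother_cores_days)), tolerance = 1e-12)
  # log-then-z differs from z-then-log on skewed input
  zthen <- log((rec$mother_cores_days - mean(rec$mother_cores_days)) /
                 sd(rec$mother_cores_days) + 3)
  expect_false(isTRUE(all.equal(tr$mother_logz, zthen)))
  rec$mother_cores_days[1] <- 0
  expect_error(transform_covariates(rec), "a")
})

test_that("build_lrs_table composes LRS and co-residence", {
  inds <- rbind(
    make_individual("mum", birth_day = -4000),
    make_individual("dad", "male", birth_day = -4000),
    make_individual("s1", "male", birth_day = 0, death_day = 6000,
                    mother_id = "mum", sire_id = "dad", cohort = "c1"),
    make_individual("g1", birth_day = 2000, death_day = 2400,
                    mother_id = "x", sire_id = "s1"),
    make_individual("g2", birth_day = 2100, death_day = 2200,
                    mother_id = "y", sire_id = "s1"))
  mem <- data.frame(id = c("mum", "dad", "s1"), group = "R",
                    start_day = c(-4000L, -4000L, 0L),
                    end_day = c(6000L, 800L, 6000L),
                    stringsAsFactors = FALSE)
  tab <- build_lrs_table(inds[inds$id == "s1", ], inds, mem)
  expect_equal(tab$lrs, 1L)           # g1 survives, g2 does not
  expect_equal(tab$father_cores_days, 800L)
  expect_equal(tab$mother_cores_days, 1461L)
})

test_that("vif matches brute-force R^2 and flags collinearity", {
  set.seed(19)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  v <- vif(X)
  for (j in names(X)) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
    expect_equal(v[[j]], 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_true(all(v >= 1))
  # orthogonal (and intercept-orthogonal) design -> VIFs exactly 1
  Xo <- as.data.frame(unclass(poly(1:100, 3)))
  expect_equal(unname(vif(Xo)), rep(1, 3), tolerance = 1e-9)
  # duplicated predictor -> infinite
  Xd <- data.frame(a = rnorm(20))
  Xd$b <- 2 * Xd$a
  expect_true(suppressWarnings(is.infinite(max(vif(Xd)))))
  expect_error(vif(data.frame(a = 1:5)), ">= 2")
})

test_that("dispersion is 0 for perfect fit, ~1 for Poisson, >1 for NB", {
  y <- rep(5L, 30)
  fit <- glm(y ~ 1, family = poisson())
  expect_equal(dispersion_parameter(fit, y), 0, tolerance = 1e-12)
  set.seed(20)
  yp <- rpois(2000, 4)
  expect_lt(abs(dispersion_parameter(glm(yp ~ 1, family = poisson()), yp) - 1),
            0.15)
  ynb <- rnbinom(2000, mu = 4, size = 1.5)
  expect_gt(dispersion_parameter(glm(ynb ~ 1, family = poisson()), ynb),
            1.5)
})

test_that("GLMM fits, LRT nests, and identical models give stat 0", {
  sim <- simulate_lrs_dataset(tiny_sim_cfg(), seed = 23)
  rec <- transform_covariates(sim$lrs)
  model <- suppressWarnings(fit_lrs_glmm(rec))
  expect_s3_class(model, "lrs_glmm")
  expect_setequal(model$fixed$term,
                  c("(Intercept)", "sexmale", "father_z", "mother_logz"))
  lrt <- lrt_full_vs_null(model)
  expect_equal(lrt$df, 3L)
  expect_gte(lrt$stat, 0)
  expect_gte(as.numeric(logLik(model$fit)),
             as.numeric(logLik(model$null_fit)))
  same <- model; same$null_fit <- model$fit
  l0 <- lrt_full_vs_null(same)
  expect_equal(l0$stat, 0)
  expect_equal(l0$p, 1)
  expect_gt(dispersion_parameter(model), 0)
})

test_that("degenerate random factors are dropped with a warning", {
  sim <- simulate_lrs_dataset(tiny_sim_cfg(), seed = 24)
  rec <- transform_covariates(sim$lrs)
  rec$cohort <- "only_one"
  expect_warning(m <- fit_lrs_glmm(rec), "cohort")
  expect_false("cohort" %in% names(lme4::ranef(m$fit)))
})

test_that("stability check refits once per level and finds influence", {
  cfg <- tiny_sim_cfg()
  cfg$lrs$n_mothers <- 5L; cfg$lrs$n_sires <- 4L
  cfg$lrs$n_cohorts <- 3L; cfg$lrs$n_groups <- 2L
  cfg$lrs$n_subjects <- 30L; cfg$lrs$n_females <- 15L
  sim <- simulate_lrs_dataset(cfg, seed = 25)
  rec <- transform_covariates(sim$lrs)
  model <- suppressWarnings(fit_lrs_glmm(rec, random_slopes = FALSE))
  st <- suppressWarnings(stability_check(model))
  n_levels <- sum(vapply(rec[c("mother_id", "sire_id", "cohort",
                               "birth_group")],
                         function(x) length(unique(x)), integer(1)))
  expect_equal(nrow(st$estimates) + length(st$failed), n_levels)
  expect_true(all(st$range["min", ] <= st$range["max", ]))

  # constructed influential case: one cohort holds all the high-LRS rows
  rec2 <- rec
  boost <- rec2$cohort == rec2$cohort[1]
  rec2$lrs[boost] <- rec2$lrs[boost] + 20L
  m2 <- suppressWarnings(fit_lrs_glmm(rec2, random_slopes = FALSE))
  st2 <- suppressWarnings(stability_check(m2, factors = "cohort"))
  spread2 <- diff(st2$range[, "(Intercept)"])
  expect_gt(spread2, 0.2)
})
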