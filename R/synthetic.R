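#' @title Seeded synthetic data generator
#' @description
#' Generates a synthetic free-ranging macaque dataset with the statistical
#' structure the analyses assume: one focal birth cohort inside a
#' matrilineal group with a despotic hierarchy, adult males with latent
#' fighting strengths driving agonistic outcomes, focal-protocol
#' affiliation events whose partner choice is biased towards high-ranking
#' males and the true sire, growth-curve morphometrics with injectable
#' predictor effects, Mendelian multi-locus genotypes, and an independent
#' demographic sample for the lifetime-reproductive-success model.
#' Defaults are calibrated once to the printed field descriptives (about
#' 1.8 affiliations per protocol day, partner pools of a few dozen males,
#' co-residence ranges 0-1461 and 459-1461 days) and are not tuned against
#' test outcomes.
#' @name synthetic_data
NULL

#' Default simulation configuration
#'
#' @return named list of generator parameters; see the methods vignette
#'   for units and the rationale of each default.
#' @export
sim_config <- function() {
  list(
    n_focals = 55L, n_focal_females = 27L,
    n_adult_males = 40L, n_adult_females = 50L,
    span_days = 1552L, birth_spread_days = 150L,
    protocols_per_week = 1.0,
    affil_rate = 1.78, focal_rate_cv = 0.15,
    sire_bias = 3, rank_attraction = 1.5,
    strength_sd = 1, agonistic_per_day = 4,
    attrition_mean_days = 2800, attrition_min_days = 60,
    growth = c(b0 = 0.45, b1 = 0.002917, b2 = 6.8e-7),
    growth_noise_sd = 0.05, frailty_sd = 0.12,
    effect_rank_gain_f = 0.25, effect_weighted_gain_f = 0.12,
    effect_evenness_gain_m = 0.25,
    qi_target = 2.68, crl_noise_sd = 0.03,
    testis_len = c(mean = 30, sd = 3), testis_wid = c(mean = 15, sd = 1.5),
    occasion_windows = list(infant = c(10L, 136L),
                            juvenile = c(407L, 517L),
                            adolescent = c(1502L, 1588L)),
    n_loci = 28L, alleles_per_locus = 8.6, genotyping_error = 0,
    lrs = list(n_subjects = 92L, n_females = 30L, n_cohorts = 10L,
               n_groups = 6L, n_mothers = 60L, n_sires = 40L,
               coef = c(intercept = 1.973, sex_male = -0.251,
                        father = -0.056, mother = 0.367),
               re_sd = c(mother = 0.2, sire = 0.2, cohort = 0.15,
                         group = 0.15),
               slope_sd = 0.1,
               frailty_sd = c(female = 0.25, male = 0.7),
               father_beta = c(0.342, 0.234),
               mother_gap = c(shape = 0.15, scale = 450, max = 1002))
  )
}

.ck_merge_config <- function(config) {
  utils::modifyList(sim_config(), config %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the population: demography, memberships, pedigree, genotypes
#'
#' Adult females (the maintained hierarchy), adult males with island
#' arrival dates and latent strengths, one focal birth cohort whose true
#' sires are drawn with strength-skewed success, and Mendelian genotypes
#' with configurable per-allele error.
#'
#' @param config partial [sim_config()] override.
#' @param seed integer seed.
#' @return list: `individuals`, `memberships`, `female_order`,
#'   `genotypes` (long table), `allele_freqs`, `truth` (male strengths and
#'   focal ground truth), `config`.
#' @export
simulate_population <- function(config = list(), seed = 1) {
  cfg <- .ck_merge_config(config)
  if (cfg$n_adult_males < 1 || cfg$n_adult_females < 1) {
    stop("config needs at least one adult of each sex", call. = FALSE)
  }
  set.seed(seed)
  horizon <- cfg$span_days + 365L
  fem_ids <- sprintf("F%02d", seq_len(cfg$n_adult_females))
  male_ids <- sprintf("M%02d", seq_len(cfg$n_adult_males))
  foc_ids <- sprintf("K%02d", seq_len(cfg$n_focals))

  females <- data.frame(
    id = fem_ids, sex = "female",
    birth_day = -sample(2000:6000, cfg$n_adult_females, replace = TRUE),
    death_day = NA_integer_, mother_id = NA_character_,
    sire_id = NA_character_, cohort = NA_character_, natal_group = "R",
    stringsAsFactors = FALSE)
  males <- data.frame(
    id = male_ids, sex = "male",
    birth_day = -sample(2000:8000, cfg$n_adult_males, replace = TRUE),
    death_day = NA_integer_, mother_id = NA_character_,
    sire_id = NA_character_, cohort = NA_character_, natal_group = "X",
    stringsAsFactors = FALSE)
  arrival <- -sample(250:1500, cfg$n_adult_males, replace = TRUE)

  strength <- stats::rnorm(cfg$n_adult_males, 0, cfg$strength_sd)
  names(strength) <- male_ids
  true_rank <- (rank(strength) - 1) / (cfg$n_adult_males - 1)

  sexes <- sample(c(rep("female", cfg$n_focal_females),
                    rep("male", cfg$n_focals - cfg$n_focal_females)))
  births <- sort(sample(0:cfg$birth_spread_days, cfg$n_focals,
                        replace = TRUE))
  mothers <- sample(fem_ids, cfg$n_focals, replace = TRUE)
  sires <- vapply(seq_len(cfg$n_focals), function(i) {
    w <- exp(2 * strength)
    sample(male_ids, 1, prob = w)
  }, character(1))
  # attrition: death or colony removal truncates observation
  dwell <- cfg$attrition_min_days +
    stats::rexp(cfg$n_focals, 1 / cfg$attrition_mean_days)
  death <- ifelse(births + dwell < horizon,
                  as.integer(births + round(dwell)), NA_integer_)
  focals <- data.frame(
    id = foc_ids, sex = sexes, birth_day = births, death_day = death,
    mother_id = mothers, sire_id = sires, cohort = "2004",
    natal_group = "R", stringsAsFactors = FALSE)

  individuals <- rbind(females, males, focals)
  memberships <- rbind(
    data.frame(id = fem_ids, group = "R",
               start_day = females$birth_day, end_day = horizon,
               stringsAsFactors = FALSE),
    data.frame(id = male_ids, group = "R", start_day = arrival,
               end_day = horizon, stringsAsFactors = FALSE),
    data.frame(id = foc_ids, group = "R", start_day = births,
               end_day = ifelse(is.na(death), horizon, death),
               stringsAsFactors = FALSE))

  female_order <- data.frame(position = seq_len(cfg$n_adult_females),
                             id = sample(fem_ids), stringsAsFactors = FALSE)

  # genotypes: allele frequencies per locus, parents from frequencies,
  # focals Mendelian from (mother, true sire) with optional error
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))
  freqs <- lapply(loci, function(l) {
    k <- max(2L, stats::rpois(1, cfg$alleles_per_locus))
    f <- stats::rgamma(k, 1)
    stats::setNames(f / sum(f), sprintf("%s_a%02d", l, seq_len(k)))
  })
  names(freqs) <- loci
  draw_geno <- function(id) {
    data.frame(id = id, locus = loci,
               allele1 = vapply(freqs, function(f)
                 sample(names(f), 1, prob = f), character(1)),
               allele2 = vapply(freqs, function(f)
                 sample(names(f), 1, prob = f), character(1)),
               stringsAsFactors = FALSE)
  }
  gt_parents <- do.call(rbind, lapply(c(fem_ids, male_ids), draw_geno))
  gt_parents_by <- split(gt_parents, gt_parents$id)
  mendel <- function(oid, mid, sid) {
    gm <- gt_parents_by[[mid]]; gs <- gt_parents_by[[sid]]
    a1 <- ifelse(stats::runif(cfg$n_loci) < 0.5, gm$allele1, gm$allele2)
    a2 <- ifelse(stats::runif(cfg$n_loci) < 0.5, gs$allele1, gs$allele2)
    if (cfg$genotyping_error > 0) {
      for (i in seq_len(cfg$n_loci)) {
        if (stats::runif(1) < cfg$genotyping_error) {
          a1[i] <- sample(names(freqs[[i]]), 1, prob = freqs[[i]])
        }
        if (stats::runif(1) < cfg$genotyping_error) {
          a2[i] <- sample(names(freqs[[i]]), 1, prob = freqs[[i]])
        }
      }
    }
    data.frame(id = oid, locus = loci, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }
  gt_focals <- do.call(rbind, lapply(seq_len(cfg$n_focals), function(i) {
    mendel(foc_ids[i], mothers[i], sires[i])
  }))
  genotypes <- rbind(gt_parents, gt_focals)
  rownames(genotypes) <- NULL

  truth <- list(
    males = data.frame(id = male_ids, strength = unname(strength),
                       true_rank = true_rank, stringsAsFactors = FALSE),
    focals = data.frame(id = foc_ids, true_sire = sires,
                        stringsAsFactors = FALSE))
  list(individuals = validate_table(individuals, "individual"),
       memberships = validate_table(memberships, "membership"),
       female_order = validate_table(female_order, "female_order"),
       genotypes = validate_table(genotypes, "genotype"),
       allele_freqs = freqs, truth = truth, config = cfg)
}

#' Simulate behavior: agonistic events, protocols, affiliation events
#'
#' Agonistic outcomes are Bernoulli on a logistic contrast of latent
#' strengths. Each focal is observed under a 20-min protocol on random
#' days (at most one per day); affiliation events per protocol day are
#' Poisson with a log-rate combining the base rate and a per-focal
#' deviation, and partners are drawn with weights
#' `exp(rank_attraction * true_rank) * sire_bias^is_sire` over the males
#' present that day, so partner counts and evenness are emergent.
#'
#' @param config partial [sim_config()] override (must match the one used
#'   for `population`).
#' @param population a [simulate_population()] result.
#' @param seed integer seed.
#' @return list: `agonistic`, `protocols`, `affiliation`, `truth`
#'   (per-focal rate deviations).
#' @export
simulate_behavior <- function(config = list(), population, seed = 2) {
  cfg <- .ck_merge_config(config)
  set.seed(seed)
  pop <- population
  tm <- pop$truth$males
  male_ids <- tm$id
  strength <- stats::setNames(tm$strength, male_ids)
  arr <- stats::setNames(
    pop$memberships$start_day[match(male_ids, pop$memberships$id)],
    male_ids)

  # agonistic events among males present each day
  days <- seq_len(cfg$span_days) - 1L
  n_ev <- stats::rpois(length(days), cfg$agonistic_per_day)
  ev <- vector("list", length(days))
  for (i in seq_along(days)) {
    if (n_ev[i] == 0) next
    present <- male_ids[arr <= days[i]]
    if (length(present) < 2) next
    a <- matrix(replicate(n_ev[i], sample(present, 2)), nrow = 2)
    p_win <- stats::plogis(strength[a[1, ]] - strength[a[2, ]])
    w <- stats::runif(n_ev[i]) < p_win
    ev[[i]] <- data.frame(day = days[i],
                          winner_id = ifelse(w, a[1, ], a[2, ]),
                          loser_id = ifelse(w, a[2, ], a[1, ]),
                          stringsAsFactors = FALSE)
  }
  agonistic <- do.call(rbind, ev)
  rownames(agonistic) <- NULL

  foc <- pop$individuals[pop$individuals$id %in% pop$truth$focals$id, ,
                         drop = FALSE]
  rate_dev <- stats::rnorm(nrow(foc), 0, cfg$focal_rate_cv)
  names(rate_dev) <- foc$id
  sire_of <- stats::setNames(pop$truth$focals$true_sire,
                             pop$truth$focals$id)
  rank_of <- stats::setNames(tm$true_rank, male_ids)

  protos <- list(); affil <- list()
  p_day <- cfg$protocols_per_week / 7
  for (i in seq_len(nrow(foc))) {
    f <- foc$id[i]
    last <- min(cfg$span_days,
                if (is.na(foc$death_day[i])) cfg$span_days
                else foc$death_day[i]) - 1L
    fdays <- foc$birth_day[i]:last
    obs <- fdays[stats::runif(length(fdays)) < p_day]
    if (!length(obs)) next
    pid <- sprintf("P_%s_%05d", f, obs)
    protos[[f]] <- data.frame(protocol_id = pid, focal_id = f, day = obs,
                              duration_min = 20, stringsAsFactors = FALSE)
    lambda <- cfg$affil_rate * exp(rate_dev[[f]])
    n_aff <- stats::rpois(length(obs), lambda)
    for (j in seq_along(obs)) {
      if (n_aff[j] == 0) next
      present <- male_ids[arr <= obs[j]]
      w <- exp(cfg$rank_attraction * rank_of[present])
      w[present == sire_of[[f]]] <- w[present == sire_of[[f]]] *
        cfg$sire_bias
      partners <- sample(present, n_aff[j], replace = TRUE, prob = w)
      affil[[length(affil) + 1]] <- data.frame(
        day = obs[j], protocol_id = pid[j], focal_id = f,
        partner_id = partners, stringsAsFactors = FALSE)
    }
  }
  protocols <- do.call(rbind, protos)
  if (is.null(protocols)) {
    protocols <- data.frame(protocol_id = character(0),
                            focal_id = character(0), day = integer(0),
                            duration_min = numeric(0))
  }
  affiliation <- do.call(rbind, affil)
  if (is.null(affiliation)) {
    affiliation <- data.frame(day = integer(0), protocol_id = character(0),
                              focal_id = character(0),
                              partner_id = character(0))
  }
  if (is.null(agonistic)) {
    agonistic <- data.frame(day = integer(0), winner_id = character(0),
                            loser_id = character(0))
  }
  rownames(protocols) <- rownames(affiliation) <- NULL
  list(agonistic = validate_table(agonistic[order(agonistic$day), ],
                                  "agonistic"),
       protocols = validate_table(protocols, "protocol"),
       affiliation = validate_table(affiliation[order(affiliation$day), ],
                                    "affiliation"),
       truth = list(rate_dev = rate_dev))
}

# realized ground-truth predictor values used for effect injection,
# computed directly from the generated tables and true male ranks
.ck_truth_predictors <- function(pop, behavior, window = c(0L, 365L)) {
  foc <- pop$individuals[pop$individuals$id %in% pop$truth$focals$id, ,
                         drop = FALSE]
  rank_of <- stats::setNames(pop$truth$males$true_rank,
                             pop$truth$males$id)
  order_pos <- stats::setNames(
    rev(seq_len(nrow(pop$female_order))) - 1,
    pop$female_order$id)
  mother_rank <- order_pos[foc$mother_id] / max(order_pos)
  ev <- behavior$affiliation
  out <- data.frame(id = foc$id, rank_true = unname(mother_rank),
                    weighted_true = 0, evenness_true = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(foc))) {
    w <- foc$birth_day[i] + window
    e <- ev[ev$focal_id == foc$id[i] & ev$day >= w[1] & ev$day < w[2], ,
            drop = FALSE]
    pd <- behavior$protocols
    npd <- sum(pd$focal_id == foc$id[i] & pd$day >= w[1] & pd$day < w[2])
    if (npd > 0) {
      out$weighted_true[i] <- sum(rank_of[e$partner_id]) / npd
    }
    if (nrow(e) > 0) {
      p <- as.numeric(table(e$partner_id))
      p <- p / sum(p)
      s <- length(rank_of)
      out$evenness_true[i] <- -sum(p * log(p)) / log(s)
    }
  }
  out
}

#' Simulate morphometric measurements
#'
#' Body mass follows the shared quadratic growth curve plus a per-focal
#' frailty, measurement noise, and — from the juvenile occasion onwards —
#' the configured sex-specific predictor effects (female rank and
#' rank-weighted affiliation, male affiliation evenness), so mass *gain*
#' carries the injected signal. Crown-rump length is back-computed from a
#' target ponderal index with noise; testis dimensions are Gaussian.
#' Measurement ages are jittered inside the configured trapping windows
#' and an occasion is only observed while the focal is still present.
#'
#' @param config partial [sim_config()] override.
#' @param population a [simulate_population()] result.
#' @param behavior a [simulate_behavior()] result.
#' @param seed integer seed.
#' @return list: `morpho` table, `truth` (frailty and realized predictor
#'   values used for injection).
#' @export
simulate_morphometrics <- function(config = list(), population, behavior,
                                   seed = 3) {
  cfg <- .ck_merge_config(config)
  set.seed(seed)
  pop <- population
  foc <- pop$individuals[pop$individuals$id %in% pop$truth$focals$id, ,
                         drop = FALSE]
  tp <- .ck_truth_predictors(pop, behavior,
                             window = c(0L, 365L))
  zs <- function(x) {
    if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) {
      return(rep(0, length(x)))
    }
    z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    z[is.na(z)] <- 0
    z
  }
  eff <- ifelse(foc$sex == "female",
                cfg$effect_rank_gain_f * zs(tp$rank_true) +
                  cfg$effect_weighted_gain_f * zs(tp$weighted_true),
                cfg$effect_evenness_gain_m * zs(tp$evenness_true))
  frailty <- stats::rnorm(nrow(foc), 0, cfg$frailty_sd)
  g <- cfg$growth
  growth_at <- function(a) g[["b0"]] + g[["b1"]] * a + g[["b2"]] * a^2
  rows <- list()
  for (i in seq_len(nrow(foc))) {
    endage <- (if (is.na(foc$death_day[i])) cfg$span_days + 365L
               else foc$death_day[i]) - foc$birth_day[i]
    for (occ in names(cfg$occasion_windows)) {
      wnd <- cfg$occasion_windows[[occ]]
      age <- sample(wnd[1]:wnd[2], 1)
      if (age >= endage) next
      bm <- growth_at(age) + frailty[i] +
        (if (occ != "infant") eff[i] else 0) +
        stats::rnorm(1, 0, cfg$growth_noise_sd)
      bm <- max(bm, 0.2)
      crl <- if (occ == "adolescent") {
        sqrt(bm / cfg$qi_target * 1000) * exp(stats::rnorm(1, 0,
                                                           cfg$crl_noise_sd))
      } else NA_real_
      tl <- tw <- NA_real_
      if (occ == "adolescent" && foc$sex[i] == "male") {
        tl <- stats::rnorm(1, cfg$testis_len[["mean"]],
                           cfg$testis_len[["sd"]])
        tw <- stats::rnorm(1, cfg$testis_wid[["mean"]],
                           cfg$testis_wid[["sd"]])
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = foc$id[i], day = foc$birth_day[i] + age,
        body_mass_kg = bm, crl_cm = crl, testis_len_mm = tl,
        testis_wid_mm = tw, stringsAsFactors = FALSE)
    }
  }
  morpho <- do.call(rbind, rows)
  rownames(morpho) <- NULL
  list(morpho = validate_table(morpho, "morpho"),
       truth = cbind(tp, frailty = frailty, injected_effect = eff))
}

#' Simulate the demographic LRS dataset
#'
#' An independent sample of subjects with known sires, co-residence drawn
#' to match the configured ranges (father 0-1461, mother 459-1461 days),
#' and LRS Poisson with a log-mean built from the configured fixed
#' coefficients, crossed random intercepts, random slopes of father
#' co-residence, and a sex-specific individual frailty (males more
#' variable than females, after Bateman).
#'
#' @param config partial [sim_config()] override.
#' @param seed integer seed.
#' @return list: `lrs` table, `truth` (the generating coefficients and
#'   realized random effects).
#' @export
simulate_lrs_dataset <- function(config = list(), seed = 4) {
  cfg <- .ck_merge_config(config)$lrs
  set.seed(seed)
  n <- cfg$n_subjects
  sex <- sample(c(rep("female", cfg$n_females),
                  rep("male", n - cfg$n_females)))
  mother <- sample(sprintf("DM%02d", seq_len(cfg$n_mothers)), n,
                   replace = TRUE)
  sire <- sample(sprintf("DS%02d", seq_len(cfg$n_sires)), n, replace = TRUE)
  cohort <- sample(sprintf("C%02d", seq_len(cfg$n_cohorts)), n,
                   replace = TRUE)
  group <- sample(sprintf("G%d", seq_len(cfg$n_groups)), n, replace = TRUE)
  father_cores <- as.integer(round(1461 * stats::rbeta(
    n, cfg$father_beta[1], cfg$father_beta[2])))
  gap <- pmin(stats::rgamma(n, shape = cfg$mother_gap[["shape"]],
                            scale = cfg$mother_gap[["scale"]]),
              cfg$mother_gap[["max"]])
  mother_cores <- as.integer(round(1461 - gap))
  z <- function(x) (x - mean(x)) / stats::sd(x)
  re <- function(ids, sd) {
    u <- stats::rnorm(length(unique(ids)), 0, sd)
    names(u) <- unique(ids)
    u[ids]
  }
  re_m <- re(mother, cfg$re_sd[["mother"]])
  re_s <- re(sire, cfg$re_sd[["sire"]])
  re_c <- re(cohort, cfg$re_sd[["cohort"]])
  re_g <- re(group, cfg$re_sd[["group"]])
  sl_c <- re(cohort, cfg$slope_sd)
  sl_g <- re(group, cfg$slope_sd)
  fz <- z(father_cores)
  eta <- cfg$coef[["intercept"]] +
    cfg$coef[["sex_male"]] * (sex == "male") +
    cfg$coef[["father"]] * fz +
    cfg$coef[["mother"]] * z(log(mother_cores)) +
    re_m + re_s + re_c + re_g + (sl_c + sl_g) * fz +
    stats::rnorm(n, 0, cfg$frailty_sd[sex])
  lrs <- stats::rpois(n, exp(eta))
  tbl <- data.frame(id = sprintf("S%03d", seq_len(n)), sex = sex,
                    lrs = lrs, father_cores_days = father_cores,
                    mother_cores_days = mother_cores, mother_id = mother,
                    sire_id = sire, cohort = cohort, birth_group = group,
                    stringsAsFactors = FALSE)
  list(lrs = validate_table(tbl, "lrs"),
       truth = list(coef = cfg$coef, eta = eta))
}

#' Simulate the full dataset
#'
#' Convenience wrapper chaining [simulate_population()],
#' [simulate_behavior()], [simulate_morphometrics()] and
#' [simulate_lrs_dataset()] with sub-seeds derived from `seed`.
#'
#' @param config partial [sim_config()] override.
#' @param seed master seed.
#' @return list with all tables, ground truth and the resolved config.
#' @export
simulate_dataset <- function(config = list(), seed = 1) {
  seed <- as.integer(seed) %% 599999L
  pop <- simulate_population(config, seed = seed * 3L + 1L)
  beh <- simulate_behavior(config, pop, seed = seed * 3L + 2L)
  mor <- simulate_morphometrics(config, pop, beh, seed = seed * 3L + 3L)
  lrs <- simulate_lrs_dataset(config, seed = seed * 3L + 4L)
  list(individuals = pop$individuals, memberships = pop$memberships,
       female_order = pop$female_order, genotypes = pop$genotypes,
       agonistic = beh$agonistic, protocols = beh$protocols,
       affiliation = beh$affiliation, morpho = mor$morpho,
       lrs = lrs$lrs,
       truth = list(population = pop$truth, behavior = beh$truth,
                    morpho = mor$truth, lrs = lrs$truth),
       config = .ck_merge_config(config))
}
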