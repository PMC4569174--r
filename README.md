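# carekit

Does affiliation between adult males and immature group members pay off
for the immatures? In despotic, matrilineal primate societies (the
motivating system is a free-ranging rhesus macaque colony), adult males
affiliate with infants and juveniles — sometimes their own offspring,
often not. `carekit` is an R package for testing whether that affiliation,
and parent–offspring co-residence more generally, predicts proxies of
immature fitness. It is aimed at behavioral ecologists who have (or want
to simulate) long-term focal-observation, demographic, morphometric and
genotype data.

The package implements the full analysis chain as small, tested modules:

1. **Dominance** — daily Elo ratings for adult males (winner gains
   `k·(1−E)` with `E = 1/(1+10^((R_l−R_w)/400))`), maintained
   adult-female order with matrilineal rank inheritance (offspring
   directly below the mother, youngest first) for everyone else; each
   hierarchy standardized per day to [0, 1].
2. **Predictors** — per focal and age window: mean male–focal affiliation
   (events/protocol day), mean paternal affiliation, mean focal rank,
   rank-weighted affiliation, and the evenness of the partner
   distribution, `E = H / ln S` with `H = −Σ p_m ln p_m` over partner
   proportions and `S` the available partner pool.
3. **Morphometrics** — body-mass normalization to standard ages via
   AIC-selected growth candidates (`bm ~ age`, `bm ~ age + age²`,
   `bm ~ ln age`; normalized mass = fitted value at the standard age +
   the individual's residual), mass gain per period, Quetelet index
   `QI = BM/CRL² · 1000`, and body-mass-corrected testis volume
   `(4/3)·π·L·W² / BM`.
4. **Association screen** — Spearman rank correlations per predictor,
   proxy and sex, combined per set by Fisher's omnibus statistic
   `X = −2 Σ ln pᵢ` (df = 2k) and calibrated by permutation (response
   shuffled, predictor matrix intact) because the five tests share data.
5. **Parentage** — microsatellite paternity exclusion: candidate sires
   filtered by age (> 1250 d) and island presence (≥ 200 d before birth),
   trio/dyad mismatch counting, and the strict (0 vs ≥ 2), relaxed
   (0 vs 1) and one-mismatch gap-3 (1 vs ≥ 3) assignment rules.
6. **LRS model** — lifetime reproductive success (offspring surviving
   their first year) regressed on sex and z-transformed father / log-z
   mother co-residence in a Poisson log-link GLMM with crossed random
   intercepts (mother, sire, cohort, birth group) and random slopes of
   father co-residence, plus LRT vs the null, Pearson dispersion, VIFs
   and leave-one-level-out stability.
7. **Synthetic data** — a seeded generator producing all of the above
   inputs with configurable effect sizes, so every stage is testable
   without field data.

## Worked example

Combining a screen's p-values with Fisher's omnibus test:

```r
library(carekit)
p  <- c(0.856, 0.479, 0.057, 0.317, 0.015)   # five Spearman p-values
fo <- fot_statistic(p)
sprintf("X = %.4f, df = %d, analytic p = %.4f",
        fo$X, fo$df, fot_analytic_p(fo$X, fo$df))
#> "X = 18.2096, df = 10, analytic p = 0.0515"
```

The omnibus statistic says the *set* of five correlations is marginally
more extreme than chance; in practice you would calibrate it with
`fot_permutation()` because the five tests share the same focals.

One Elo update from a symmetric start (`k = 100`):

```r
s <- elo_update(elo_state(), "male_A", "male_B")
s$ratings
#> male_A male_B
#>   1050    950
```

A small end-to-end run on synthetic data (14 focals, ~1.5 years):

```r
cfg <- default_config()
cfg$sim <- list(n_focals = 14L, n_focal_females = 7L, n_adult_males = 15L,
                n_adult_females = 12L, span_days = 520L,
                lrs = list(n_subjects = 60L, n_females = 25L))
cfg$n_perm <- 200L
run_pipeline(cfg, "demo_out", seed = 1)
read.csv("demo_out/table2_report.csv")
#>         term estimate     se      z        p
#>  (Intercept)   1.9592 0.1769 11.074 1.67e-28
#>      sexmale  -0.4060 0.1870 -2.172 2.99e-02
#>     father_z   0.0883 0.0975  0.906 3.65e-01
#>  mother_logz   0.3055 0.1164  2.625 8.67e-03
```

Here mother co-residence (log-then-z transformed) predicts LRS
(estimate 0.31, p = 0.009) while father co-residence does not — exactly
the structure the generator injects (its default mother coefficient is
0.367). `demo_out/table1_report.csv` holds the correlation screen (five
predictor rows plus one FOT row per proxy and sex) and
`demo_out/lrs_diagnostics.json` the dispersion, VIF, LRT and stability
diagnostics.

## Command line

```sh
inst/cli/carekit run --seed 1 --out out_dir            # whole chain
inst/cli/carekit ranks --out out_dir --k 100           # one stage
inst/cli/carekit run --stages ranks,predictors --out out_dir
```

Each stage reads/writes declared CSV tables in `--out`; `manifest.json`
records the seed, config hash and per-file checksums (bit-reproducible
for a fixed seed).

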