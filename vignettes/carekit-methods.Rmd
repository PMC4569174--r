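---
title: "Methods: models, parameters and design choices in carekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in carekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carekit` tests two linked questions about male care in matrilineal
primate groups: whether adult-male affiliation with immatures predicts
proxies of immature fitness (mass gain, body fat, testis volume), and
whether parent–offspring co-residence predicts lifetime reproductive
success. This vignette documents the statistics, the defaults and their
units, what the synthetic generator does and does not emulate, and the
places where the design was genuinely open and we had to choose.

## 1. Dominance hierarchies

Adult-male ranks come from sequential Elo ratings. After each dyadic
agonistic outcome the winner gains $k\,(1-E)$ points and the loser loses
the same amount, with
$E = 1/\!\left(1+10^{(R_\ell - R_w)/400}\right)$ the winner's expected
score. The update is exactly zero-sum, winning strictly increases a
rating, and ratings of undefeated individuals never decrease.

*Defaults and why.* Start rating 1000 and $k = 100$ (points) are the
conventional defaults of the animal-contest Elo literature; the method's
originators give no canonical alternative and the downstream analyses use
only within-day *orderings*, which are insensitive to affine changes of
the rating scale. Both are configurable (`--k`, `--start-rating`).
Events within one day are processed in input order and the day's rank is
taken after the last event — a determinism convention, since sub-daily
timestamps are unavailable.

Females and immatures are ranked from a *maintained input ordering* of
adult females (the field convention: a historical ordering updated from
long-term observation), with each living immature inserted directly
below its mother, youngest sibling first ("youngest ascendancy").
Re-deriving the female hierarchy from 1990s agonistic data is explicitly
out of scope. Both hierarchies are recomputed daily (births, deaths,
migrations) and standardized to $[0,1]$ by $(n-i)/(n-1)$ for position
$i$ of $n$; a singleton hierarchy standardizes to 1 by convention
(configurable; it never occurs in realistic data).

## 2. Affiliation predictors

All "per day" rates denominate by **protocol days** — days the focal was
actually observed under the 20-min focal protocol — not calendar days,
because observation effort varies across individuals (early death or
removal). The five predictors per focal and age window:

| predictor | definition | units |
|---|---|---|
| mean male affiliation | events with any adult male / protocol days | events/day |
| mean paternal affiliation | events with the sire / protocol days | events/day |
| focal rank | mean daily standardized rank | [0, 1] |
| rank-weighted affiliation | Σ partner's male rank on event day / protocol days | events/day |
| evenness | $H/\ln S$, $H=-\sum p_m \ln p_m$ | [0, 1] |

*Evenness denominator.* The "maximum index possible" for a focal is taken
as $\ln S$ with $S$ the number of adult males **available** (co-resident
in the group during the window), not the number interacted with. This
makes a focal that concentrates all events on one partner score 0 rather
than being undefined, while a focal spreading events uniformly over every
available male scores 1. Zero-event focals get a missing value (entropy
is undefined at zero events) and are excluded from that correlation
rather than imputed.

Windows default to infancy $[0, 365)$ and full immaturity $[0, 1461)$
days since birth, both configurable. In the bundled pipeline the
infancy-window predictors screen first-year mass gain and the
immaturity-window predictors screen the longer-horizon proxies.

## 3. Growth normalization and morphometric indices

Trapping ages vary by up to ~3 months within an occasion, so masses are
normalized to standard ages (period 1: days 90 and 455; period 2: days
90 and 1552 — 4.25 y × 365.25). Three least-squares growth candidates
are fitted with sexes pooled (immature growth curves do not differ
detectably by sex in this species): linear ($bm\sim age$), squared
($bm\sim age+age^2$ — quadratic *nesting* the linear model, not $age^2$
alone), logarithmic ($bm\sim\ln age$). Selection is by least-squares AIC
$n\ln(\mathrm{RSS}/n) + 2p$ (the Gaussian constant cancels between
candidates; equal RSS makes the quadratic lose by exactly 2). The
normalized mass is the fitted value at the standard age plus the
individual's residual — its "fixed deviation from the normal growth
curve" — so an individual measured exactly at the standard age keeps its
observed mass, and normalization preserves within-occasion ordering.

*One fit per period, residuals per measurement.* A period's growth curve
is fitted on the pooled measurements of the period's trapping occasions,
and each measurement's residual normalizes it to its own occasion's
standard age. Fitting per occasion instead (an alternative reading) would
restrict each fit to a ~120-day age window in which quadratic curvature
is numerically undetectable at realistic noise, so the squared candidate
could never be selected; the pooled-period fit is the reading under which
the squared candidate's dominance is reproducible.

*AIC selection error.* With a penalty of 2, AIC accepts a spurious
quadratic term over a true linear model with irreducible probability
$P(\chi^2_1 > 2) \approx 0.157$; "recovers the generating candidate
> 90% of the time" is therefore a property of the quadratic generator
(our stated world), not of every candidate.

Body fat is proxied by the Quetelet index
$QI = BM/CRL^2 \times 1000$ (kg, cm). Testis volume uses
$(4/3)\pi L W^2 / BM$ with $L, W$ in mm the means over both testes and
triplicate measurements. Note the printed ellipsoid form differs from
the semi-axis ellipsoid volume ($\pi/6\,L W^2$) by a factor of 8; we
implement the formula as conventionally printed for this index — it is a
relative, not absolute, volume proxy, and all downstream use is
rank-based.

## 4. Correlation screen and permutation omnibus test

Each proxy is screened against each predictor by a Spearman correlation
(mid-ranks for ties; two-sided p from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df), separately per sex.
Because the five p-values per set share the same focals, the set is
combined by Fisher's omnibus statistic $X = -2\sum\ln p_i$
($\chi^2_{2k}$ under independence) and calibrated by permutation.

*What is permuted.* The response vector is shuffled across focals within
sex while the predictor matrix stays intact. This preserves the
inter-predictor dependence that motivates the permutation in the first
place; permuting predictors would destroy it. The permutation p-value
uses the add-one rule $(1 + \#\{X_\pi \ge X_0\})/(n_\pi + 1)$, so it is
never 0 and is bounded below by $1/(n_\pi+1)$. The Spearman p inside the
permutation pass uses the same t-approximation as the observed pass, so
the statistic is computed identically in both. Defaults: 1000
permutations, seeded. Labels follow the reporting convention
$p \le 0.05$ significant, $0.05 < p \le 0.1$ trend.

Multi-predictor regression for these proxies is deliberately absent:
at these sample sizes its assumptions fail, which is what motivates the
rank-correlation screen.

## 5. Paternity exclusion

Candidate sires: sampled males older than 1250 days at the infant's
birth (earliest age at reproduction) and present on the island
throughout the 200 days before it (one gestation, 166.5 ± 7.4 d, plus
margin). Mismatches are counted per locus shared by offspring and
candidate: in trio mode the candidate must carry one of the offspring's
*possible paternal alleles* (those whose complementary allele the mother
carries; an offspring–mother-incompatible locus falls back to dyad
logic); in dyad mode (mother unsampled) simple allele sharing. Candidates
sharing fewer than 12 loci with the offspring are dropped.

Assignment: best candidate 0 mismatches and runner-up ≥ 2 → strict;
0 and exactly 1 → relaxed; best 1 and runner-up ≥ 3 → accepted
one-mismatch case; anything else unassigned. Ties at the best count stay
unassigned — in the field workflow such cases go to likelihood software
(CERVUS), whose LOD machinery is out of scope here. "Runner-up" means the
minimum mismatch count among the remaining candidates. Genotyping error
is not modeled in the rule itself (the gap rules absorb it); the
generator can inject per-allele error to probe robustness.

## 6. Lifetime reproductive success model

LRS = number of offspring surviving to day 365 (missing death day counts
as survival, i.e. censored alive). Co-residence = days within the
offspring's first 1461 days (4 years — inferred from the observed range
maximum, since "immaturity" has no canonical day count in this analysis)
on which parent and offspring were both alive and in the same group,
computed on half-open membership intervals $[start, end)$ so transition
days are never double-counted.

The model is `lrs ~ sex + z(father_days) + z(log(mother_days))` with
Poisson error and log link, random intercepts for mother, sire, cohort
and birth group, and random slopes of father co-residence within cohort
and within birth group. Mother co-residence is log-transformed *before*
z-scoring (its distribution is strongly left-skewed toward the 1461-day
cap); father co-residence is z-scored only. Slope–intercept correlations
are not estimated (they add boundary-prone parameters at n ≈ 92 and the
source analysis does not state a covariance structure); this is
configurable in `fit_lrs_glmm()`.

The numerical engine is `lme4::glmer` (Laplace). The module's contract —
transforms, LRT against the random-effects-only null (df = 3, standard
χ² reference with the usual boundary caveat), Pearson dispersion
$\sum r_P^2/(n-p)$, VIFs from an ordinary linear model of the fixed
effects only, and leave-one-level-out stability of the fixed estimates —
is computed in-module and oracle-tested. The zero-variance identity
(GLMM = GLM) is asymptotic: finite samples estimate small positive
variances with positive probability, so exact agreement needs large
samples with few random-factor levels (the acceptance test uses
n = 2000).

## 7. The synthetic world

The generator emulates the structure the analyses assume, with defaults
set once from the study system's printed descriptives and never adjusted
against test outcomes:

* one focal birth cohort (default 55 focals, 27 female) born within a
  150-day season inside one group; attrition (death/removal) with mean
  dwell 2800 d, minimum 60 d, so roughly half the cohort leaves before
  4.25 y;
* ~40 adult males with latent strengths (SD 1 on the logit scale)
  driving Bernoulli agonistic outcomes (default 4/day) and a
  strength-skewed paternity lottery;
* one 20-min protocol per focal-week on average; affiliation events
  Poisson per protocol day at base rate 1.78 events/day with a lognormal
  per-focal deviation (CV 0.15); partner choice weighted by
  $\exp(1.5\cdot rank)$ and a ×3 sire bias, so partner counts and
  evenness are *emergent*, not drawn;
* quadratic growth $0.45 + 0.002917\,a + 6.8\times10^{-7}a^2$ kg (day
  $a$), chosen so first-year gain ≈ 1.2 kg and the 4.25-y mass ≈ 6.6 kg;
  measurement noise SD 0.05 kg, per-individual frailty SD 0.12 kg;
  sex-specific effects (female rank 0.25, female rank-weighted
  affiliation 0.12, male evenness 0.25 kg per SD) injected from the
  juvenile occasion onward so they appear in mass *gain*; measurement
  ages jittered inside the trapping windows 10–136, 407–517 and
  1502–1588 days;
* 28 microsatellite loci with ~8.6 alleles each, Mendelian inheritance,
  optional per-allele error;
* an independent LRS sample (default 92 subjects, 30 female, 10 cohorts,
  6 groups) with father co-residence Beta-shaped over [0, 1461] (mean
  ≈ 867, SD ≈ 572) and mother co-residence 1461 minus a truncated Gamma
  gap (range [459, 1461]); LRS Poisson with fixed coefficients
  (intercept 1.973, male −0.251, father −0.056, mother 0.367), crossed
  random effects, and sex-specific frailty (male 0.7, female 0.25) to
  reproduce the Bateman-style excess of male variance.

*What a green test does and does not establish.* The generator has no
seasonal breeding, spatial structure, observer error, female migration,
infanticide or provisioning covariates; memberships are mostly
rectangular. Green tests establish that the estimators recover what the
generator injects under the stated noise — i.e. implementation
correctness and statistical calibration — not that the field findings
themselves replicate; the source study's headline values derive from
unreleased field data and are not desk-reproducible.

## 8. Numerical and edge-case conventions

* Dates are integer day offsets from a configurable epoch; ISO dates are
  converted on read. Missing values are empty CSV fields, never
  sentinels.
* Rating ties in the daily male ordering break by id (deterministic).
* Spearman p-values are clamped to $[10^{-300}, 1]$ so the omnibus log
  never overflows; constant vectors yield missing correlations with a
  warning.
* `fot_permutation` with `n_perm = 0` returns p = 1 (only the observed
  statistic counts).
* Random factors with a single level are dropped from the GLMM with a
  warning; failed leave-one-out refits are flagged, not fatal.
* The pipeline manifest hashes the resolved config and every output
  file; identical seed + config ⇒ identical checksums (timestamps are
  recorded but excluded from the determinism contract).

## 9. Known limitations

* The female hierarchy is an input; no I&SI or David's-score inference.
* No likelihood-based (LOD) paternity confirmation; top-count ties stay
  unassigned.
* The LRT for fixed effects uses the standard χ² reference despite the
  random effects (common practice; slightly conservative here).
* The printed testis-volume formula is used as printed (see §3); values
  are comparable within this package, not across formulas.
* Per-occasion vs per-period growth fitting is a genuine ambiguity of
  the source method; we document and implement the per-period reading
  (§3).
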