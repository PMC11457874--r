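---
title: "Deriving and applying surface-fines and FSBI benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying surface-fines and FSBI benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedbench)
```

## Scope and model

`sedbench` derives sediment benchmarks for wadable (1st–4th Strahler
order) streams from bioassessment monitoring data and applies them to rate
the strength of evidence that fine sediment has altered the
macroinvertebrate community at a sampled reach. Two indicators drive
everything:

* **SF**, percent surface fines: the share of particles finer than 2.5 mm
  in a Wolman pebble count pooled across the reach's three transects. The
  2.5 mm cutoff treats the finest of the 11 count classes as sand and
  fines; a particle measured exactly at 2.5 mm belongs to the next class
  up (classes are half-open `[lower, upper)`).
* **FSBI**, the Fine Sediment Biotic Index: the sum of per-taxon sediment
  sensitivity scores over the distinct taxa present in a sample.
  Occurrence only — abundance never enters, and duplicate records
  collapse.

Three kinds of benchmark are derived.

**SF reference benchmark (`SF_ref`).** Within each stream order, a linear
τ = 0.75 quantile regression of SF on bankfull width over reference-labelled
sites. The fitted line is the SF level below which 75% of reference reaches
of that order and width are expected to fall; predicting at a reach's
bankfull width gives a reach-specific upper bound expected under reference
conditions. Quantile regression is used deliberately instead of a
conditional-mean model: local geomorphic control of bed sediment makes
exact site-specific prediction unreliable, while an upper quantile
acknowledges that variability and stays protective (a quarter of true
reference reaches will exceed it — see the false-positive discussion
below).

**FSBI reference benchmark (`FSBI_ref`).** The 25th percentile of FSBI
among reference sites within each of three ecoregion site classes
(mountains, foothills, PPBV). An FSBI strictly below it is "worse than
reference".

**Stressor–response benchmarks (`SR50`, `SR75`).** Within each site
class × order cell, logistic regression of the binary outcome
`FSBI < FSBI_ref` on SF, inverted at p = 0.5 and p = 0.75. These are the
fines levels at which the model predicts a marginal (50%) and high (75%)
probability of a worse-than-reference community.

The **evidence framework** then rates each sample event with paired data:
`unlikely` when both SF_ref and FSBI_ref are achieved, `mixed_evidence`
when exactly one is, `likely` when neither is. The rating is a pure
function of the two achievement flags; the magnitude of an exceedance
never matters. **Design-weighted relative risk** quantifies, over a
probability survey, how much more likely poor biological condition is when
the SF benchmark is exceeded than when it is achieved.

## Conventions at boundaries

Several conventions are deliberate and consistent package-wide:

* *Achievement at equality.* An indicator exactly at its benchmark is
  rated "good"/achieved; "exceeded" and "worse" are strict inequalities.
  This applies to the SF_ref comparison, the FSBI_ref comparison, the
  logistic response label (`FSBI < FSBI_ref`), and condition flags used in
  relative risk. The source coefficient tables do not state the boundary
  convention; resolving equality as achievement is the protective-of-the-
  assessor choice and is surfaced here so users can audit it.
* *Fines cutoff.* Fines are particles strictly below 2.5 mm. The exact
  boundaries of the 11 count classes are configurable; defaults follow a
  half-phi modified Wentworth series (2.5, 6, 15, 32, 45, 64, 90, 128,
  180, 256 mm, coarsest class open-ended).
* *Clipping.* `predict_sf_ref()` clips the affine prediction to [0, 100]:
  fitted lines extrapolate below zero for wide channels and a percentage
  benchmark must stay valid.
* *Rounding.* Reported SR benchmarks are rounded to the nearest integer,
  half away from zero; full precision is retained in `sf_value` and used
  in all internal computation.

## Numerical choices

**Quantile regression.** The pinball (check) loss
`Σ ρ_τ(SF_i − a − b·BW_i)` is minimised exactly for n ≤ 200 by evaluating
every line through a pair of data points — an optimal solution of the
underlying LP always interpolates two points — and by iteratively
reweighted least squares with an annealed smoothing floor above n = 200,
followed by a vertex polish (pair search among the 40 points nearest the
IRLS line, scored on the full-data loss). Flat LP optima are real:
ties within 1e-9 of the best loss are broken by smallest |slope|, then
smallest intercept, so fits are reproducible. At the optimum the number of
non-positive residuals lies in the LP band `[⌈nτ⌉ − 2, ⌊nτ⌋ + 2]`, which
the test suite checks.

**Logistic fitting.** Newton–Raphson/IRLS with step halving, standard
errors from the observed information. Complete separation is detected
(runaway linear predictor with fitted probabilities indistinguishable from
the labels) and raised as an error instead of returning divergent
coefficients. Deviances are retained so the model chi-square is exactly
`null − residual`.

**Hosmer–Lemeshow.** Events are ranked by predicted probability and split
into ten near-equal groups; events with identical predicted probability
are never split across a boundary (stable rank, boundary snapped
forward), because decile splits are otherwise order-dependent. Groups with
a degenerate expected count merge into a neighbour; the test needs at
least three final groups (df ≥ 1). Models with a significant HL p-value
but a strong chi-square and an odds-ratio interval above 1 are retained
with a warning rather than discarded — calibration failure in one decile
does not invalidate a monotone dose–response signal used only for
threshold inversion.

**Relative risk.** Weighted conditional probabilities with a
Taylor-linearised variance of log RR treating the design as single-stage
with known weights; the interval is `RR · exp(±1.96·se)`. The original
survey-package estimator uses a local-neighbourhood variance; the method
actually used is recorded in the output (`ci_method`) so intervals are not
over-interpreted. RR is invariant to rescaling all weights.

**Published coefficient sets.** `idaho_sf_ref_models()`,
`idaho_fsbi_ref()` and `idaho_sr_models()` ship the published statewide
coefficients so benchmarks can be applied without the calibration data.
One printed intercept (mountains, order 2) appears without a sign in the
source table while every other fitted intercept is negative; it is stored
as −2.18, the only sign under which inverting the printed coefficients
reproduces the reported benchmarks. Reported SR values elsewhere in that
table cannot all be regenerated exactly from the printed
two-decimal coefficients (the originals were evidently inverted at full
precision); the package reproduces the two cells that are exactly
recoverable and treats the shipped SR columns as the published values, not
as recomputations.

## The synthetic-data generator

`simulate_events()` draws BURP-like datasets with recorded generating
truth:

* site class and order are multinomial with proportions defaulting to the
  relative cell sizes of the statewide calibration dataset (classes
  0.20/0.54/0.26; orders 0.17/0.43/0.31/0.09);
* bankfull width is lognormal within order (median widths 2.5/4/7/12 m),
  truncated to physically plausible wadable-stream ranges (upper bounds
  12/14/24/40 m). Truncation keeps the generating quantile line positive
  over the whole support, so the configured line is exactly the
  conditional 75th percentile everywhere;
* SF is a logit-normal deviation around the order's generating quantile
  line: `SF = 100·plogis(logit(q(BW)/100) + shift + σ(Z − z₀.₇₅))`. By
  construction the line is the exact 75th percentile of reference SF
  (shift 0); stress and ambient events are shifted up by +1.0 and +0.5
  logits. With the default σ = 0.7 the implied reference medians (≈29% SF
  in first-order streams) and stress medians (≈48%) match the calibration
  dataset's summary statistics;
* taxa are independent Bernoulli occurrences with logistic occupancy in
  SF; score-carrying (sensitive) taxa have non-positive occupancy slopes,
  which produces the wedge-shaped FSBI response (high variance at low SF,
  a falling upper bound as SF rises). A per-class occupancy shift
  (+0.5/0/−1.5) reproduces the large between-class FSBI differences;
* weights are 1 (`equal`) or stratum extent over stratum sample size
  (`order_stratified`).

The recorded truth is never re-estimated from the emitted sample: the
quantile lines are the configured parameters; the per-class reference
`FSBI_ref` comes from the generating model via a dedicated Monte-Carlo
substream (n = 20000 per class, so its own error is below ±1 FSBI point);
and the per-class SR50/SR75 come from exact dynamic-programming
convolution of the integer taxon scores followed by root finding. Because
the occupancy mechanism does not vary with order, true SR values repeat
across orders within a class.

What the generator does *not* emulate: spatial structure and GIS
covariates, temporal autocorrelation across years, taxonomic correlation
between co-occurring taxa, abundance, and any real-data measurement error
beyond multinomial pebble-count noise. Passing recovery tests therefore
demonstrates the estimators are correct under the stated mechanism, not
that the mechanism is a complete model of field data. The within-reach SF
noise distribution in particular is a modelling convenience (nothing in
the source states it); the logit-normal form guarantees valid percentages
with a controllable upper quantile.

## Test problem sizes

The parameter-recovery suite runs the full derivation on a simulated
dataset with ~500 events per order and per site-class × order cell (6000
events, equal class and order proportions, 40% reference), and asserts
per-order quantile slopes within ±15% of truth and SR50 within ±5 SF
percentage points. That check uses a moderate SF noise level (σ = 0.3)
rather than the data-realistic default (σ = 0.7): the asymptotic sampling
error of a τ = 0.75 regression slope at 500 events per order under σ = 0.7
is roughly a quarter of the slope itself, so at realistic noise the ±15%
band measures sampling variability, not estimator quality. The moderate-
noise configuration keeps sampling error well inside the band and makes
the check informative about the implementation. Oracle-equivalence tests
(exhaustive pinball-loss search, numeric-optimizer likelihoods, relative
risk enumeration over all small 2×2 tables) run at small n where the
oracles are exact.

## Known limitations

* Site-class derivation (ordination of reference communities) and
  landscape-disturbance screening are out of scope; `reference`/`stress`
  labels and site classes are consumed as given.
* The shipped 40-taxon score table is a demonstration set; production FSBI
  scoring requires the published 206-taxon table as a user CSV. The
  percentile-to-score binning that built the published table is likewise
  consumed as configuration, not re-derived (`derive_taxon_tolerance()`
  computes the underlying 75th-percentile-at-occurrence statistic).
* Quantile fits are independent across orders; nothing prevents fitted
  lines of adjacent orders from crossing.
* Benchmarks and ratings are per sample event; aggregating ratings across
  reaches or years into a regulatory assessment decision is intentionally
  unsupported.
* The framework emits no rating on partial data — an event missing either
  indicator is excluded and reported, never downgraded to a single line of
  evidence.
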