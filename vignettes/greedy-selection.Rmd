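---
title: "Greedy three-gate variable selection for n << p linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy three-gate variable selection for n << p linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimlm)
```

## The model and its assumptions

`slimlm` fits an ordinary linear model `y = b0 + X_S b + e` where the
support `S` is a small subset of a very wide column pool — typically CpG
methylation beta values on an array with hundreds of thousands of probes
and only a few hundred to a few thousand samples. The method assumes:

* the signal is (approximately) linear and sparse — a handful of columns
  carry most of the predictable variance;
* marginal correlation is a usable proxy for relevance: a column worth
  including correlates with the outcome (or with what remains of it)
  on its own. Signals visible only through suppressor-style
  combinations of columns will be missed, a deliberate trade-off;
* columns are heavily redundant (methylomes are strongly
  inter-correlated), so rejecting a near-duplicate of an already
  accepted column loses little.

Selection proceeds in three gates. Marginal screening keeps columns with
`|cor(x_j, y)|` strictly above `corr_threshold` and queues them by
descending absolute correlation, ties broken by ascending column index
(stable and explicit, so runs are comparable). Candidates are then popped
in order; each must first correlate with the *current residuals* above
`resid_corr_threshold` — a cheap O(n) test that skips the QR refit for
candidates that can no longer contribute — and, if refit, must raise the
adjusted coefficient of determination
`1 - (1 - R^2)(n - 1)/(n - k - 1)` by at least `delta_r2`. The adjusted
form penalizes model size, which is what keeps false positives rare and
models small. Rejected candidates are discarded permanently: the queue is
walked once, unlike the active-set cycling of coordinate-descent lasso.

The ranking key is the absolute correlation, not the signed value:
strongly negative correlates are as valuable as positive ones, and
sorting on signed r would demote them to the queue tail.

The reported coefficients always come from the final joint QR refit, so
regressing the outcome on the selected columns by any least-squares
routine reproduces them (the test suite asserts agreement with a
normal-equations solve to 1e-10 on every selection run it performs).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `corr_threshold` | 0.1 | marginal screen; unitless correlation |
| `resid_corr_threshold` | 0.1 | residual-correlation shortcut gate |
| `delta_r2` | 0.01 | minimum adjusted-R² gain per accepted term (1% of outcome variance) |
| `strict_gt` | `FALSE` | use `>` instead of `>=` for the gain gate |
| `B` | 1000 | bootstrap replicates in `paired_bootstrap_f()` |
| `alpha` | 0.05 | tail probability of the central-F band |
| `epsilon` | 0.01 | R² gain to keep a term in `reduce_model()` |

Lowering the two correlation thresholds admits more candidates and more
refits (more compute); lowering `delta_r2` admits more, smaller
contributions (larger models). The gain comparison uses `>=` because
"at least 1%" is the machine-precise reading of the default gate; the
`strict_gt` switch is provided for users who prefer the strict reading.
`reduce_model()`'s `epsilon` mirrors `delta_r2` — the choice of 0.01 is
this package's own, configurable default for the test-set pruning step.

## Degrees of freedom and the comparison machinery

`calibration_fit()` regresses observed on predicted outcome; since that
simple regression has one explanatory variable, all F-band quantiles in
`paired_bootstrap_f()` use `n - 2` degrees of freedom on both margins,
derived from the actual vector length (lengths 678 and 438 give 676 and
436). Residual variances use the n−1 denominator on both sides; the
ratio is invariant to that convention as long as it is shared. Both
calibration regressions are refit inside each bootstrap replicate on the
same case draw — resampling cases, not residuals — because the two
prediction vectors are typically strongly correlated and only a paired
design keeps the comparison honest. A replicate whose resampled
prediction vector is constant has no defined calibration slope; it is
redrawn (with a log message), capped at 10·B draws. Comparing a
predictor with itself gives every `F_b = 1`, inside any band, hence
p = 1 exactly; swapping the two predictors maps each `F_b` to its
reciprocal and leaves p unchanged.

## Numerical choices

* **QR rank tolerance.** Rank deficiency is flagged at relative
  tolerance 1e-10 in the QR factorization and treated as a *rejection*
  during selection, not an error: exact or near duplicates of accepted
  columns are expected in methylome-like data. (In practice an exact
  duplicate is already caught by the residual gate — OLS residuals are
  orthogonal to accepted columns — so the rank path guards the
  near-collinear remainder.)
* **Baseline.** The first candidate passes the same two gates as every
  other, against the intercept-only model: residuals `y - mean(y)`,
  adjusted R² = 0. No special case is needed.
* **Degenerate inputs.** Zero-variance columns get r = 0 (flagged, never
  enqueued, counted in one warning); a constant outcome yields the
  intercept-only model; correlation against an all-zero residual vector
  is defined as 0 rather than NaN.
* **Degrees-of-freedom guard.** Selection halts with a warning if
  accepting another term would drive the adjusted-R² denominator
  `n - k - 1` below 1.
* **Determinism.** The screening pass accumulates each column's sums
  serially within fixed-size column blocks, so results are identical
  whatever the worker count; `workers` changes wall time only. (Block
  *size* is fixed internally: different partitions reorder BLAS
  accumulations and may differ at the 1e-16 level.)
* **Strictness.** "Above the threshold" is read as strict `>` for both
  correlation gates.

## What the synthetic generators emulate — and what they do not

`generate_null()` reproduces the canonical false-positive design: every
entry and the outcome iid standard Gaussian, so *every* selected variable
is a false positive. At n = 1000, p = 500,000 the default gates admit
about 32 variables (the seed-to-seed spread in the test suite is roughly
32–34) — the size-penalized gate is what keeps this number at a few
dozen out of the ~800 columns that clear the marginal screen by chance.

`generate_planted()` adds a sparse linear signal
`y = X[, support] %*% effects + N(0, noise_sd^2)` and, optionally,
equicorrelated column blocks built from one shared latent factor per
block: `x = sqrt(rho) z_block + sqrt(1 - rho) noise`, which hits the
target within-block correlation while keeping every column marginally
N(0,1) — the same marginal the null design uses.

Real methylation data differ in ways these generators do not model:
beta values live in [0, 1] and are typically beta-distributed, not
Gaussian; correlation is structured by genomic neighborhood and cell
composition rather than exchangeable blocks; and batch effects induce
low-rank structure. Passing tests on synthetic data therefore
demonstrate the *algorithmic* contracts (exact screening, gate logic,
OLS equivalence, false-positive behaviour under independence), not
clock-building performance on any particular cohort.

## Problem sizes used by the test suite

The suite runs the full-scale null experiment (p = 500,000, n = 1,000,
five seeds), parameter recovery on 100 planted datasets
(n = 500, p = 2,000, effects 1.5 and −1.0, noise sd 0.5), bootstrap
comparisons at B = 1000, and oracle cross-checks (brute-force screening,
normal-equations refits, frozen F-quantile values) on dozens of small
random instances. Smaller presets (e.g. n = 200, p = 5,000) are the
natural choice for quick interactive checks.

## Known limitations

* Linear, additive models only: no interactions, no basis expansions.
* Training-set p-values for the selected coefficients are deliberately
  not produced — selection over hundreds of thousands of candidates
  invalidates them by implicit multiple testing. Use held-out data and
  the comparison tools instead.
* Groups of columns that correlate similarly with the outcome are
  resolved by queue order; complicated correlation structures can make
  the greedy walk miss combinations a global penalty would find.
* Everything is held in memory; at p = 500,000 and n = 1,000 the design
  matrix alone occupies 4 GB.
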