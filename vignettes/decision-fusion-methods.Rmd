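---
title: "Decision-level fusion for DR screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-level fusion for DR screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drfusion)
```

## The problem

Automated diabetic-retinopathy (DR) screening systems commonly train several
convolutional networks on the same fundus images and obtain, per image, one
class-1 (disease) probability from each network. The networks are accurate
but correlated — they see the same lesions and share the same failure modes —
so the question is not whether to combine them but *how*: different
decision-level aggregation rules make different assumptions about classifier
reliability, interaction, and calibration. `drfusion` implements seven such
rules behind a single `score_panel` interface, together with the threshold
calibration, metric, and diagnostic machinery needed to compare them fairly.

This vignette records the models and the design decisions behind the
package; it states no result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Fusion operators

Let `p_ij` be classifier `j`'s class-1 probability for sample `i`, with `m`
classifiers.

**Hard voting** discretizes first: classifier `j` votes positive when
`p_ij ≥ 0.5` and the fused score is the vote fraction. The 0.5 vote cut with
ties voting positive matches argmax on a two-class softmax (a probability of
exactly 0.5 means the positive logit is not smaller); the cut is exposed as
`vote_cut` since screening deployments sometimes bias the base votes.

**Soft voting** averages the probabilities; **weighted soft voting** uses
weights `ω_j = Score_j / Σ Score_j` derived from per-classifier test
performance. Accuracy is the default weighting score (AUC and F1 are
supported) — with classifiers this close in accuracy the three choices are
nearly indistinguishable, and accuracy is the quantity most often published
alongside a model. Because the weights are normalized at construction, the
weighted mean needs no denominator; uniform weights recover soft voting
exactly, which the tests assert.

**Rank-based fusion** replaces each classifier's scores by fractional ranks
over the batch (average rank on ties), normalized by the batch size to
`(0, 1]`, and averages those. The fused score is therefore *batch-relative*:
it is invariant to any strictly increasing transform of a classifier's score
column (asserted property-style), which makes the method immune to
calibration differences between classifiers but means a sample's score
depends on the batch it is scored with. Average ranks on ties keep the rank
sum exact and the transform deterministic.

**Choquet and Sugeno integrals** aggregate against a fuzzy measure `μ` on
classifier coalitions, allowing the ensemble to value specific groups of
classifiers more (or less) than the sum of their parts. Per sample the
scores are sorted ascending, `a_(1) ≤ … ≤ a_(m)`, and

- Choquet: `Σ_i (a_(i) − a_(i−1)) · μ(A_i)` with `a_(0) = 0`,
- Sugeno: `max_i min(a_(i), μ(A_i))`,

where `A_i` is the coalition scoring at least `a_(i)`. Ties contribute zero
increments (Choquet) or duplicated min arguments (Sugeno), so the internal
tie order provably cannot change either value; the stable ascending sort is
used and the property is asserted. Both outputs are bounded by the sample's
extreme scores. The Sugeno integral is non-compensatory — it uses ordinal
structure only — which is why it is the operator most sensitive to poorly
chosen densities.

## The Sugeno λ-measure

Densities `g_j ∈ [0,1]` set the singleton measures, and unions obey
`μ(A∪B) = μ(A) + μ(B) + λ μ(A) μ(B)`. Requiring `μ(full set) = 1` pins λ as
the unique nontrivial root of

```
1 + λ = Π_j (1 + λ g_j),   λ ∈ (−1, ∞)
```

This identity — with λ inside the product — is the only form consistent with
the union rule and the boundary condition; the degenerate reading without λ
on the right defines nothing. The root is bracketed analytically (the side
of 0 is determined by `sign(1 − Σg)`, since `f(λ) = Π(1+λg_j) − (1+λ)` is
convex with `f(0) = 0` and `f'(0) = Σg − 1`) and solved with
`stats::uniroot` at tolerance 1e−12; `Σg = 1` short-circuits to the additive
λ = 0. Construction re-checks `μ(full) = 1` to 1e−6 and rejects infeasible
density vectors (all zero, any `g > 1`, or configurations with no root such
as a single positive density below 1). Subset evaluation folds the union
rule; tests compare it against the closed form `(Π(1+λg) − 1)/λ` and check
monotonicity over all subsets for `m ≤ 4`.

Because published ensembles rarely report their densities, two presets turn
per-classifier performance scores into densities: `"additive"` (normalize to
sum 1, λ = 0, Choquet = weighted mean) and `"sub-unit"` (normalize then
scale by `density_sum`, default 0.8, giving λ > 0 — a redundancy-aware
measure appropriate when classifiers are correlated, as CNNs trained on the
same data are). The 0.8 default is a moderate, deliberately unremarkable
choice: it keeps all coalition values well inside (0, 1) while making
super-additivity visible. A lone classifier is always assigned density 1,
the only measure consistent with `μ(full) = 1`.

## Threshold optimization and metrics

The decision rule is inclusive (`score ≥ τ` predicts DR), so `τ = 0`
predicts everything positive. The sweep evaluates the objective (F1 by
default; balanced accuracy and accuracy available) on the grid
`0, step, …, 1` with `step = 0.01` and returns the *smallest* maximizing
grid point. Smallest-wins tie-breaking favors recall — in screening, a
missed DR case costs more than a false referral. The grid is built as
`(0:k)·step` rather than `seq()` to keep the endpoints exact.

Metrics are kept at full precision as percentages and rounded only for
display. Zero-denominator conventions (precision/recall/F1 = 0 when
undefined) match how degenerate all-negative classifiers are conventionally
tabulated. AUC is the midrank Mann–Whitney statistic, identical to the
trapezoidal ROC area; tests verify this against a brute-force pairwise
oracle and an external ROC implementation.

The sweep, like the study design it mirrors, tunes τ on the evaluation set
itself. That is an optimistic protocol; `stratified_split()` is provided so
new studies can tune on a held-out calibration split instead, and the
package documentation recommends doing so.

## Calibration diagnostics

Class-conditional score densities use a Gaussian kernel with Scott's-rule
bandwidth `sd(x)·n^{−1/5}` on a 512-point grid spanning at least
`[−0.2, 1.2]` (extended by three bandwidths when scores leave `[0,1]`,
which keeps the trapezoidal integral of each density within 2% of 1). The
*decision margin* is operationalized as the 5th percentile of positive-class
scores minus the 95th percentile of negative-class scores — the width of the
no-man's-land between the bulk (90%) of each class, negative when the
classes overlap. Percentiles were chosen over extrema because single
outliers should not erase a reported margin. Margins map to three patterns:
`excellent` above 0.4 (clear bimodal separation, flexible threshold
placement), `moderate` in (0, 0.4] (compressed but usable), `severe` at or
below 0 (overlapping classes). The 0.4 and 0 cut-offs are descriptive
conventions, exposed as arguments.

## CLAHE

The five-step pipeline: tile the image, histogram each tile, clip, equalize,
and reconstruct by bilinear interpolation of tile mappings.

- **Clip convention.** A bare clip value of 2.0 is meaningless without
  units; the package interprets it relative to the mean bin height, so the
  effective cap is `max(1, clip_limit · tile_area / n_bins)` and the same
  number means the same amplification limit at any tile size. The floor of 1
  prevents a degenerate all-zero cap on tiny tiles.
- **Redistribution.** Truncated excess is spread uniformly over all bins in
  one pass. Bins may marginally exceed the cap afterward; the one-pass rule
  is deterministic and conserves mass exactly (asserted for random
  histograms).
- **Equalization.** `LUT(v) = round(255 · CDF(v))`; monotone by
  construction, last occupied bin maps to 255.
- **Reconstruction.** Each output pixel blends the LUTs of its four nearest
  tile centers bilinearly, clamping at borders and corners; with one tile
  and an unbounded clip this reduces exactly to global histogram
  equalization (oracle-tested). Images are padded to tile multiples by edge
  replication and cropped back.
- **Color.** The BT.601 luma `Y = 0.299R + 0.587G + 0.114B` is enhanced and
  the luma delta added back to all three channels, which preserves the
  chroma planes identically (up to rounding at the gamut clip); grayscale
  content stored as RGB matches the grayscale path.
- **Edge behavior worth knowing.** On a constant image the clipped histogram
  is nearly uniform, so the mapping is near-identity — within ±3 grey levels
  for tile areas of a few hundred pixels (the default 8×8 grid on 128–224 px
  images). Toy tiles below ~50 px hit the clip floor and can shift a
  constant image by a few more levels; this is a property of the
  relative-clip convention, not an error.

Default parameters are clip 2.0 and an 8×8 grid with 256 bins, the standard
configuration for 224×224 fundus inputs; `resize_bilinear()` provides the
224×224 resampling with the half-pixel-center convention. Enhancement is
applied before resizing by default in the CLI (enhance at native resolution,
then downsample), and the order is configurable since the reverse is also
defensible.

## The synthetic panel generator

The generator exists so that every operator is testable, deterministic, and
fast without any real images or trained networks. A panel spec fixes `n`,
prevalence, `m`, class-conditional Beta shapes per classifier, and an
exchangeable Gaussian-copula correlation `rho`.

- **Label counts are deterministic**: `ceiling(n · prevalence)` positives,
  so the emulated test composition of 733 samples at prevalence 372/733
  contains exactly 372 positives.
- **The `"aptos-like"` preset** uses positives `Beta(log 0.01 / log 0.5, 1)`
  ≈ Beta(6.64, 1) and negatives `Beta(1, log 0.02 / log 0.5)` ≈
  Beta(1, 5.64). These shapes are solved, not tuned: a `Beta(a, 1)` variable
  has `P(X < 0.5) = 0.5^a`, so the shapes place *exactly* 1% of positive
  mass below the 0.5 cut and 2% of negative mass above it — sensitivity 0.99
  and specificity 0.98 as marginal operating points, which the copula
  preserves. `rho = 0.6` reflects strongly correlated errors between
  networks trained on the same data.
- **Logits** are reconstructed as `(0, logit p)` — any pair with that
  difference is softmax-equivalent, so average-logit fusion is exercised on
  consistent inputs.
- **What it does not emulate**: real CNN logit magnitudes (confidence
  scaling), per-image difficulty structure, class-dependent correlation, or
  the heavy spike-near-0/1 calibration of trained softmax heads. Passing
  tests on this generator therefore demonstrate correctness of the fusion
  arithmetic and plausible ensemble behavior, not performance claims about
  any real dataset. In particular the preset's fused margins land in the
  "moderate" band — reproducing a specific published margin pattern would
  require the (unpublished) score distributions of the trained networks.

`panel_from_confusion()` inverts a confusion matrix into a single-classifier
panel whose thresholded predictions reproduce the matrix exactly (scores
drawn away from the 0.5 boundary, order shuffled), which is how the package
recomputes published per-model metric rows from their printed matrices.
`simulate_fundus()` draws a low-contrast retina-like RGB image (field-of-view
mask, bright disc, vessel walks, lesion blobs) as a CLAHE test input.

## Numerical choices and degenerate inputs

- λ root solve: bracketed `uniroot`, tolerance 1e−12, boundary re-check at
  1e−6; infeasible density vectors rejected with classed errors.
- Softmax and logit transforms use `plogis`/`qlogis` with probabilities
  clipped to `[1e−12, 1 − 1e−12]` before `logit`.
- Threshold grids and report floats are serialized at fixed precision (6
  decimals internally, 2 for display columns), and all text writers format
  numbers explicitly, so identical configs and seeds produce byte-identical
  CSV/TSV/JSON outputs (asserted).
- Constant score vectors in the KDE fall back to a 1e−3 bandwidth rather
  than failing (hard voting can produce zero-variance classes).
- All generators take a `seed` argument and restore the caller's RNG state.

## Problem sizes

The test suite runs the worked examples at their natural sizes (confusion
matrices of 733 samples, split of 3662), the property suites on hundreds of
random small instances (m ≤ 6, n ≤ 80), and the simulation checks at
n = 733–10,000; the full suite completes in well under a minute on one CPU,
and `scripts/acceptance.R` in a few seconds. These sizes were chosen to keep
randomization error far below the asserted tolerances while remaining
instant to run.

## Known limitations

- Fuzzy densities are supplied or preset-derived, never learned from data;
  multi-class (severity-grade) fusion is out of scope.
- Rank fusion scores are batch-relative and not directly comparable across
  batches of different sizes.
- The calibration module diagnoses separation; it does not recalibrate
  (no Platt/isotonic mapping, reliability diagrams, or ECE).
- CLAHE supports 8-bit images only.
- Threshold optimization on the evaluation set inherits that protocol's
  optimism; use a separate tuning split for deployable estimates.
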