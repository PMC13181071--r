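# drfusion

Decision-level ensemble fusion for binary medical screening, motivated by
automated diabetic retinopathy (DR) detection from fundus photographs.

Screening pipelines often train several convolutional networks on the same
images and then need a principled way to merge their per-image disease
probabilities into one decision. `drfusion` implements that merge step as a
standalone, testable toolkit for anyone building or auditing such ensembles:
it takes a *score panel* (an `n × m` table of class-1 probabilities from `m`
classifiers, optionally with the raw logit pairs) plus 0/1 labels, and
provides fusion, threshold calibration, screening metrics, calibration
diagnostics, and the CLAHE preprocessing step used on the images themselves.

## Methods

Seven decision-level fusion operators over a panel `p_ij` (sample `i`,
classifier `j`):

| method | fused score |
|---|---|
| hard voting | fraction of classifiers with `p_ij ≥ 0.5` (vote fraction) |
| soft voting | `mean_j p_ij` |
| weighted soft voting | `Σ_j ω_j p_ij`, `ω_j = Score_j / Σ Score_j` from per-classifier accuracy/AUC/F1 |
| rank-based fusion | mean over `j` of the batch-fractional rank of `p_ij` |
| Choquet integral | `Σ_i (a_(i) − a_(i−1)) μ(A_i)` over sorted scores and upper coalitions |
| Sugeno integral | `max_i min(a_(i), μ(A_i))` |
| average logits | two-class softmax of the mean logit pair |

The fuzzy integrals use a Sugeno λ-measure built from per-classifier
densities `g_j ∈ [0,1]`: `μ({j}) = g_j`,
`μ(A∪B) = μ(A) + μ(B) + λ μ(A) μ(B)`, with λ the unique root of
`1 + λ = Π_j (1 + λ g_j)` in `(−1, ∞)` (additive when `Σg = 1`).

Around the fusion core:

- **Threshold optimization** — sweep `τ ∈ {0, 0.01, …, 1}`, predict DR when
  `score ≥ τ`, return the smallest `τ` maximizing F1 (or balanced accuracy /
  accuracy).
- **Metrics** — accuracy, precision, recall (sensitivity), specificity, F1,
  balanced accuracy (all percentages from the `[[TN,FP],[FN,TP]]` confusion
  matrix) and Mann–Whitney ROC-AUC.
- **Calibration diagnostics** — class-conditional Gaussian KDE of the fused
  scores, a percentile decision margin (5th percentile of DR scores minus
  95th percentile of No_DR scores), and a three-way separation pattern
  (`excellent` / `moderate` / `severe`).
- **CLAHE** — contrast-limited adaptive histogram equalization (clip 2.0,
  8×8 tiles by default) with per-tile histogram clipping, uniform excess
  redistribution, and bilinear blending of tile mappings; grayscale and
  luminance-only RGB modes, plus bilinear resizing to 224×224.
- **Synthetic panels** — a Gaussian-copula / Beta-marginal generator that
  emulates a 733-sample screening test set (372 DR / 361 No_DR, four
  classifiers at sensitivity ≈ 0.99 and specificity ≈ 0.98, inter-classifier
  correlation 0.6), so every operator is testable without any image data.

## Worked example

```r
library(drfusion)

sim   <- simulate_panel(panel_spec(preset = "aptos-like"), seed = 42)
fused <- soft_vote(sim$panel)
opt   <- optimize_threshold(sim$labels, fused, objective = "f1")
ev    <- evaluate_scores(sim$labels, fused, tau = opt$tau_star)
print(opt)
print(ev$confusion)
print(ev$metrics)
margin <- decision_margin(fused, sim$labels)
cat(sprintf("margin = %.3f -> %s\n", margin, classify_separation(margin)))
```

```
<threshold_result> tau* = 0.53 maximizing f1 = 99.87% (grid of 101)
       pred
true    No_DR  DR
  No_DR   361   0
  DR        1 371
accuracy            99.86%
precision          100.00%
recall              99.73%
specificity        100.00%
f1                  99.87%
balanced_accuracy   99.87%
auc                100.00%
margin = 0.298 -> moderate
```

Soft voting over four correlated ~99%-sensitive classifiers leaves a single
false negative at the F1-optimal threshold 0.53; the 0.298 decision margin
says the two score clouds are separated but compressed, so threshold
placement has limited slack.

The same workflow is scriptable from a shell via the bundled CLI
(`inst/scripts/drfusion`): `simulate-panel`, `fuse`, `optimize-threshold`,
`evaluate`, `calibration`, `clahe`, and `report` subcommands; see
`?drfusion_cli`.

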