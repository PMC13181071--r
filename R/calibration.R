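#' Class-conditional score densities (Gaussian KDE)
#'
#' Estimates the probability density of the fused score separately for the
#' negative (No_DR) and positive (DR) classes with a Gaussian kernel and
#' Scott's-rule bandwidth `sd(x) * n^(-1/5)`, evaluated on a common 512-point
#' grid spanning at least `[-0.2, 1.2]` so both distributions and their tails
#' are visible around the unit score interval.
#'
#' @param scores a [fused_scores()] object or numeric score vector.
#' @param labels 0/1 ground-truth vector; each class needs >= 2 samples.
#' @param n_grid number of grid points, default 512.
#' @param grid_range numeric length-2; grid is extended to cover this range,
#'   default `c(-0.2, 1.2)`.
#' @param bandwidth optional fixed bandwidth overriding Scott's rule (one
#'   value applied to both classes).
#' @return list with `grid`, `density_neg`, `density_pos`, `bandwidth`
#'   (length 2, neg/pos).
#' @export
kde_density <- function(scores, labels, n_grid = 512,
                        grid_range = c(-0.2, 1.2), bandwidth = NULL) {
  s <- as_scores(scores)
  labels <- as.integer(labels)
  if (length(labels) != length(s)) drf_stop("labels and scores length mismatch")
  neg <- s[labels == 0L]
  pos <- s[labels == 1L]
  if (length(neg) < 2L || length(pos) < 2L) {
    drf_stop("KDE needs at least 2 samples in each class")
  }
  scott <- function(x) {
    bw <- stats::sd(x) * length(x)^(-1 / 5)
    if (!is.finite(bw) || bw <= 0) bw <- 1e-3  # degenerate (constant) scores
    bw
  }
  bw_neg <- if (is.null(bandwidth)) scott(neg) else bandwidth
  bw_pos <- if (is.null(bandwidth)) scott(pos) else bandwidth
  lo <- min(grid_range[1], min(s) - 3 * max(bw_neg, bw_pos))
  hi <- max(grid_range[2], max(s) + 3 * max(bw_neg, bw_pos))
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- function(x, bw) {
    d <- stats::density(x, bw = bw, kernel = "gaussian",
                        from = lo, to = hi, n = n_grid)
    d$y
  }
  list(grid = grid,
       density_neg = dens(neg, bw_neg),
       density_pos = dens(pos, bw_pos),
       bandwidth = c(neg = bw_neg, pos = bw_pos))
}

#' Decision margin between the class score distributions
#'
#' Defined as the 5th percentile of the positive-class scores minus the 95th
#' percentile of the negative-class scores: the width of the score band that
#' separates the bulk (90%) of each class. Negative values indicate
#' overlapping distributions. The margin is translation-invariant in the
#' scores.
#'
#' @inheritParams kde_density
#' @return the margin in probability units (may be negative).
#' @export
decision_margin <- function(scores, labels) {
  s <- as_scores(scores)
  labels <- as.integer(labels)
  if (length(labels) != length(s)) drf_stop("labels and scores length mismatch")
  neg <- s[labels == 0L]
  pos <- s[labels == 1L]
  if (length(neg) == 0L || length(pos) == 0L) {
    drf_stop("decision margin needs both classes present")
  }
  unname(stats::quantile(pos, 0.05) - stats::quantile(neg, 0.95))
}

#' Classify the separation pattern of a fused-score distribution
#'
#' Maps a decision margin to one of three calibration patterns seen in
#' ensemble score distributions: `"excellent"` for wide margins (clear bimodal
#' separation, flexible threshold placement), `"moderate"` for positive but
#' compressed margins (adequate separation, limited threshold flexibility),
#' and `"severe"` for zero or negative margins (near-overlapping classes,
#' ambiguous decision regions).
#'
#' @param margin decision margin in probability units.
#' @param cut_excellent margin above which separation is `"excellent"`
#'   (default 0.4).
#' @param cut_severe margin at or below which separation is `"severe"`
#'   (default 0).
#' @return one of `"excellent"`, `"moderate"`, `"severe"`.
#' @export
classify_separation <- function(margin, cut_excellent = 0.4, cut_severe = 0) {
  if (!is_scalar_number(margin)) drf_stop("`margin` must be a single number")
  if (cut_severe >= cut_excellent) drf_stop("`cut_severe` must be below `cut_excellent`")
  if (margin > cut_excellent) "excellent"
  else if (margin > cut_severe) "moderate"
  else "severe"
}

#' Full calibration summary for a fused score vector
#'
#' Combines [kde_density()], [decision_margin()] and [classify_separation()]
#' into the per-method calibration diagnostic reported by the workflow.
#'
#' @inheritParams kde_density
#' @param tau optional decision threshold to record alongside (overlay value
#'   for density plots).
#' @param ... passed to [kde_density()].
#' @return list with `grid`, `density_neg`, `density_pos`, `bandwidth`,
#'   `margin`, `pattern`, `tau`.
#' @export
calibration_summary <- function(scores, labels, tau = NA_real_, ...) {
  kd <- kde_density(scores, labels, ...)
  margin <- decision_margin(scores, labels)
  c(kd, list(margin = margin, pattern = classify_separation(margin), tau = tau))
}

#' Write class-conditional densities as TSV
#'
#' Columns: `grid_point`, `density_neg`, `density_pos`.
#'
#' @param kd output of [kde_density()] or [calibration_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(kd, path) {
  df <- data.frame(grid_point = fmt_num(kd$grid),
                   density_neg = fmt_num(kd$density_neg),
                   density_pos = fmt_num(kd$density_pos))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
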