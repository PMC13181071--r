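#' Specification of a synthetic classifier score panel
#'
#' Describes a panel of `m` correlated binary classifiers scored on `n`
#' samples. Class-1 probabilities are drawn per sample from class-conditional
#' Beta distributions (one shape pair per classifier for disease-positive and
#' disease-negative samples), coupled across classifiers through a Gaussian
#' copula with exchangeable correlation `rho` so the classifiers make
#' correlated errors, as independently trained networks on the same images
#' do.
#'
#' The `"aptos-like"` preset emulates a 733-sample fundus-screening test set
#' with 372 diseased / 361 healthy samples and four classifiers whose
#' marginal sensitivity and specificity at the 0.5 cut are 0.99 and 0.98:
#' positive-class scores follow `Beta(log(0.01)/log(0.5), 1)` (so exactly 1%
#' of the mass falls below 0.5) and negative-class scores
#' `Beta(1, log(0.02)/log(0.5))` (2% of the mass above 0.5), with
#' `rho = 0.6`.
#'
#' @param n sample count (>= 2).
#' @param prevalence fraction of disease-positive samples, in `(0, 1)`.
#' @param m number of classifiers.
#' @param beta_pos,beta_neg Beta shape pairs for the class-1 probability of
#'   positive / negative samples: length-2 vector (shared by all classifiers)
#'   or `m x 2` matrix.
#' @param rho inter-classifier Gaussian-copula correlation in `[0, 1)`.
#' @param preset `"aptos-like"` fills every field with the values above
#'   (explicit arguments still override n/m/rho if supplied).
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(n = 733, prevalence = 372 / 733, m = 4,
                       beta_pos = NULL, beta_neg = NULL, rho = 0.6,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "aptos-like")
    if (is.null(beta_pos)) beta_pos <- c(log(0.01) / log(0.5), 1)
    if (is.null(beta_neg)) beta_neg <- c(1, log(0.02) / log(0.5))
  }
  if (is.null(beta_pos)) beta_pos <- c(log(0.01) / log(0.5), 1)
  if (is.null(beta_neg)) beta_neg <- c(1, log(0.02) / log(0.5))
  if (!is_scalar_number(n) || n < 2) drf_stop("`n` must be >= 2")
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1) {
    drf_stop("`prevalence` must lie in (0, 1)")
  }
  if (!is_scalar_number(m) || m < 1) drf_stop("`m` must be >= 1")
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    drf_stop("`rho` must lie in [0, 1)")
  }
  shape_mat <- function(x, what) {
    x <- if (is.matrix(x)) x else matrix(rep(as.numeric(x), each = m), nrow = m)
    if (ncol(x) != 2L || nrow(x) != m || anyNA(x) || any(x <= 0)) {
      drf_stop(sprintf("`%s` must be positive Beta shapes: length-2 or m x 2", what))
    }
    x
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence, m = as.integer(m),
         beta_pos = shape_mat(beta_pos, "beta_pos"),
         beta_neg = shape_mat(beta_neg, "beta_neg"),
         rho = rho),
    class = "panel_spec"
  )
}

#' Simulate a correlated classifier score panel with labels
#'
#' Label counts are deterministic: the positive class gets
#' `ceiling(n * prevalence)` samples (so the `"aptos-like"` preset yields
#' exactly 372 positives out of 733), randomly interleaved. Per sample, `m`
#' correlated standard normals (`z = sqrt(rho) * shared + sqrt(1-rho) *
#' individual`) are pushed through the normal CDF to correlated uniforms and
#' then through the class-appropriate Beta quantile function, preserving each
#' classifier's marginal score distribution while inducing the requested
#' correlation. Logit pairs are reconstructed as `(0, logit(p))`, whose
#' two-class softmax recovers `p` exactly.
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed; the same seed always reproduces the same panel.
#' @return list with `panel` (a [score_panel()] carrying probs and logits)
#'   and `labels` (0/1 integer vector).
#' @export
simulate_panel <- function(spec, seed = 1) {
  if (!inherits(spec, "panel_spec")) drf_stop("expected a `panel_spec`")
  with_seed(seed, {
    n <- spec$n; m <- spec$m
    n_pos <- as.integer(ceiling(n * spec$prevalence))
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L
    shared <- stats::rnorm(n)
    z <- sqrt(spec$rho) * matrix(shared, n, m) +
      sqrt(1 - spec$rho) * matrix(stats::rnorm(n * m), n, m)
    u <- stats::pnorm(z)
    probs <- matrix(NA_real_, n, m)
    for (j in seq_len(m)) {
      pos <- labels == 1L
      probs[pos, j] <- stats::qbeta(u[pos, j], spec$beta_pos[j, 1], spec$beta_pos[j, 2])
      probs[!pos, j] <- stats::qbeta(u[!pos, j], spec$beta_neg[j, 1], spec$beta_neg[j, 2])
    }
    p_clip <- clamp(probs, 1e-12, 1 - 1e-12)
    logits <- array(0, dim = c(n, m, 2))
    logits[, , 2] <- stats::qlogis(p_clip)
    panel <- score_panel(probs, logits = logits,
                         sample_ids = sprintf("s%04d", seq_len(n)),
                         classifier_ids = paste0("clf", seq_len(m)))
    list(panel = panel, labels = labels)
  })
}

#' Stratified train/test split
#'
#' Per class, `ceiling(test_fraction * class size)` samples go to the test
#' set (random assignment under `seed`); the split of 3662 fundus images with
#' classes 1805/1857 at fraction 0.2 therefore yields a 733-sample test set
#' (361 + 372).
#'
#' @param labels 0/1 vector.
#' @param test_fraction fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) drf_stop("labels must be 0/1")
  if (!is_scalar_number(test_fraction) || test_fraction < 0 || test_fraction > 1) {
    drf_stop("`test_fraction` must lie in [0, 1]")
  }
  with_seed(seed, {
    test <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      k <- as.integer(ceiling(test_fraction * length(idx)))
      if (k > 0L) test <- c(test, sample(idx, k))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Single-classifier panel realizing a given confusion matrix
#'
#' Emits a score panel with one classifier whose scores, thresholded at 0.5,
#' reproduce the supplied confusion matrix exactly: true negatives and false
#' negatives get scores in `[0, 0.5)`, false positives and true positives in
#' `[0.5, 1]`. Useful for reconstructing the metric rows behind published
#' confusion matrices.
#'
#' @param cm a [confusion_matrix()].
#' @param seed integer seed for the score jitter.
#' @return list with `panel` (m = 1 [score_panel()]) and `labels`.
#' @export
panel_from_confusion <- function(cm, seed = 1) {
  if (!inherits(cm, "confusion_matrix")) drf_stop("expected a `confusion_matrix`")
  with_seed(seed, {
    lo <- function(k) if (k > 0) stats::runif(k, 0.02, 0.48) else numeric(0)
    hi <- function(k) if (k > 0) stats::runif(k, 0.52, 0.98) else numeric(0)
    scores <- c(lo(cm$tn), hi(cm$fp), lo(cm$fn), hi(cm$tp))
    labels <- c(rep(0L, cm$tn + cm$fp), rep(1L, cm$fn + cm$tp))
    ord <- sample.int(length(scores))  # shuffle so order carries no signal
    panel <- score_panel(matrix(scores[ord], ncol = 1),
                         sample_ids = sprintf("s%04d", seq_along(scores)),
                         classifier_ids = "clf1")
    list(panel = panel, labels = labels[ord])
  })
}

#' Synthetic low-contrast fundus-like image
#'
#' Draws a retina-like RGB test image: a dark background with a circular
#' field of view, a brighter optic-disc blob, darker curvilinear vessel
#' strokes radiating from the disc, and a few small bright/dark blobs
#' standing in for exudates and hemorrhages. The intensity range is finally
#' compressed around its mean by `contrast_level` (1 keeps full contrast;
#' smaller values flatten the image), which makes the image a natural CLAHE
#' test input.
#'
#' @param height,width positive image dimensions.
#' @param contrast_level contrast compression factor in `(0, 1]`.
#' @param seed integer seed.
#' @return RGB array `height x width x 3` of integers in `[0, 255]`.
#' @export
simulate_fundus <- function(height = 224, width = 224, contrast_level = 0.5,
                            seed = 1) {
  if (!is_scalar_number(height) || !is_scalar_number(width) ||
      height < 1 || width < 1) {
    drf_stop("image dimensions must be positive")
  }
  if (!is_scalar_number(contrast_level) || contrast_level <= 0 ||
      contrast_level > 1) {
    drf_stop("`contrast_level` must lie in (0, 1]")
  }
  with_seed(seed, {
    H <- as.integer(height); W <- as.integer(width)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    r_fov <- 0.48 * min(H, W)
    d_center <- sqrt((yy - cy)^2 + (xx - cx)^2)
    fov <- d_center <= r_fov

    # base retina: reddish-orange with a mild radial falloff
    base <- 150 - 40 * (d_center / r_fov)^2
    red <- base * 1.15
    grn <- base * 0.62
    blu <- base * 0.30

    # optic disc: bright blob off-center
    dy <- cy + stats::runif(1, -0.15, 0.15) * H
    dx <- cx + stats::runif(1, 0.1, 0.25) * W
    disc <- exp(-((yy - dy)^2 + (xx - dx)^2) / (2 * (0.06 * min(H, W))^2))
    red <- red + 90 * disc; grn <- grn + 80 * disc; blu <- blu + 50 * disc

    # vessels: random walks from the disc, drawn as darker strokes
    vess <- matrix(0, H, W)
    for (k in seq_len(8)) {
      py <- dy; px <- dx
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(round(0.9 * min(H, W)))) {
        ang <- ang + stats::rnorm(1, 0, 0.18)
        py <- py + sin(ang); px <- px + cos(ang)
        iy <- round(py); ix <- round(px)
        if (iy < 2 || iy > H - 1 || ix < 2 || ix > W - 1) break
        vess[(iy - 1):(iy + 1), (ix - 1):(ix + 1)] <- 1
      }
    }
    red <- red - 55 * vess; grn <- grn - 35 * vess; blu <- blu - 15 * vess

    # lesions: small bright (exudate) and dark (hemorrhage) blobs
    for (k in seq_len(6)) {
      ly <- stats::runif(1, 0.25 * H, 0.75 * H)
      lx <- stats::runif(1, 0.25 * W, 0.75 * W)
      blob <- exp(-((yy - ly)^2 + (xx - lx)^2) / (2 * (0.012 * min(H, W))^2))
      sgn <- if (k %% 2 == 0) 1 else -1
      red <- red + sgn * 45 * blob
      grn <- grn + sgn * 40 * blob
    }

    # sensor noise, field-of-view mask, contrast compression
    noise <- matrix(stats::rnorm(H * W, 0, 3), H, W)
    img <- array(0, dim = c(H, W, 3))
    planes <- list(red + noise, grn + noise, blu + noise)
    for (ch in 1:3) {
      p <- planes[[ch]]
      p[!fov] <- 8
      mu <- mean(p[fov])
      p[fov] <- mu + (p[fov] - mu) * contrast_level
      img[, , ch] <- clamp(round(p), 0, 255)
    }
    img
  })
}
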