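#' Sugeno lambda-fuzzy measure
#'
#' Builds a fuzzy measure (capacity) over subsets of classifiers from
#' per-classifier densities `g_i` in `[0, 1]`. Singleton measures are the
#' densities themselves; unions obey
#' `mu(A u B) = mu(A) + mu(B) + lambda * mu(A) * mu(B)`, and the interaction
#' parameter lambda is the unique root in `(-1, Inf)` of
#'
#'   `1 + lambda = prod_i (1 + lambda * g_i)`
#'
#' subject to the boundary `mu({1..m}) = 1`. When the densities sum to one
#' lambda is 0 and the measure is additive; a density sum below one forces
#' `lambda > 0` (redundancy), above one `lambda < 0` (complementarity).
#'
#' @param densities numeric vector of m densities in `[0, 1]`, not all zero.
#' @param tol convergence tolerance for the root solve.
#' @return an object of class `lambda_measure` with elements `densities`,
#'   `lambda`, and `m`.
#' @examples
#' mu <- lambda_measure(c(0.4, 0.4))
#' mu$lambda            # 1.25
#' measure_of(mu, 1:2)  # 1
#' @export
lambda_measure <- function(densities, tol = 1e-12) {
  g <- as.numeric(densities)
  if (length(g) < 1L || anyNA(g)) drf_stop("densities must be numeric")
  if (any(g < 0) || any(g > 1)) drf_stop("each density must lie in [0, 1]")
  if (all(g == 0)) drf_stop("densities must not all be zero")
  lam <- solve_lambda(g, tol = tol)
  obj <- structure(list(densities = g, lambda = lam, m = length(g)),
                   class = "lambda_measure")
  # boundary check: full-set measure must be 1 (within 1e-6)
  full <- measure_of(obj, seq_along(g))
  if (abs(full - 1) > 1e-6) {
    drf_stop(sprintf("lambda solve failed: mu(full set) = %.8f", full))
  }
  obj
}

# Root of f(lam) = prod(1 + lam * g_i) - (1 + lam) on (-1, Inf), excluding the
# trivial root lam = 0 unless sum(g) == 1. f is convex with f(0) = 0, so the
# nontrivial root is bracketed on one side of 0 determined by sign(1 - sum(g)).
solve_lambda <- function(g, tol = 1e-12) {
  s <- sum(g)
  if (abs(s - 1) < 1e-12) return(0)
  if (length(g) == 1L) {
    # single classifier: boundary mu({1}) = g = 1 required
    if (abs(g - 1) > 1e-9) drf_stop("a single density must be 1 (mu(full) = 1)")
    return(0)
  }
  f <- function(lam) prod(1 + lam * g) - (1 + lam)
  if (s < 1) {
    if (sum(g > 0) < 2L) {
      # product is affine in lambda: no root above 0, mu(full) cannot reach 1
      drf_stop("densities admit no valid lambda: need >= 2 positive densities when their sum is below 1")
    }
    lo <- tol
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2  # f -> +Inf as lam -> Inf (>= 2 nonzero g)
  } else {
    # f(-1^+) = prod(1 - g_i) >= 0 and f(0^-) < 0 since f'(0) = s - 1 > 0;
    # a density of exactly 1 collapses the product and leaves no root.
    if (any(g >= 1)) {
      drf_stop("densities admit no valid lambda: a density of 1 with total above 1 has no root in (-1, 0)")
    }
    lo <- -1 + 1e-12
    hi <- -tol
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Evaluate a lambda measure on a classifier subset
#'
#' Folds the union rule over the subset:
#' `mu(A u {i}) = mu(A) + g_i + lambda * mu(A) * g_i`.
#'
#' @param measure a [lambda_measure()].
#' @param subset integer indices of classifiers (possibly empty).
#' @return the measure value; 0 for the empty set, 1 for the full set.
#' @export
measure_of <- function(measure, subset) {
  if (!inherits(measure, "lambda_measure")) drf_stop("expected a `lambda_measure`")
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(0)
  if (any(subset < 1L) || any(subset > measure$m) || anyDuplicated(subset)) {
    drf_stop("subset must be distinct classifier indices in 1..m")
  }
  g <- measure$densities[subset]
  lam <- measure$lambda
  mu <- g[1]
  for (gi in g[-1]) mu <- mu + gi + lam * mu * gi
  mu
}

#' @export
print.lambda_measure <- function(x, ...) {
  cat(sprintf("<lambda_measure> m=%d lambda=%.6g\n", x$m, x$lambda))
  cat("densities:", paste(signif(x$densities, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Preset fuzzy densities from per-classifier performance scores
#'
#' Two conventions for turning reliability scores (accuracies, AUCs, ...) into
#' densities: `"additive"` normalizes them to sum to 1, which makes the
#' lambda-measure additive (lambda = 0) and Choquet fusion coincide with
#' weighted soft voting; `"sub-unit"` additionally scales the normalized
#' densities by `density_sum < 1`, yielding lambda > 0 so that coalitions are
#' worth more than the sum of their parts (a redundancy-aware measure).
#'
#' @param scores_per_classifier nonnegative performance scores, one per
#'   classifier.
#' @param preset `"additive"` or `"sub-unit"`.
#' @param density_sum target density sum for `"sub-unit"`, default 0.8.
#' @return a [lambda_measure()].
#' @export
density_preset <- function(scores_per_classifier,
                           preset = c("additive", "sub-unit"),
                           density_sum = 0.8) {
  preset <- match.arg(preset)
  w <- derive_weights(scores_per_classifier)
  # a lone classifier must carry the whole measure regardless of preset
  if (length(w) == 1L) return(lambda_measure(1))
  if (preset == "sub-unit") {
    if (!is_scalar_number(density_sum) || density_sum <= 0 || density_sum >= 1) {
      drf_stop("`density_sum` must lie in (0, 1)")
    }
    w <- w * density_sum
  }
  lambda_measure(w)
}

# Shared sorting machinery for the two fuzzy integrals. For one sample with
# scores a (length m): sort ascending; A_i is the set of classifiers whose
# score is >= a_(i), i.e. the last m-i+1 positions of the sort order. Tied
# scores contribute zero increments (Choquet) / identical min arguments
# (Sugeno), so tie order cannot change either integral.
upper_measures <- function(ord, measure) {
  m <- length(ord)
  vapply(seq_len(m), function(i) measure_of(measure, ord[i:m]), numeric(1))
}

#' Choquet-integral fusion
#'
#' Per sample, sorts the classifier scores ascending `a_1 <= ... <= a_m`
#' (with `a_0 = 0`) and accumulates `sum_i (a_i - a_{i-1}) * mu(A_i)` where
#' `A_i` is the coalition of classifiers scoring at least `a_i`. With an
#' additive measure this is exactly a weighted mean; a non-additive measure
#' lets the integral reward (or discount) agreement among specific coalitions.
#' The result always lies between the smallest and largest input score.
#'
#' @inheritParams hard_vote
#' @param measure a [lambda_measure()] over the panel's classifiers.
#' @return a [fused_scores()] with method `"choquet"`.
#' @export
choquet_fuse <- function(panel, measure) {
  assert_panel(panel)
  if (!inherits(measure, "lambda_measure")) drf_stop("expected a `lambda_measure`")
  m <- n_classifiers(panel)
  if (measure$m != m) {
    drf_stop(sprintf("measure arity %d does not match %d classifiers", measure$m, m))
  }
  out <- apply(panel$probs, 1, function(a) {
    ord <- order(a)
    mus <- upper_measures(ord, measure)
    sum(diff(c(0, a[ord])) * mus)
  })
  fused_scores(out, "choquet", panel$sample_ids)
}

#' Sugeno-integral fusion
#'
#' Per sample, sorts the classifier scores ascending and takes
#' `max_i min(a_i, mu(A_i))` over the upper coalitions `A_i`. The Sugeno
#' integral is a non-compensatory (max-min) aggregator: it uses the ordinal
#' structure of the scores rather than their differences, so it is robust to
#' outliers but discards fine-grained confidence information. The result lies
#' between the smallest and largest input score.
#'
#' @inheritParams choquet_fuse
#' @return a [fused_scores()] with method `"sugeno"`.
#' @export
sugeno_fuse <- function(panel, measure) {
  assert_panel(panel)
  if (!inherits(measure, "lambda_measure")) drf_stop("expected a `lambda_measure`")
  m <- n_classifiers(panel)
  if (measure$m != m) {
    drf_stop(sprintf("measure arity %d does not match %d classifiers", measure$m, m))
  }
  out <- apply(panel$probs, 1, function(a) {
    ord <- order(a)
    mus <- upper_measures(ord, measure)
    max(pmin(a[ord], mus))
  })
  fused_scores(out, "sugeno", panel$sample_ids)
}
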