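#' Hard (majority) voting
#'
#' Each base classifier casts a discrete vote for the disease class when its
#' own class-1 probability reaches `vote_cut` (ties vote positive, matching
#' argmax on a two-class softmax). The fused score is the fraction of positive
#' votes, a value in `{0, 1/m, ..., 1}`; thresholding that fraction at tau
#' recovers majority-rule classification.
#'
#' @param panel a [score_panel()].
#' @param vote_cut per-classifier vote cut-off, default 0.5.
#' @return a [fused_scores()] with method `"hard"`.
#' @export
hard_vote <- function(panel, vote_cut = 0.5) {
  assert_panel(panel)
  if (!is_scalar_number(vote_cut) || vote_cut < 0 || vote_cut > 1) {
    drf_stop("`vote_cut` must be a probability in [0, 1]")
  }
  votes <- panel$probs >= vote_cut
  fused_scores(rowMeans(votes), "hard", panel$sample_ids)
}

#' Soft (average-probability) voting
#'
#' Fused score is the arithmetic mean across classifiers of the class-1
#' probability.
#'
#' @inheritParams hard_vote
#' @return a [fused_scores()] with method `"soft"`.
#' @export
soft_vote <- function(panel) {
  assert_panel(panel)
  fused_scores(rowMeans(panel$probs), "soft", panel$sample_ids)
}

#' Derive normalized ensemble weights from per-classifier performance
#'
#' Converts per-classifier reliability scores (typically test accuracy, AUC or
#' F1) into weights `w_j = score_j / sum(score_j)`.
#'
#' @param scores_per_classifier nonnegative reliability scores, one per
#'   classifier; at least one must be positive.
#' @return numeric weight vector summing to 1.
#' @export
derive_weights <- function(scores_per_classifier) {
  s <- as.numeric(scores_per_classifier)
  if (length(s) < 1L || anyNA(s) || any(s < 0)) {
    drf_stop("classifier scores must be nonnegative numbers")
  }
  tot <- sum(s)
  if (tot <= 0) drf_stop("cannot derive weights: all classifier scores are zero")
  s / tot
}

check_weights <- function(weights, m) {
  w <- as.numeric(weights)
  if (length(w) != m) {
    drf_stop(sprintf("weight vector length %d does not match %d classifiers",
                     length(w), m))
  }
  if (anyNA(w) || any(w < 0)) drf_stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) drf_stop("weights must sum to 1 (within 1e-9)")
  w
}

#' Weighted soft voting
#'
#' Fused score is `sum_j w_j p_j` with weights summing to one (so the
#' normalizing denominator is 1). With uniform weights this reduces exactly to
#' [soft_vote()].
#'
#' @inheritParams hard_vote
#' @param weights nonnegative weights summing to 1 (see [derive_weights()]).
#' @return a [fused_scores()] with method `"weighted"`.
#' @export
weighted_soft_vote <- function(panel, weights) {
  assert_panel(panel)
  w <- check_weights(weights, n_classifiers(panel))
  fused_scores(as.numeric(panel$probs %*% w), "weighted", panel$sample_ids)
}

#' Rank-based fusion
#'
#' Per classifier, the class-1 probabilities over the batch are replaced by
#' fractional ranks (ascending; ties get the average rank), normalized to
#' `(0, 1]` by dividing by the batch size `n`. The fused score is the mean of
#' the m normalized ranks. The transform is invariant to any strictly
#' increasing per-classifier rescaling of the scores, which makes the method
#' insensitive to differences in classifier calibration.
#'
#' Note the fused score is batch-relative: it depends on the sample's standing
#' within the scored batch, not on the probability values themselves.
#'
#' @inheritParams hard_vote
#' @return a [fused_scores()] with method `"rank"`.
#' @export
rank_fuse <- function(panel) {
  assert_panel(panel)
  n <- n_samples(panel)
  ranks <- apply(panel$probs, 2, rank, ties.method = "average") / n
  ranks <- matrix(ranks, nrow = n)  # apply() drops dims when n == 1
  fused_scores(rowMeans(ranks), "rank", panel$sample_ids)
}

#' Average-logits fusion
#'
#' Averages the raw two-class logit pairs elementwise across classifiers and
#' applies the two-class softmax; the fused score is the resulting class-1
#' probability. Operating before the softmax lets confident classifiers (large
#' logit magnitudes) carry more influence than probability averaging allows.
#'
#' @inheritParams hard_vote
#' @return a [fused_scores()] with method `"avg_logits"`.
#' @export
average_logits_fuse <- function(panel) {
  assert_panel(panel)
  if (is.null(panel$logits)) {
    drf_stop("average-logits fusion requires a logit panel (panel$logits)")
  }
  l0 <- rowMeans(panel$logits[, , 1, drop = FALSE])
  l1 <- rowMeans(panel$logits[, , 2, drop = FALSE])
  # stable two-class softmax: p1 = 1 / (1 + exp(l0 - l1))
  p1 <- stats::plogis(l1 - l0)
  fused_scores(p1, "avg_logits", panel$sample_ids)
}

#' Apply any of the seven fusion operators by tag
#'
#' Convenience dispatcher over the individual fusion functions.
#'
#' @inheritParams hard_vote
#' @param method one of [fusion_methods()].
#' @param weights weights for `"weighted"` (required for that method).
#' @param measure a [lambda_measure()] for `"choquet"`/`"sugeno"` (required).
#' @param vote_cut vote cut-off for `"hard"`.
#' @return a [fused_scores()].
#' @export
fuse <- function(panel, method, weights = NULL, measure = NULL, vote_cut = 0.5) {
  method <- match.arg(method, fusion_methods())
  switch(method,
    hard = hard_vote(panel, vote_cut),
    soft = soft_vote(panel),
    weighted = {
      if (is.null(weights)) drf_stop("method 'weighted' requires `weights`")
      weighted_soft_vote(panel, weights)
    },
    rank = rank_fuse(panel),
    choquet = {
      if (is.null(measure)) drf_stop("method 'choquet' requires a lambda `measure`")
      choquet_fuse(panel, measure)
    },
    sugeno = {
      if (is.null(measure)) drf_stop("method 'sugeno' requires a lambda `measure`")
      sugeno_fuse(panel, measure)
    },
    avg_logits = average_logits_fuse(panel)
  )
}
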