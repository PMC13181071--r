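# Independent reference implementations used to cross-check the package.
# These deliberately use different formulas/algorithms than the package code.

# Closed form for the Sugeno lambda-measure of a subset:
# mu(S) = (prod_{i in S} (1 + lambda g_i) - 1) / lambda   (lambda != 0)
#       = sum_{i in S} g_i                                (lambda == 0)
oracle_mu <- function(densities, lam, subset) {
  if (length(subset) == 0) return(0)
  g <- densities[subset]
  if (abs(lam) < 1e-14) return(sum(g))
  (prod(1 + lam * g) - 1) / lam
}

# Choquet integral by exact level-set integration: C = int_0^max mu({a >= t}) dt,
# piecewise constant between the sorted unique score values.
oracle_choquet <- function(a, densities, lam) {
  brk <- sort(unique(c(0, a)))
  total <- 0
  for (k in seq_along(brk)[-1]) {
    set <- which(a >= brk[k])
    total <- total + (brk[k] - brk[k - 1]) * oracle_mu(densities, lam, set)
  }
  total
}

# Sugeno integral by full subset enumeration:
# S = max_{A != empty} min( min_{i in A} a_i, mu(A) )
oracle_sugeno <- function(a, densities, lam) {
  m <- length(a)
  best <- -Inf
  for (mask in 1:(2^m - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    best <- max(best, min(min(a[set]), oracle_mu(densities, lam, set)))
  }
  best
}

# AUC by brute-force pairwise comparison over all positive/negative pairs.
oracle_auc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  100 * mean(cmp)
}

# Exhaustive threshold grid search written as a plain loop.
oracle_best_tau <- function(labels, scores, objective = "f1", step = 0.01) {
  taus <- (0:floor(1 / step + 1e-9)) * step
  best_tau <- NA_real_
  best_val <- -Inf
  for (tau in taus) {
    pred <- as.integer(scores >= tau)
    tp <- sum(labels == 1 & pred == 1); fn <- sum(labels == 1 & pred == 0)
    tn <- sum(labels == 0 & pred == 0); fp <- sum(labels == 0 & pred == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    val <- switch(objective,
      f1 = if (prec + rec > 0) 200 * prec * rec / (prec + rec) else 0,
      balanced_accuracy = 50 * (rec + spec),
      accuracy = 100 * (tp + tn) / length(labels)
    )
    if (val > best_val) { best_val <- val; best_tau <- tau }
  }
  list(tau = best_tau, value = best_val)
}

# Plain global histogram equalization on an 8-bit grayscale matrix.
oracle_global_he <- function(img) {
  h <- tabulate(as.vector(img) + 1L, nbins = 256)
  lut <- round(255 * cumsum(h) / length(img))
  matrix(lut[img + 1L], nrow(img), ncol(img))
}

# Shorthand fixture: tiny deterministic panel with logits.
tiny_panel <- function(probs) {
  probs <- as.matrix(probs)
  p <- pmin(pmax(probs, 1e-9), 1 - 1e-9)
  logits <- array(0, dim = c(nrow(p), ncol(p), 2))
  logits[, , 2] <- log(p / (1 - p))
  score_panel(probs, logits = logits)
}
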