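#' Score panels: per-classifier probability (and logit) outputs
#'
#' A score panel collects, for each of `n` samples, the class-1 (disease)
#' probability emitted by each of `m` base classifiers, and optionally the raw
#' two-class logit pair each classifier produced before its softmax. It is the
#' common input to every fusion operator in the package.
#'
#' @param probs numeric matrix, `n` samples by `m` classifiers, of class-1
#'   probabilities in `[0, 1]`.
#' @param logits optional numeric array `n x m x 2` of raw pre-softmax score
#'   pairs (column order: class 0, class 1). Required only by
#'   [average_logits_fuse()].
#' @param sample_ids optional character vector of `n` sample identifiers;
#'   defaults to `probs` row names or `"s1" ... "sn"`.
#' @param classifier_ids optional character vector of `m` classifier names;
#'   defaults to `probs` column names or `"clf1" ... "clfm"`.
#'
#' @return An object of class `score_panel`: a list with elements `probs`,
#'   `logits` (or `NULL`), `sample_ids`, `classifier_ids`.
#' @examples
#' p <- score_panel(matrix(c(0.1, 0.9, 0.2, 0.8), 2, 2))
#' soft_vote(p)
#' @export
score_panel <- function(probs, logits = NULL, sample_ids = NULL,
                        classifier_ids = NULL) {
  probs <- as.matrix(probs)
  if (!is.numeric(probs) || nrow(probs) < 1L || ncol(probs) < 1L) {
    drf_stop("`probs` must be a non-empty numeric matrix (samples x classifiers)")
  }
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    drf_stop("all probabilities must be finite and in [0, 1]")
  }
  n <- nrow(probs)
  m <- ncol(probs)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(probs)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  if (is.null(classifier_ids)) {
    classifier_ids <- colnames(probs)
    if (is.null(classifier_ids)) classifier_ids <- paste0("clf", seq_len(m))
  }
  if (length(sample_ids) != n) drf_stop("`sample_ids` length must equal nrow(probs)")
  if (length(classifier_ids) != m) drf_stop("`classifier_ids` length must equal ncol(probs)")
  if (!is.null(logits)) {
    if (!is.array(logits) || length(dim(logits)) != 3L ||
        !all(dim(logits) == c(n, m, 2L))) {
      drf_stop("`logits` must be an n x m x 2 array matching `probs`")
    }
    if (anyNA(logits) || any(!is.finite(logits))) {
      drf_stop("logits must be finite")
    }
  }
  dimnames(probs) <- list(sample_ids, classifier_ids)
  structure(
    list(probs = probs, logits = logits,
         sample_ids = as.character(sample_ids),
         classifier_ids = as.character(classifier_ids)),
    class = "score_panel"
  )
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("<score_panel> %d samples x %d classifiers%s\n",
              nrow(x$probs), ncol(x$probs),
              if (is.null(x$logits)) "" else " (+logits)"))
  cat("classifiers:", paste(x$classifier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.score_panel <- function(x) dim(x$probs)

n_classifiers <- function(panel) ncol(panel$probs)
n_samples <- function(panel) nrow(panel$probs)

assert_panel <- function(panel) {
  if (!inherits(panel, "score_panel")) {
    drf_stop("expected a `score_panel` object; see score_panel()")
  }
  invisible(panel)
}

#' Fused ensemble scores
#'
#' Container for the per-sample fused score produced by one of the seven
#' fusion operators, tagged with the method that produced it and, once chosen,
#' the decision threshold tau.
#'
#' @param scores numeric vector of fused per-sample scores.
#' @param method one of `"hard"`, `"soft"`, `"weighted"`, `"rank"`,
#'   `"choquet"`, `"sugeno"`, `"avg_logits"`.
#' @param sample_ids optional identifiers carried through from the panel.
#' @param threshold optional decision threshold in `[0, 1]`.
#' @return An object of class `fused_scores`.
#' @export
fused_scores <- function(scores, method, sample_ids = NULL, threshold = NA_real_) {
  method <- match.arg(method, fusion_methods())
  scores <- as.numeric(scores)
  if (length(scores) < 1L || anyNA(scores) || any(!is.finite(scores))) {
    drf_stop("fused scores must be a non-empty finite numeric vector")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(scores))
  if (!is.na(threshold) && (threshold < 0 || threshold > 1)) {
    drf_stop("`threshold` must lie in [0, 1]")
  }
  structure(
    list(scores = scores, method = method,
         sample_ids = as.character(sample_ids), threshold = threshold),
    class = "fused_scores"
  )
}

#' The seven fusion method tags
#' @return character vector of method names understood by [fuse()].
#' @export
fusion_methods <- function() {
  c("hard", "soft", "weighted", "rank", "choquet", "sugeno", "avg_logits")
}

#' @export
print.fused_scores <- function(x, ...) {
  cat(sprintf("<fused_scores> method=%s n=%d%s\n", x$method, length(x$scores),
              if (is.na(x$threshold)) "" else sprintf(" tau=%.4g", x$threshold)))
  print(utils::head(x$scores))
  invisible(x)
}

# Coerce fused_scores or bare numeric to a numeric score vector.
as_scores <- function(x) {
  if (inherits(x, "fused_scores")) return(x$scores)
  if (is.numeric(x)) return(as.numeric(x))
  drf_stop("expected `fused_scores` or a numeric vector of scores")
}

## ---- CSV dialects ----------------------------------------------------------
## Score panel:  sample_id, <clf_1>, ..., <clf_m>      (probabilities)
## Logit panel:  sample_id, <clf>_logit0, <clf>_logit1 pairs
## Labels:       sample_id, label                      (0 = No_DR, 1 = DR)
## Fused scores: sample_id, score, method

#' Read a score panel (and optionally a logit panel) from CSV
#'
#' @param path CSV with header `sample_id, <classifier_1>, ...`.
#' @param logits_path optional CSV with `<classifier>_logit0/_logit1` column
#'   pairs; sample order must match `path`.
#' @return a [score_panel()].
#' @export
read_score_panel <- function(path, logits_path = NULL) {
  if (!file.exists(path)) drf_stop(sprintf("score panel file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df) || ncol(df) < 2L) {
    drf_stop("score panel CSV needs a `sample_id` column plus >= 1 classifier column")
  }
  ids <- as.character(df$sample_id)
  probs <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(probs) <- "double"
  logits <- NULL
  if (!is.null(logits_path)) {
    if (!file.exists(logits_path)) {
      drf_stop(sprintf("logit panel file not found: %s", logits_path))
    }
    ldf <- utils::read.csv(logits_path, check.names = FALSE, stringsAsFactors = FALSE)
    lcols <- setdiff(names(ldf), "sample_id")
    clf <- unique(sub("_logit[01]$", "", lcols))
    if (!setequal(c(paste0(clf, "_logit0"), paste0(clf, "_logit1")), lcols)) {
      drf_stop("logit panel CSV must have <classifier>_logit0/_logit1 column pairs")
    }
    clf <- colnames(probs)  # enforce panel order
    logits <- array(NA_real_, dim = c(nrow(ldf), length(clf), 2L))
    for (j in seq_along(clf)) {
      logits[, j, 1] <- ldf[[paste0(clf[j], "_logit0")]]
      logits[, j, 2] <- ldf[[paste0(clf[j], "_logit1")]]
    }
  }
  score_panel(probs, logits = logits, sample_ids = ids,
              classifier_ids = colnames(probs))
}

#' Write a score panel to CSV (and its logits, when present)
#' @param panel a [score_panel()].
#' @param path output CSV path for probabilities.
#' @param logits_path optional output path for the logit pairs.
#' @return `path`, invisibly.
#' @export
write_score_panel <- function(panel, path, logits_path = NULL) {
  assert_panel(panel)
  df <- data.frame(sample_id = panel$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(panel$probs))) {
    df[[panel$classifier_ids[j]]] <- fmt_num(panel$probs[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(logits_path)) {
    if (is.null(panel$logits)) drf_stop("panel carries no logits to write")
    ldf <- data.frame(sample_id = panel$sample_ids, check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(panel$probs))) {
      ldf[[paste0(panel$classifier_ids[j], "_logit0")]] <- fmt_num(panel$logits[, j, 1])
      ldf[[paste0(panel$classifier_ids[j], "_logit1")]] <- fmt_num(panel$logits[, j, 2])
    }
    utils::write.csv(ldf, logits_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a binary label vector from CSV
#' @param path CSV with header `sample_id,label`; labels 0 (No_DR) / 1 (DR).
#' @return integer vector of labels, named by sample id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) drf_stop(sprintf("label file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    drf_stop("label CSV must have columns `sample_id,label`")
  }
  labels <- as.integer(df$label)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    drf_stop("labels must be 0 (No_DR) or 1 (DR)")
  }
  stats::setNames(labels, as.character(df$sample_id))
}

#' Write labels to CSV
#' @param labels 0/1 vector; names (if any) become sample ids.
#' @param path output path.
#' @param sample_ids optional explicit sample ids.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sample_ids = NULL) {
  labels <- as.integer(labels)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(labels))) names(labels) else paste0("s", seq_along(labels))
  }
  utils::write.csv(
    data.frame(sample_id = sample_ids, label = labels),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write fused scores to CSV (`sample_id, score, method`)
#' @param fused a [fused_scores()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fused_scores <- function(fused, path) {
  if (!inherits(fused, "fused_scores")) drf_stop("expected a `fused_scores` object")
  utils::write.csv(
    data.frame(sample_id = fused$sample_ids,
               score = fmt_num(fused$scores),
               method = fused$method),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read fused scores written by [write_fused_scores()]
#' @param path CSV with columns `sample_id, score, method`.
#' @return a [fused_scores()] object.
#' @export
read_fused_scores <- function(path) {
  if (!file.exists(path)) drf_stop(sprintf("fused score file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "score", "method") %in% names(df))) {
    drf_stop("fused score CSV must have columns `sample_id,score,method`")
  }
  fused_scores(df$score, method = df$method[1], sample_ids = df$sample_id)
}
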