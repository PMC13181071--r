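#' Run the full fusion workflow from a configuration
#'
#' Executes one or more fusion methods over a score panel, optionally
#' optimizes the decision threshold, evaluates screening metrics and
#' calibration diagnostics per method, and (when `out_dir` is given) writes
#' one fused-score CSV per method plus a machine-readable JSON report.
#'
#' The configuration is a plain list (directly, or loaded from YAML with
#' [read_run_config()]) with fields:
#' \describe{
#'   \item{scores, logits, labels}{input CSV paths (panel, optional logit
#'     panel, labels).}
#'   \item{synthetic}{alternatively, a list passed to [panel_spec()] plus a
#'     `seed`; generates the panel and labels instead of reading files.}
#'   \item{methods}{character vector of [fusion_methods()] tags; default all
#'     seven (avg_logits is skipped with a warning when no logits exist).}
#'   \item{weight_source}{`"accuracy"`, `"auc"` or `"f1"`: per-classifier
#'     test metric (at cut 0.5) used to derive weights for weighted voting;
#'     default accuracy. Or `weights`: explicit numeric weights.}
#'   \item{densities}{explicit fuzzy densities for Choquet/Sugeno, or
#'     `density_preset` (`"additive"` / `"sub-unit"`) built from the same
#'     per-classifier metric; `density_sum` tunes `"sub-unit"` (default
#'     0.8).}
#'   \item{threshold}{list: `optimize` (default `TRUE`), `objective`
#'     (default `"f1"`), `step` (default 0.01), or a fixed `tau`.}
#'   \item{out_dir}{output directory; created if missing.}
#'   \item{vote_cut}{per-classifier vote cut for hard voting (default 0.5).}
#' }
#'
#' @param config configuration list as described above.
#' @return the report: named list (one entry per method) of metrics,
#'   threshold, confusion counts, decision margin and separation pattern,
#'   invisibly carrying attribute `paths` with any files written.
#' @export
run_fuse <- function(config) {
  if (!is.list(config)) drf_usage_stop("`config` must be a list")
  dat <- load_run_inputs(config)
  panel <- dat$panel
  labels <- dat$labels
  if (length(labels) != n_samples(panel)) {
    drf_stop("labels and score panel disagree on sample count")
  }

  methods <- config$methods %||% fusion_methods()
  bad <- setdiff(methods, fusion_methods())
  if (length(bad) > 0) {
    drf_usage_stop(sprintf("unknown fusion method(s): %s", paste(bad, collapse = ", ")))
  }
  if ("avg_logits" %in% methods && is.null(panel$logits)) {
    warning("no logit panel available; skipping avg_logits")
    methods <- setdiff(methods, "avg_logits")
  }

  # per-classifier reliability at cut 0.5 drives weights and density presets
  source <- config$weight_source %||% "accuracy"
  clf_scores <- per_classifier_metric(panel, labels, source)
  weights <- config$weights %||% derive_weights(clf_scores)
  measure <- NULL
  if (any(c("choquet", "sugeno") %in% methods)) {
    measure <- if (!is.null(config$densities)) {
      lambda_measure(config$densities)
    } else {
      density_preset(clf_scores,
                     preset = config$density_preset %||% "sub-unit",
                     density_sum = config$density_sum %||% 0.8)
    }
  }

  thr <- config$threshold %||% list()
  optimize <- thr$optimize %||% is.null(thr$tau)
  objective <- thr$objective %||% "f1"
  step <- thr$step %||% 0.01

  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  report <- list()
  paths <- character(0)
  for (method in methods) {
    fused <- fuse(panel, method, weights = weights, measure = measure,
                  vote_cut = config$vote_cut %||% 0.5)
    if (optimize) {
      opt <- optimize_threshold(labels, fused, objective = objective, step = step)
      tau <- opt$tau_star
    } else {
      tau <- thr$tau %||% 0.5
    }
    fused$threshold <- tau
    ev <- evaluate_scores(labels, fused, tau = tau)
    margin <- decision_margin(fused, labels)
    report[[method]] <- list(
      method = method,
      tau = tau,
      threshold_objective = if (optimize) objective else "fixed",
      metrics = unclass(ev$metrics),
      confusion = list(tn = ev$confusion$tn, fp = ev$confusion$fp,
                       fn = ev$confusion$fn, tp = ev$confusion$tp),
      margin = margin,
      pattern = classify_separation(margin)
    )
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, sprintf("fused_%s.csv", method))
      write_fused_scores(fused, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "report.json")
    write_report_json(report, rp)
    paths <- c(paths, rp)
  }
  attr(report, "paths") <- paths
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_run_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    spec_args <- sy[intersect(names(sy),
                              c("n", "prevalence", "m", "beta_pos", "beta_neg",
                                "rho", "preset"))]
    spec <- do.call(panel_spec, spec_args)
    sim <- simulate_panel(spec, seed = sy$seed %||% 1)
    return(list(panel = sim$panel, labels = sim$labels))
  }
  if (is.null(config$scores) || is.null(config$labels)) {
    drf_usage_stop("config needs either `synthetic` or both `scores` and `labels`")
  }
  panel <- read_score_panel(config$scores, logits_path = config$logits)
  labels <- read_labels(config$labels)
  list(panel = panel, labels = unname(labels))
}

per_classifier_metric <- function(panel, labels, source = "accuracy") {
  source <- match.arg(source, c("accuracy", "auc", "f1"))
  vapply(seq_len(n_classifiers(panel)), function(j) {
    s <- panel$probs[, j]
    if (source == "auc") return(roc_auc(labels, s))
    m <- metrics_from_confusion(confusion(labels, as.integer(s >= 0.5)))
    m[[if (source == "f1") "f1" else "accuracy"]]
  }, numeric(1))
}

#' Read a run configuration from YAML
#' @param path YAML file whose top-level keys match the fields documented in
#'   [run_fuse()].
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) drf_usage_stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

#' Write a fusion report as deterministic JSON
#'
#' Keys keep insertion order and floats are serialized at 6 decimals, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param report list returned by [run_fuse()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  attr(report, "paths") <- NULL
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Rank fusion methods across one or more reports
#'
#' Reads JSON reports written by [run_fuse()], flattens them to one row per
#' method, and orders rows by the chosen metric (descending), breaking ties
#' by method name so the ordering is deterministic.
#'
#' @param report_paths character vector of report JSON paths (>= 1).
#' @param by metric column to rank by, default `"accuracy"`.
#' @param out optional TSV output path; metric columns are displayed at 2
#'   decimals.
#' @return data.frame of the ranked comparison table (full precision).
#' @export
run_report <- function(report_paths, by = "accuracy", out = NULL) {
  if (length(report_paths) < 1L) drf_usage_stop("need at least one report file")
  rows <- list()
  for (rp in report_paths) {
    if (!file.exists(rp)) drf_stop(sprintf("report not found: %s", rp))
    rep <- jsonlite::read_json(rp, simplifyVector = TRUE)
    for (method in names(rep)) {
      e <- rep[[method]]
      rows[[length(rows) + 1L]] <- data.frame(
        report = basename(rp), method = method,
        accuracy = e$metrics$accuracy, precision = e$metrics$precision,
        recall = e$metrics$recall, specificity = e$metrics$specificity,
        f1 = e$metrics$f1, balanced_accuracy = e$metrics$balanced_accuracy,
        auc = e$metrics$auc %||% NA_real_,
        tau = e$tau, margin = e$margin, pattern = e$pattern,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (!by %in% names(tab) || !is.numeric(tab[[by]])) {
    drf_usage_stop(sprintf("cannot rank by `%s`", by))
  }
  tab <- tab[order(-tab[[by]], tab$method, tab$report), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(out)) {
    disp <- tab
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], function(x) fmt_num(x, 2))
    utils::write.table(disp, out, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tab
}
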