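make_run_inputs <- function(dir, n = 200, seed = 5) {
  sim <- simulate_panel(panel_spec(n = n, preset = "aptos-like"), seed = seed)
  paths <- list(scores = file.path(dir, "scores.csv"),
                logits = file.path(dir, "logits.csv"),
                labels = file.path(dir, "labels.csv"))
  write_score_panel(sim$panel, paths$scores, logits_path = paths$logits)
  write_labels(sim$labels, paths$labels, sample_ids = sim$panel$sample_ids)
  paths
}

test_that("run_fuse produces a complete report for all seven methods", {
  dir <- withr::local_tempdir()
  paths <- make_run_inputs(dir)
  report <- run_fuse(list(scores = paths$scores, logits = paths$logits,
                          labels = paths$labels, out_dir = dir))
  expect_setequal(names(report), fusion_methods())
  for (entry in report) {
    expect_true(all(c("accuracy", "precision", "recall", "specificity", "f1",
                      "balanced_accuracy", "auc") %in% names(entry$metrics)))
    expect_true(all(is.finite(unlist(entry$metrics))))
    expect_true(entry$pattern %in% c("excellent", "moderate", "severe"))
    expect_true(entry$tau >= 0 && entry$tau <= 1)
    expect_equal(sum(unlist(entry$confusion)), 200)
  }
  expect_true(file.exists(file.path(dir, "report.json")))
  for (m in fusion_methods()) {
    expect_true(file.exists(file.path(dir, sprintf("fused_%s.csv", m))))
  }
})

test_that("soft voting and uniform weighted voting coincide in a run", {
  dir <- withr::local_tempdir()
  paths <- make_run_inputs(dir)
  report <- run_fuse(list(scores = paths$scores, labels = paths$labels,
                          methods = c("soft", "weighted"),
                          weights = rep(0.25, 4)))
  expect_identical(report$soft$metrics, report$weighted$metrics)
  expect_identical(report$soft$tau, report$weighted$tau)
  expect_identical(report$soft$margin, report$weighted$margin)
})

test_that("a panel rebuilt from a published confusion matrix reproduces its metric row", {
  dir <- withr::local_tempdir()
  sim <- panel_from_confusion(confusion_matrix(354, 7, 3, 369), seed = 2)
  sp <- file.path(dir, "s.csv"); lp <- file.path(dir, "l.csv")
  write_score_panel(sim$panel, sp)
  write_labels(sim$labels, lp, sample_ids = sim$panel$sample_ids)
  report <- run_fuse(list(scores = sp, labels = lp, methods = "soft",
                          threshold = list(optimize = FALSE, tau = 0.5)))
  m <- report$soft$metrics
  expect_equal(round(m$accuracy, 2), 98.64)
  expect_equal(round(m$precision, 2), 98.14)
  expect_equal(round(m$recall, 2), 99.19)
  expect_equal(round(m$f1, 2), 98.66)
})

test_that("report ranking is deterministic with name tie-breaks", {
  dir <- withr::local_tempdir()
  paths <- make_run_inputs(dir)
  run_fuse(list(scores = paths$scores, labels = paths$labels,
                methods = c("soft", "hard", "rank"), out_dir = dir))
  rp <- file.path(dir, "report.json")
  tab <- run_report(rp, by = "accuracy")
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$accuracy) <= 0))
  # identical duplicate reports: stable tie order by method then report
  tab2 <- run_report(c(rp, rp), by = "accuracy")
  expect_equal(nrow(tab2), 6)
  ties <- tab2[tab2$accuracy == max(tab2$accuracy), ]
  expect_equal(ties$method, sort(ties$method))
  # single report, TSV output
  out <- file.path(dir, "cmp.tsv")
  tab3 <- run_report(rp, by = "f1", out = out)
  expect_true(file.exists(out))
  expect_true(all(diff(tab3$f1) <= 0))
  expect_error(run_report(character(0)), class = "drf_usage_error")
  expect_error(run_report(rp, by = "pattern"), class = "drf_usage_error")
})

test_that("fixed config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    p <- make_run_inputs(d, seed = 31)
    run_fuse(list(scores = p$scores, labels = p$labels,
                  methods = c("soft", "choquet"), out_dir = d))
  }
  for (f in c("report.json", "fused_soft.csv", "fused_choquet.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("config validation fails cleanly", {
  expect_error(run_fuse(list()), class = "drf_usage_error")
  expect_error(run_fuse(list(scores = "nope.csv", labels = "nope.csv")),
               class = "drf_error")
  dir <- withr::local_tempdir()
  paths <- make_run_inputs(dir)
  expect_error(run_fuse(list(scores = paths$scores, labels = paths$labels,
                             methods = "teleport")),
               class = "drf_usage_error")
  # avg_logits without logits is skipped with a warning, not an error
  expect_warning(
    rep2 <- run_fuse(list(scores = paths$scores, labels = paths$labels,
                          methods = c("soft", "avg_logits"))),
    "logit")
  expect_setequal(names(rep2), "soft")
})

test_that("the CLI drives the workflow end to end", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "s.csv"); lg <- file.path(dir, "g.csv")
  lp <- file.path(dir, "l.csv")
  expect_equal(drfusion_cli(c("simulate-panel", "--n", "150", "--seed", "4",
                              "--out-scores", sp, "--out-logits", lg,
                              "--out-labels", lp)), 0L)
  expect_true(file.exists(sp) && file.exists(lg) && file.exists(lp))
  expect_equal(drfusion_cli(c("fuse", "--scores", sp, "--logits", lg,
                              "--labels", lp, "--methods", "all",
                              "--out-dir", dir)), 0L)
  expect_true(file.exists(file.path(dir, "report.json")))
  fp <- file.path(dir, "fused_soft.csv")
  curve <- file.path(dir, "curve.tsv")
  expect_equal(drfusion_cli(c("optimize-threshold", "--fused", fp,
                              "--labels", lp, "--out", curve)), 0L)
  expect_true(file.exists(curve))
  rep_json <- file.path(dir, "eval.json")
  expect_equal(drfusion_cli(c("evaluate", "--fused", fp, "--labels", lp,
                              "--tau", "0.5", "--out", rep_json)), 0L)
  parsed <- jsonlite::read_json(rep_json, simplifyVector = TRUE)
  expect_true(parsed$metrics$accuracy >= 0 && parsed$metrics$accuracy <= 100)
  dens <- file.path(dir, "dens.tsv"); summ <- file.path(dir, "summ.json")
  expect_equal(drfusion_cli(c("calibration", "--fused", fp, "--labels", lp,
                              "--out-density", dens, "--out-summary", summ)), 0L)
  expect_true(file.exists(dens) && file.exists(summ))
  tab <- file.path(dir, "cmp.tsv")
  expect_equal(drfusion_cli(c("report", "--reports",
                              file.path(dir, "report.json"),
                              "--by", "f1", "--out", tab)), 0L)
  expect_true(file.exists(tab))
  # CLAHE subcommand on a synthetic fundus PNG
  pin <- file.path(dir, "in.png"); pout <- file.path(dir, "out.png")
  write_image_png(simulate_fundus(48, 48, 0.3, seed = 2), pin)
  expect_equal(drfusion_cli(c("clahe", "--in", pin, "--out", pout,
                              "--clip", "2.0", "--tiles", "4x4",
                              "--resize", "32x32")), 0L)
  out_img <- read_image_png(pout)
  expect_equal(dim(out_img), c(32, 32, 3))
  # exit codes: usage error 2, data error 3
  expect_equal(drfusion_cli(character(0)), 2L)
  expect_equal(drfusion_cli(c("teleport")), 2L)
  expect_equal(drfusion_cli(c("evaluate", "--fused", "missing.csv",
                              "--labels", lp)), 3L)
  # the installed launcher script exists and is a plain Rscript wrapper
  launcher <- system.file("scripts", "drfusion", package = "drfusion")
  expect_true(nzchar(launcher))
  expect_match(readLines(launcher)[1], "Rscript")
})
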