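small_run_cfg <- function(seed = 3L) {
  list(
    cohort = list(classes = list(A = 14L, B = 10L), amplitude = 0.2,
                  noise_cv = 0.05, seed = 77L),
    comparison = c("B", "A"),
    pipeline = list(epochs = 120L),
    outer_k = 3L, inner_k = 2L, bootstrap_B = 100L, seed = seed
  )
}

test_that("run configs parse from JSON with defaults and reject unknown fields", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "config.json")
  jsonlite::write_json(small_run_cfg(), path, auto_unbox = TRUE)
  cfg <- run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$cohort$classes, c(A = 14L, B = 10L))
  expect_equal(cfg$outer_k, 3L)
  expect_equal(cfg$pipeline$epochs, 120L)
  expect_match(cfg$fingerprint, "^[0-9a-f]{8}$")

  writeLines('{"coh0rt": {}}', path)
  expect_error(run_config(path), "unknown config field 'coh0rt'")
  writeLines('{"cohort": ', path)
  expect_error(run_config(path), "malformed JSON")
})

test_that("simulate writes a parseable cohort, byte-identical across reruns", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  enose_simulate(small_run_cfg(), dir1)
  enose_simulate(small_run_cfg(), dir2)
  expect_identical(readLines(file.path(dir1, "measurements.csv")),
                   readLines(file.path(dir2, "measurements.csv")))
  expect_identical(readLines(file.path(dir1, "metadata.csv")),
                   readLines(file.path(dir2, "metadata.csv")))
  back <- read_measurements(file.path(dir1, "measurements.csv"),
                            file.path(dir1, "metadata.csv"))
  expect_equal(nrow(back$metadata), 24)
})

test_that("an end-to-end run writes predictions, metrics, ROC and report", {
  dir <- withr::local_tempdir()
  cv <- enose_run(small_run_cfg(), dir)
  expect_true(all(file.exists(file.path(
    dir, c("predictions.csv", "metrics.json", "roc.csv", "report.txt")
  ))))
  preds <- readr::read_csv(file.path(dir, "predictions.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(preds), 24)
  expect_named(preds, c("patient_id", "outer_fold", "predictive_value",
                        "predicted_label", "true_label"))
  metrics <- jsonlite::fromJSON(file.path(dir, "metrics.json"))
  expect_true(all(c("sensitivity", "specificity", "accuracy", "mcc", "auc",
                    "confidence_intervals", "config_fingerprint") %in%
                    names(metrics)))
  expect_equal(metrics$positive, "B")
  expect_equal(nrow(metrics$confidence_intervals), 5)
  report <- readLines(file.path(dir, "report.txt"))
  expect_true(any(grepl("Selected judge per outer fold", report)))

  # absent comparison class errors before any computation
  bad <- small_run_cfg(); bad$comparison <- c("B", "Z")
  expect_error(enose_run(bad, withr::local_tempdir()), "absent")
})

test_that("a run is reproducible end-to-end from the master seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  enose_run(small_run_cfg(seed = 5L), dir1)
  enose_run(small_run_cfg(seed = 5L), dir2)
  expect_identical(readLines(file.path(dir1, "predictions.csv")),
                   readLines(file.path(dir2, "predictions.csv")))
  expect_identical(readLines(file.path(dir1, "metrics.json")),
                   readLines(file.path(dir2, "metrics.json")))
})

test_that("stats command reproduces the baseline table from a metadata file", {
  co <- generate_cohort(cohort_config(classes = c(A = 30L, B = 15L), seed = 19))
  dir <- withr::local_tempdir()
  meta_path <- file.path(dir, "metadata.csv")
  readr::write_csv(co$metadata, meta_path)
  tab <- enose_stats(meta_path, c("A", "B"), out = file.path(dir, "stats.csv"))
  expect_equal(tab, baseline_table(co$metadata, c("A", "B")))
  expect_true(file.exists(file.path(dir, "stats.csv")))
})

test_that("tidiers and autoplots cover the main result types", {
  co <- make_small_cohort(10, 8, amplitude = 0.25, seed = 23)
  cv <- double_cross_validate(co$measurements, co$metadata,
                              outer_k = 3, inner_k = 2, seed = 2,
                              config = pipeline_config(epochs = 80))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_false(inherits(tidy(cv), "enose_cv"))
  g <- glance(cv)
  expect_named(g, c("positive", "negative", "n", "sensitivity", "specificity",
                    "accuracy", "mcc", "auc", "seed"))
  roc <- roc_curve(cv)
  expect_equal(glance(roc)$auc, as.numeric(attr(roc, "auc")))
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(roc), "ggplot")

  tensors <- measurement_tensors(co$measurements)
  fit <- hooi(tensors[[1]], c(3, 2, 2))
  expect_equal(nrow(tidy(fit)), 64 * 3 + 36 * 2 + 3 * 2)
  expect_equal(glance(fit)$method, "hooi")
  expect_named(glance(train_mlp(matrix(rnorm(40), 20, 2),
                                rep(c(-1, 1), 10), epochs = 10)),
               c("input_size", "hidden", "epochs", "learning_rate", "seed",
                 "final_loss"))
})
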