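#' Read or build a run configuration
#'
#' A run configuration bundles everything one end-to-end analysis needs:
#' either a synthetic-cohort specification or paths to measurement and
#' metadata files, the comparison pair (positive class first), the
#' pipeline search space, the fold counts, the bootstrap size and the
#' master seed. It can be given as a JSON file (the on-disk interface) or
#' as an R list with the same fields; missing fields take the documented
#' defaults.
#'
#' @param config path to a JSON file, or a list.
#' @return A `run_config` list with elements `cohort` (a [cohort_config()]
#'   or `NULL`), `files` (paths or `NULL`), `comparison`, `pipeline` (a
#'   [pipeline_config()]), `outer_k`, `inner_k`, `bootstrap_B`, `seed` and
#'   a `fingerprint` hash.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- tryCatch(
      jsonlite::fromJSON(config, simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("malformed JSON config: %s", conditionMessage(e)))
      }
    )
  }
  stopifnot(is.list(config))
  known <- c("cohort", "files", "comparison", "pipeline", "outer_k",
             "inner_k", "bootstrap_B", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config field '%s'", unknown[1]))
  }

  seed <- as.integer(config$seed %||% 1L)
  cohort <- NULL
  if (!is.null(config$cohort)) {
    cc <- config$cohort
    cohort <- cohort_config(
      classes = unlist(cc$classes %||% c(HNSCC = 100L, bladder = 40L, colon = 28L)),
      amplitude = cc$amplitude %||% 0.15,
      signature_ranks = cc$signature_ranks %||% c(1L, 1L, 1L),
      noise_cv = cc$noise_cv %||% 0.05,
      device_sdlog = cc$device_sdlog %||% 0.1,
      serial_props = cc$serial_props,
      metadata_params = cc$metadata_params,
      seed = cc$seed %||% derive_seed(seed, "cohort")
    )
  }
  pl <- config$pipeline %||% list()
  pipeline <- pipeline_config(
    scaling_options = pl$scaling_options %||% "log_baseline_ratio",
    ranks_grid = pl$ranks_grid %||% list(c(4L, 3L, 2L)),
    hidden_sizes = pl$hidden_sizes %||% c(4L, 8L),
    net_seeds = pl$net_seeds %||% c(1L, 2L),
    epochs = pl$epochs %||% 800L,
    learning_rate = pl$learning_rate %||% 0.01,
    m = pl$m %||% 8L,
    metric = pl$metric %||% "mcc"
  )
  out <- list(
    cohort = cohort,
    files = config$files,
    comparison = config$comparison,
    pipeline = pipeline,
    outer_k = as.integer(config$outer_k %||% 10L),
    inner_k = as.integer(config$inner_k %||% 5L),
    bootstrap_B = as.integer(config$bootstrap_B %||% 500L),
    seed = seed
  )
  out$fingerprint <- config_fingerprint(out)
  structure(out, class = "run_config")
}

load_cohort <- function(config) {
  if (!is.null(config$files)) {
    read_measurements(config$files$measurements, config$files$metadata)
  } else if (!is.null(config$cohort)) {
    generate_cohort(config$cohort)
  } else {
    abort("config must provide either `cohort` or `files`")
  }
}

#' Simulate a cohort and write it to measurement/metadata files
#'
#' @param config a [run_config()] (or anything it accepts) with a `cohort`
#'   entry.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths of `measurements.csv` and `metadata.csv`.
#' @export
enose_simulate <- function(config, out_dir) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(config$cohort)) abort("config has no `cohort` entry to simulate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort)
  write_measurements(
    cohort$measurements, cohort$metadata,
    file.path(out_dir, "measurements.csv"),
    file.path(out_dir, "metadata.csv")
  )
  invisible(file.path(out_dir, c("measurements.csv", "metadata.csv")))
}

#' Run the full double cross-validation analysis for one comparison
#'
#' Loads (or simulates) the cohort, runs [double_cross_validate()] for the
#' configured class pair and writes the standard outputs to `out_dir`:
#' `predictions.csv` (per-patient out-of-fold predictive values),
#' `metrics.json` (sensitivity, specificity, accuracy, MCC, AUC with
#' bootstrap confidence intervals, plus the config fingerprint and seed),
#' `roc.csv` (ROC points) and `report.txt` (human-readable summary naming
#' the selected judge per fold).
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory.
#' @param plots also write scatter and ROC figures as PNG files?
#' @return The `enose_cv` record tibble, invisibly.
#' @export
enose_run <- function(config, out_dir, plots = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(config)

  comparison <- config$comparison
  if (!is.null(comparison)) {
    comparison <- as.character(unlist(comparison))
    missing <- setdiff(comparison, unique(cohort$metadata$label))
    if (length(missing)) {
      abort(sprintf("comparison class '%s' absent from the cohort", missing[1]))
    }
  }
  cv <- double_cross_validate(
    cohort$measurements, cohort$metadata, classes = comparison,
    outer_k = config$outer_k, inner_k = config$inner_k,
    seed = config$seed, config = config$pipeline
  )
  positive <- attr(cv, "positive")

  readr::write_csv(
    dplyr::select(
      as_tibble(cv), "patient_id", "outer_fold", "predictive_value",
      "predicted_label", "true_label"
    ),
    file.path(out_dir, "predictions.csv"), progress = FALSE
  )

  cm <- confusion_metrics(cv)
  roc <- roc_curve(cv)
  cis <- lapply(
    c("sensitivity", "specificity", "accuracy", "mcc", "auc"),
    function(met) bootstrap_ci(cv, met, B = config$bootstrap_B,
                               seed = derive_seed(config$seed, met))
  )
  cis <- dplyr::bind_rows(cis)
  metrics <- list(
    positive = positive,
    negative = attr(cv, "negative"),
    n = nrow(cv),
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    accuracy = cm$accuracy, mcc = cm$mcc,
    auc = as.numeric(attr(roc, "auc")),
    confidence_intervals = cis,
    threshold = 0,
    seed = config$seed,
    config_fingerprint = config$fingerprint
  )
  jsonlite::write_json(
    metrics, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  readr::write_csv(as_tibble(roc), file.path(out_dir, "roc.csv"),
                   progress = FALSE)

  folds <- cv_fold_artifacts(cv)
  report <- c(
    sprintf("Comparison: %s (positive) vs %s", positive, attr(cv, "negative")),
    sprintf("Patients: %d; outer folds: %d; inner folds: %d; seed: %d",
            nrow(cv), config$outer_k, config$inner_k, config$seed),
    sprintf("Config fingerprint: %s", config$fingerprint),
    sprintf("Sensitivity %.3f | Specificity %.3f | Accuracy %.3f | MCC %.3f | AUC %.3f",
            cm$sensitivity, cm$specificity, cm$accuracy, cm$mcc,
            as.numeric(attr(roc, "auc"))),
    "",
    "Selected judge per outer fold:",
    vapply(seq_along(folds), function(f) {
      a <- folds[[f]]
      sprintf(
        "  fold %d: scaling %s, ranks (%s), gate %s, pos {%s}, neg {%s}, inner %s %.3f",
        f, a$scaling_name, paste(a$ranks, collapse = ","),
        a$selection$tags[a$selection$gate],
        paste(a$selection$tags[a$selection$positive], collapse = ","),
        paste(a$selection$tags[a$selection$negative], collapse = ","),
        a$selection$metric, a$selection$score
      )
    }, character(1))
  )
  writeLines(report, file.path(out_dir, "report.txt"))

  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "predictions.png"), autoplot(cv),
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "roc.png"), autoplot(roc),
                    width = 5, height = 5, dpi = 150)
  }
  invisible(cv)
}

#' Baseline-characteristics report for a class pair
#'
#' @param metadata patient metadata tibble (or a metadata CSV path).
#' @param groups length-2 character vector of class labels.
#' @param out optional path for a delimited-text report.
#' @return The [baseline_table()] tibble.
#' @export
enose_stats <- function(metadata, groups = NULL, out = NULL) {
  if (is.character(metadata)) {
    metadata <- readr::read_csv(metadata, show_col_types = FALSE,
                                progress = FALSE)
  }
  tab <- baseline_table(metadata, groups)
  if (!is.null(out)) readr::write_csv(tab, out, progress = FALSE)
  tab
}
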