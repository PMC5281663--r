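#' Pipeline configuration for the nested cross-validation search
#'
#' Defines the model-selection search space explored inside the inner
#' folds: preprocessing options, Tucker core ranks, network widths and
#' initialisation seeds, the training schedule of the candidate nets, and
#' the brute-force enumeration bound.
#'
#' @param scaling_options character vector of scaling options to search
#'   (see [fit_scaling()]).
#' @param ranks_grid list of integer triples of Tucker core ranks.
#' @param hidden_sizes,net_seeds hyperparameter grid for [build_pool()];
#'   the pool holds one net per (hidden size, seed) pair for every
#'   (scaling, ranks) configuration.
#' @param epochs,learning_rate training schedule of the candidate nets.
#' @param m brute-force enumeration bound (committees drawn from the top-`m`
#'   members; see [brute_force_select()]).
#' @param metric selection metric, `"mcc"` or `"accuracy"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scaling_options = "log_baseline_ratio",
                            ranks_grid = list(c(4L, 3L, 2L)),
                            hidden_sizes = c(4L, 8L),
                            net_seeds = c(1L, 2L),
                            epochs = 800L,
                            learning_rate = 0.01,
                            m = 8L,
                            metric = "mcc") {
  scaling_options <- vapply(
    scaling_options, function(s) match.arg(s, SCALING_OPTIONS), character(1),
    USE.NAMES = FALSE
  )
  if (!length(ranks_grid)) abort("`ranks_grid` must be non-empty")
  structure(
    list(
      scaling_options = scaling_options,
      ranks_grid = lapply(ranks_grid, as.integer),
      hidden_sizes = as.integer(hidden_sizes),
      net_seeds = as.integer(net_seeds),
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      m = as.integer(m),
      metric = match.arg(metric, c("mcc", "accuracy"))
    ),
    class = "pipeline_config"
  )
}

#' Stratified cross-validation folds
#'
#' Samples are shuffled within class (seeded) and dealt to folds in
#' rotation, so class proportions are as balanced as the counts allow and
#' the assignment depends only on labels and the seed, never on the
#' measurements.
#'
#' @param labels class label per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    missing <- setdiff(unique(labels), unique(labels[fold != f]))
    if (length(missing)) {
      abort(sprintf(
        "class '%s' is absent from the training part of fold %d; use a smaller k",
        missing[1], f
      ))
    }
  }
  fold
}

# center/scale features on training rows only; zero-variance columns are
# left unscaled
fit_feature_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_feature_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

# fit scaling + compressor + feature scaler on training tensors and return
# standardized feature matrices for arbitrary index sets
fit_feature_pipeline <- function(tensors, train_ids, scaling_name, ranks) {
  sc <- fit_scaling(tensors[train_ids], scaling_name)
  scaled_train <- lapply(tensors[train_ids], function(t) apply_scaling(sc, t))
  comp <- fit_compressor(scaled_train, ranks)
  feats_train <- t(vapply(
    scaled_train, function(t) compress(comp, t), numeric(prod(comp$ranks))
  ))
  fs <- fit_feature_scaler(feats_train)
  list(
    scaling = sc, compressor = comp, feature_scaler = fs,
    transform = function(ids) {
      f <- t(vapply(
        tensors[ids],
        function(t) compress(comp, apply_scaling(sc, t)),
        numeric(prod(comp$ranks))
      ))
      apply_feature_scaler(fs, f)
    }
  )
}

#' Double (nested) cross-validation of the full pipeline
#'
#' The outer loop estimates how the finished classifier generalises to
#' future breath samples; the inner loop performs every piece of model
#' selection. For each outer fold, and for every (scaling, ranks)
#' configuration in the search grid: preprocessing, Tucker compressor,
#' feature standardisation and the candidate-network pool are fitted on
#' inner-training data only, each pool member's out-of-fold predictive
#' values are collected over the inner folds, and [brute_force_select()]
#' picks the best judge assembly by mean inner-fold score. The winning
#' configuration is refitted on the whole outer-training fold and scores
#' the held-out outer-test samples exactly once, so every patient receives
#' one out-of-fold predictive value.
#'
#' @param measurements long-format measurement tibble.
#' @param metadata patient metadata tibble.
#' @param classes length-2 character vector `(positive, negative)`. If
#'   `NULL` the two classes present are used with the smaller one as the
#'   positive class (the convention used for the reported sensitivities).
#' @param outer_k,inner_k fold counts of the outer and inner loops.
#' @param seed master seed; every stochastic choice (fold assignments) is
#'   derived from it via [derive_seed()].
#' @param config a [pipeline_config()].
#' @return An `enose_cv` tibble of prediction records — `patient_id`,
#'   `true_label`, `predictive_value`, `outer_fold`, `predicted_label`
#'   (threshold 0) — with the per-fold fitted artifacts attached (see
#'   [cv_fold_artifacts()]).
#' @export
double_cross_validate <- function(measurements, metadata, classes = NULL,
                                  outer_k = 10L, inner_k = 5L, seed = 1L,
                                  config = pipeline_config()) {
  validate_measurements(measurements, metadata)
  stopifnot(inherits(config, "pipeline_config"))

  if (is.null(classes)) {
    present <- sort(unique(metadata$label))
    if (length(present) != 2L) {
      abort("`classes` must be given when the cohort has more than two classes")
    }
    counts <- table(metadata$label)
    classes <- names(sort(counts)) # smaller class first -> positive
  }
  positive <- classes[1]
  negative <- classes[2]
  keep <- metadata$label %in% c(positive, negative)
  if (!any(metadata$label == positive) || !any(metadata$label == negative)) {
    abort(sprintf("classes '%s'/'%s' not both present", positive, negative))
  }
  metadata <- metadata[keep, , drop = FALSE]
  measurements <- measurements[measurements$patient_id %in% metadata$patient_id, ,
                               drop = FALSE]
  tensors <- measurement_tensors(measurements)
  tensors <- tensors[metadata$patient_id]
  y <- ifelse(metadata$label == positive, 1, -1)
  n <- length(y)

  outer_fold <- make_stratified_folds(
    metadata$label, outer_k, derive_seed(seed, "outer_folds")
  )
  grid <- expand.grid(
    scaling = config$scaling_options,
    ranks_i = seq_along(config$ranks_grid),
    stringsAsFactors = FALSE
  )

  value <- numeric(n)
  artifacts <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    train_idx <- which(outer_fold != f)
    test_idx <- which(outer_fold == f)
    inner_fold <- make_stratified_folds(
      metadata$label[train_idx], inner_k, derive_seed(seed, "inner_folds", f)
    )

    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      scaling_name <- grid$scaling[gi]
      ranks <- config$ranks_grid[[grid$ranks_i[gi]]]
      n_pool <- length(config$hidden_sizes) * length(config$net_seeds)
      oof <- matrix(NA_real_, length(train_idx), n_pool)
      for (j in seq_len(inner_k)) {
        it_train <- train_idx[inner_fold != j]
        it_test <- train_idx[inner_fold == j]
        fp <- fit_feature_pipeline(tensors, names(tensors)[it_train],
                                   scaling_name, ranks)
        pool <- build_pool(
          fp$transform(names(tensors)[it_train]), y[it_train],
          hidden_sizes = config$hidden_sizes, seeds = config$net_seeds,
          epochs = config$epochs, learning_rate = config$learning_rate
        )
        pred <- pool_predict(pool, fp$transform(names(tensors)[it_test]))
        oof[match(it_test, train_idx), ] <- pred
        colnames(oof) <- colnames(pred)
      }
      sel <- brute_force_select(
        oof, y[train_idx], folds = inner_fold, m = config$m,
        metric = config$metric
      )
      if (is.null(best) || sel$score > best$selection$score) {
        best <- list(scaling_name = scaling_name, ranks = ranks, selection = sel)
      }
    }

    fp <- fit_feature_pipeline(tensors, names(tensors)[train_idx],
                               best$scaling_name, best$ranks)
    pool <- build_pool(
      fp$transform(names(tensors)[train_idx]), y[train_idx],
      hidden_sizes = config$hidden_sizes, seeds = config$net_seeds,
      epochs = config$epochs, learning_rate = config$learning_rate
    )
    judge <- assemble_judge(
      pool, best$selection,
      provenance = list(scaling = best$scaling_name, ranks = best$ranks)
    )
    value[test_idx] <- judge_predict(judge, fp$transform(names(tensors)[test_idx]))
    artifacts[[f]] <- list(
      scaling = fp$scaling, compressor = fp$compressor,
      feature_scaler = fp$feature_scaler, pool = pool,
      selection = best$selection, judge = judge,
      scaling_name = best$scaling_name, ranks = best$ranks
    )
  }

  records <- tibble(
    patient_id = metadata$patient_id,
    true_label = metadata$label,
    predictive_value = value,
    outer_fold = outer_fold,
    predicted_label = classify(value, positive = positive, negative = negative)
  )
  structure(
    records,
    class = c("enose_cv", class(records)),
    folds = artifacts,
    positive = positive,
    negative = negative,
    seed = seed,
    outer_k = outer_k,
    inner_k = inner_k,
    config = config
  )
}

#' Per-fold fitted artifacts of a double cross-validation run
#'
#' Each element holds the outer fold's fitted scaling option, Tucker
#' compressor, feature scaler, refitted network pool, brute-force selection
#' and assembled judge — everything fitted on that fold's training data.
#'
#' @param x an `enose_cv` object.
#' @return A list with one element per outer fold.
#' @export
cv_fold_artifacts <- function(x) {
  stopifnot(inherits(x, "enose_cv"))
  attr(x, "folds")
}

#' Threshold classification of predictive values
#'
#' Predictive values at or above the threshold (default 0.00, the natural
#' boundary of the tanh output) are called positive; ties go to the
#' positive class.
#'
#' @param value numeric vector of predictive values in \[-1, 1\].
#' @param threshold decision cutoff.
#' @param positive,negative class names to return.
#' @return Character vector of predicted labels.
#' @export
classify <- function(value, threshold = 0, positive = "positive",
                     negative = "negative") {
  ifelse(value >= threshold, positive, negative)
}

#' Confusion counts and threshold metrics of prediction records
#'
#' Computes TP/FP/TN/FN at the given threshold and the derived
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n and
#' Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with MCC defined
#' as 0 whenever a denominator factor vanishes.
#'
#' @param records tibble with columns `true_label` and `predictive_value`
#'   (e.g. the output of [double_cross_validate()]).
#' @param positive name of the positive class; defaults to the `enose_cv`
#'   attribute when present.
#' @param threshold decision cutoff (default 0).
#' @return A one-row tibble: counts, the four metrics, threshold and
#'   positive class.
#' @export
confusion_metrics <- function(records, positive = NULL, threshold = 0) {
  positive <- positive %||% attr(records, "positive")
  if (is.null(positive)) abort("`positive` class must be given")
  truth <- records$true_label
  if (!any(truth == positive) || all(truth == positive)) {
    abort("both classes must be present in the records")
  }
  pred_pos <- records$predictive_value >= threshold
  is_pos <- truth == positive
  tp <- sum(pred_pos & is_pos)
  fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(truth),
    mcc = mcc,
    threshold = threshold,
    positive = positive
  )
}

#' Receiver operating characteristic curve of prediction records
#'
#' Sweeps the decision threshold over the distinct predictive values
#' (ties grouped), returning the (false-positive rate, true-positive rate)
#' staircase from (0,0) to (1,1) and its trapezoidal area.
#'
#' @inheritParams confusion_metrics
#' @return An `enose_roc` tibble with columns `threshold`, `fpr`, `tpr`;
#'   the area under the curve is in `attr(, "auc")` and in [glance()].
#' @export
roc_curve <- function(records, positive = NULL) {
  positive <- positive %||% attr(records, "positive")
  if (is.null(positive)) abort("`positive` class must be given")
  truth <- records$true_label == positive
  if (!any(truth) || all(truth)) abort("both classes must be present")
  value <- records$predictive_value
  thresholds <- c(Inf, sort(unique(value), decreasing = TRUE))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  tpr <- vapply(thresholds, function(t) sum(value >= t & truth) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(value >= t & !truth) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  out <- tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  structure(
    out,
    class = c("enose_roc", class(out)),
    auc = auc, positive = positive
  )
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Patients are resampled with replacement within class (stratified), the
#' metric is recomputed on each resample and the percentile interval is
#' returned. A degenerate resample (metric undefined) is redrawn, up to a
#' redraw cap.
#'
#' @inheritParams confusion_metrics
#' @param metric one of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"mcc"`, `"auc"`.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return A one-row tibble: metric name, point estimate, lower and upper
#'   bounds, `level` and `B`.
#' @export
bootstrap_ci <- function(records, metric = "accuracy", B = 1000L, seed = 1L,
                         level = 0.95, positive = NULL, threshold = 0) {
  metric <- match.arg(
    metric, c("accuracy", "sensitivity", "specificity", "mcc", "auc")
  )
  stopifnot(B >= 100)
  positive <- positive %||% attr(records, "positive")
  if (is.null(positive)) abort("`positive` class must be given")

  eval_metric <- function(rec) {
    if (metric == "auc") {
      as.numeric(attr(roc_curve(rec, positive), "auc"))
    } else {
      confusion_metrics(rec, positive, threshold)[[metric]]
    }
  }
  point <- eval_metric(records)

  idx_by_class <- split(seq_len(nrow(records)), records$true_label == positive)
  set.seed(derive_seed(seed, "bootstrap"))
  stats_boot <- numeric(B)
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in seq_len(100L)) {
      idx <- unlist(lapply(idx_by_class, function(i) {
        i[sample.int(length(i), replace = TRUE)]
      }), use.names = FALSE)
      val <- tryCatch(eval_metric(records[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val)) abort("bootstrap resampling kept producing degenerate samples")
    stats_boot[b] <- val
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha)))
  tibble(
    metric = metric, estimate = point, lower = ci[1], upper = ci[2],
    level = level, B = as.integer(B)
  )
}
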