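random_records <- function(n, seed, positive = "case", negative = "control") {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("R%03d", seq_len(n)),
    true_label = sample(c(positive, negative), n, replace = TRUE,
                        prob = c(0.4, 0.6)),
    predictive_value = round(runif(n, -1, 1), 2) # rounding forces ties
  )
}

test_that("threshold classification calls >= threshold positive, ties included", {
  expect_equal(classify(0.3), "positive")
  expect_equal(classify(-0.2), "negative")
  expect_equal(classify(0.0), "positive")
  expect_equal(classify(c(-1, 0, 1), positive = "colon", negative = "HNSCC"),
               c("HNSCC", "colon", "colon"))
})

test_that("confusion metrics reproduce the stated formulas on a fixed table", {
  # 22/6/81/19 confusion table: sens 22/28, spec 81/100, acc 103/128,
  # MCC = (22*81 - 19*6)/sqrt(41*28*100*87) = 0.52785...
  rec <- tibble::tibble(
    true_label = c(rep("case", 28), rep("control", 100)),
    predictive_value = c(rep(0.5, 22), rep(-0.5, 6), rep(-0.5, 81), rep(0.5, 19))
  )
  cm <- confusion_metrics(rec, positive = "case")
  expect_equal(cm$tp, 22); expect_equal(cm$fn, 6)
  expect_equal(cm$tn, 81); expect_equal(cm$fp, 19)
  expect_equal(cm$sensitivity, 22 / 28)
  expect_equal(cm$specificity, 0.81)
  expect_equal(cm$accuracy, 103 / 128)
  expect_equal(cm$mcc, (22 * 81 - 19 * 6) / sqrt(41 * 28 * 100 * 87))

  perfect <- tibble::tibble(
    true_label = rep(c("case", "control"), each = 5),
    predictive_value = rep(c(0.9, -0.9), each = 5)
  )
  cmp <- confusion_metrics(perfect, positive = "case")
  expect_equal(unlist(cmp[c("sensitivity", "specificity", "accuracy", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, mcc = 1))

  all_pos <- perfect
  all_pos$predictive_value <- abs(all_pos$predictive_value)
  expect_equal(confusion_metrics(all_pos, positive = "case")$mcc, 0)

  expect_error(confusion_metrics(perfect[1:5, ], positive = "case"),
               "both classes")
})

test_that("confusion counts match the counting oracle on random record sets", {
  for (seed in 1:25) {
    rec <- random_records(40, seed)
    cm <- confusion_metrics(rec, positive = "case")
    oc <- oracle_confusion(rec$true_label, rec$predictive_value, "case")
    expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn),
                     c(oc$tp, oc$fp, oc$tn, oc$fn))
    expect_equal(cm$mcc, oc$mcc)
  }
})

test_that("ROC curves are monotone staircases whose AUC matches pair counting", {
  sep <- tibble::tibble(
    true_label = rep(c("case", "control"), each = 4),
    predictive_value = c(0.5, 0.6, 0.7, 0.8, -0.5, -0.6, -0.7, -0.8)
  )
  expect_equal(as.numeric(attr(roc_curve(sep, "case"), "auc")), 1)

  flat <- sep
  flat$predictive_value <- rep(0.2, 8)
  expect_equal(as.numeric(attr(roc_curve(flat, "case"), "auc")), 0.5)

  for (seed in 1:25) {
    rec <- random_records(30, seed)
    roc <- roc_curve(rec, positive = "case")
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_equal(as.numeric(attr(roc, "auc")),
                 oracle_auc(rec$true_label, rec$predictive_value, "case"),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  rec <- random_records(40, 99)
  auc0 <- as.numeric(attr(roc_curve(rec, "case"), "auc"))
  rec2 <- rec
  rec2$predictive_value <- tanh(3 * rec$predictive_value + 0.2)
  expect_equal(as.numeric(attr(roc_curve(rec2, "case"), "auc")), auc0)
})

test_that("AUC agrees with pROC on random record sets", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    rec <- random_records(50, seed)
    auc_prc <- as.numeric(pROC::auc(pROC::roc(
      response = rec$true_label == "case",
      predictor = rec$predictive_value, quiet = TRUE, direction = "<"
    )))
    expect_equal(as.numeric(attr(roc_curve(rec, "case"), "auc")), auc_prc,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are deterministic, bounded and degenerate-safe", {
  rec <- random_records(60, 3)
  ci1 <- bootstrap_ci(rec, "mcc", B = 200, seed = 4, positive = "case")
  ci2 <- bootstrap_ci(rec, "mcc", B = 200, seed = 4, positive = "case")
  expect_identical(ci1, ci2)
  expect_gte(ci1$lower, -1); expect_lte(ci1$upper, 1)
  expect_lte(ci1$lower, ci1$upper)

  perfect <- tibble::tibble(
    true_label = rep(c("case", "control"), each = 10),
    predictive_value = rep(c(0.9, -0.9), each = 10)
  )
  ci <- bootstrap_ci(perfect, "accuracy", B = 100, seed = 1, positive = "case")
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
})

test_that("stratified folds partition samples and keep classes in training parts", {
  labels <- rep(c("a", "b"), c(30, 12))
  fold <- make_stratified_folds(labels, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 42)
  for (f in 1:5) {
    expect_setequal(unique(labels[fold != f]), c("a", "b"))
  }
  # a singleton class cannot survive the training-fold check
  expect_error(make_stratified_folds(c("a", rep("b", 10)), 3, seed = 1),
               "smaller k")
})

test_that("double CV yields one record per patient and honours error contracts", {
  co <- make_small_cohort(16, 10, amplitude = 0.2, seed = 41)
  cfg <- pipeline_config(epochs = 150)
  cv <- double_cross_validate(co$measurements, co$metadata,
                              outer_k = 4, inner_k = 2, seed = 8, config = cfg)
  expect_s3_class(cv, "enose_cv")
  expect_equal(sort(cv$patient_id), sort(co$metadata$patient_id))
  expect_equal(anyDuplicated(cv$patient_id), 0L)
  expect_true(all(cv$predictive_value >= -1 & cv$predictive_value <= 1))
  expect_equal(cv$predicted_label,
               ifelse(cv$predictive_value >= 0, "B", "A")) # B smaller -> positive
  expect_length(cv_fold_artifacts(cv), 4)

  # duplicated patient ids are rejected
  dup_meta <- co$metadata
  dup_meta$patient_id[2] <- dup_meta$patient_id[1]
  expect_error(
    double_cross_validate(co$measurements, dup_meta, outer_k = 3,
                          inner_k = 2, seed = 8, config = cfg),
    "duplicate|metadata"
  )

  # rerun with the same master seed reproduces the records exactly
  cv2 <- double_cross_validate(co$measurements, co$metadata,
                               outer_k = 4, inner_k = 2, seed = 8, config = cfg)
  expect_equal(tidy(cv), tidy(cv2), tolerance = 0)
})

test_that("perturbing an outer-test tensor never touches its fold's fitted artifacts", {
  co <- make_small_cohort(16, 10, amplitude = 0.2, seed = 42)
  cfg <- pipeline_config(epochs = 150)
  cv <- double_cross_validate(co$measurements, co$metadata,
                              outer_k = 4, inner_k = 2, seed = 9, config = cfg)

  victim <- cv$patient_id[1]
  fold <- cv$outer_fold[cv$patient_id == victim]
  meas2 <- co$measurements
  sel <- meas2$patient_id == victim
  meas2$conductivity[sel] <- meas2$conductivity[sel] * 1e6
  cv2 <- double_cross_validate(meas2, co$metadata,
                               outer_k = 4, inner_k = 2, seed = 9, config = cfg)

  # the fold that held the victim out: artifacts bit-identical
  a1 <- cv_fold_artifacts(cv)[[fold]]
  a2 <- cv_fold_artifacts(cv2)[[fold]]
  expect_identical(a1, a2)
  # co-records of that fold (other patients) unchanged
  same_fold <- cv$outer_fold == fold & cv$patient_id != victim
  expect_identical(cv$predictive_value[same_fold], cv2$predictive_value[same_fold])
})

test_that("pipeline recovers a strong class signal on a small cohort", {
  co <- make_small_cohort(16, 10, amplitude = 0.25, seed = 43)
  cv <- double_cross_validate(co$measurements, co$metadata,
                              outer_k = 4, inner_k = 2, seed = 10,
                              config = pipeline_config(epochs = 200))
  g <- glance(cv)
  expect_gte(g$accuracy, 0.85)
  expect_gte(g$auc, 0.9)
})

test_that("average AUC rises with the class-effect amplitude", {
  auc_at <- function(amplitude, seed) {
    co <- make_small_cohort(14, 10, amplitude = amplitude, seed = seed)
    cv <- double_cross_validate(co$measurements, co$metadata,
                                outer_k = 3, inner_k = 2, seed = seed,
                                config = pipeline_config(epochs = 120))
    glance(cv)$auc
  }
  seeds <- c(51, 52)
  expect_gt(mean(vapply(seeds, function(s) auc_at(0.25, s), numeric(1))),
            mean(vapply(seeds, function(s) auc_at(0, s), numeric(1))))
})
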