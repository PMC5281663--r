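#' Tidy the factor loadings of a Tucker model
#'
#' @param x a `tucker_model` or `tucker_compressor`.
#' @param ... unused.
#' @return A tibble with one row per (mode, index, component) loading.
#' @export
tidy.tucker_model <- function(x, ...) {
  mode_names <- c("step", "cycle", "sensor")
  purrr::map_dfr(1:3, function(m) {
    u <- x$factors[[m]]
    tibble(
      mode = mode_names[m],
      index = rep(seq_len(nrow(u)) - 1L, ncol(u)),
      component = rep(seq_len(ncol(u)), each = nrow(u)),
      loading = as.vector(u)
    )
  })
}

#' @rdname tidy.tucker_model
#' @export
tidy.tucker_compressor <- tidy.tucker_model

#' One-row fit summary of a Tucker model
#'
#' @param x a `tucker_model`.
#' @param ... unused.
#' @return A one-row tibble: ranks, relative reconstruction error,
#'   iterations, convergence flag and method.
#' @export
glance.tucker_model <- function(x, ...) {
  tibble(
    r1 = x$ranks[1], r2 = x$ranks[2], r3 = x$ranks[3],
    rel_error = x$rel_error, iterations = x$iterations,
    converged = x$converged, method = x$method
  )
}

#' @rdname glance.tucker_model
#' @export
glance.tucker_compressor <- function(x, ...) {
  tibble(
    r1 = x$ranks[1], r2 = x$ranks[2], r3 = x$ranks[3],
    rel_error = x$rel_error, iterations = x$iterations,
    n_train = x$n_train
  )
}

#' One-row training summary of a fitted network
#'
#' @param x an `mlp_model`.
#' @param ... unused.
#' @return A one-row tibble of architecture, training schedule, seed and
#'   final loss.
#' @export
glance.mlp_model <- function(x, ...) {
  tibble(
    input_size = x$input_size, hidden = x$hidden, epochs = x$epochs,
    learning_rate = x$learning_rate, seed = x$seed, final_loss = x$final_loss
  )
}

#' Prediction records of a cross-validation run as a plain tibble
#'
#' @param x an `enose_cv` object.
#' @param ... unused.
#' @return The per-patient record tibble without the attached artifacts.
#' @export
tidy.enose_cv <- function(x, ...) {
  as_tibble(unclass_enose(x))
}

#' One-row performance summary of a cross-validation run
#'
#' @param x an `enose_cv` object.
#' @param ... unused.
#' @return A one-row tibble: comparison, n, threshold-0 sensitivity,
#'   specificity, accuracy, MCC, and ROC AUC.
#' @export
glance.enose_cv <- function(x, ...) {
  cm <- confusion_metrics(x)
  tibble(
    positive = attr(x, "positive"),
    negative = attr(x, "negative"),
    n = nrow(x),
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    accuracy = cm$accuracy,
    mcc = cm$mcc,
    auc = as.numeric(attr(roc_curve(x), "auc")),
    seed = attr(x, "seed")
  )
}

#' @rdname tidy.enose_cv
#' @export
tidy.enose_roc <- function(x, ...) {
  as_tibble(unclass_enose(x))
}

#' @rdname glance.enose_cv
#' @export
glance.enose_roc <- function(x, ...) {
  tibble(
    auc = as.numeric(attr(x, "auc")),
    positive = attr(x, "positive"),
    n_points = nrow(x)
  )
}

unclass_enose <- function(x) {
  out <- x
  class(out) <- setdiff(class(out), c("enose_cv", "enose_roc"))
  for (a in c("folds", "positive", "negative", "seed", "outer_k", "inner_k",
              "config", "auc")) {
    attr(out, a) <- NULL
  }
  out
}
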