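#' Fit a preprocessing (scaling) option on training measurements
#'
#' Five scaling options define the preprocessing search space applied to a
#' raw conductivity tensor before Tucker compression:
#'
#' * `none` — identity.
#' * `baseline_ratio` — each sensor's trace is divided by that sensor's mean
#'   conductivity over the first cycle (cycle 0) of the same measurement,
#'   removing per-measurement and per-device multiplicative level.
#' * `log_baseline_ratio` — natural log of the baseline ratio (the default
#'   downstream: log-conductance ratios are the usual response measure for
#'   metal-oxide sensors).
#' * `per_sensor_zscore` — each sensor channel centred and scaled by that
#'   sensor's mean and standard deviation pooled over the *training*
#'   measurements only.
#' * `per_measurement_minmax` — affine map of each measurement's tensor onto
#'   \[0, 1\].
#'
#' Only `per_sensor_zscore` has fitted parameters; the other options are
#' measurement-local, but all go through the same fit/apply interface so the
#' caller can guarantee that preprocessing never sees test data.
#'
#' @param tensors list of 64 x 36 x 3 training arrays.
#' @param option one of `"none"`, `"baseline_ratio"`, `"log_baseline_ratio"`,
#'   `"per_sensor_zscore"`, `"per_measurement_minmax"`.
#' @return An object of class `scaling_option`.
#' @seealso [apply_scaling()]
#' @export
fit_scaling <- function(tensors, option = "log_baseline_ratio") {
  option <- match.arg(option, SCALING_OPTIONS)
  params <- list()
  if (option == "per_sensor_zscore") {
    if (!length(tensors)) abort("per_sensor_zscore needs training tensors")
    lapply(tensors, check_tensor)
    by_sensor <- vapply(
      seq_len(MEAS_DIM[["sensor"]]),
      function(s) {
        vals <- unlist(lapply(tensors, function(t) t[, , s]), use.names = FALSE)
        c(mean(vals), stats::sd(vals))
      },
      numeric(2)
    )
    if (any(by_sensor[2, ] == 0)) {
      abort(sprintf(
        "zero training variance for sensor %d; cannot z-score",
        which(by_sensor[2, ] == 0)[1] - 1L
      ))
    }
    params <- list(mean = by_sensor[1, ], sd = by_sensor[2, ])
  }
  structure(list(option = option, params = params), class = "scaling_option")
}

#' Apply a fitted scaling option to one measurement tensor
#'
#' @param scaling a `scaling_option` from [fit_scaling()].
#' @param tensor a 64 x 36 x 3 array of strictly positive conductivities.
#' @return The preprocessed 64 x 36 x 3 array.
#' @export
apply_scaling <- function(scaling, tensor) {
  stopifnot(inherits(scaling, "scaling_option"))
  check_tensor(tensor)
  switch(scaling$option,
    none = tensor,
    baseline_ratio = baseline_ratio(tensor),
    log_baseline_ratio = {
      ratio <- baseline_ratio(tensor)
      if (any(ratio <= 0)) {
        abort("log_baseline_ratio requires strictly positive baseline ratios")
      }
      log(ratio)
    },
    per_sensor_zscore = {
      out <- tensor
      for (s in seq_len(MEAS_DIM[["sensor"]])) {
        out[, , s] <- (tensor[, , s] - scaling$params$mean[s]) /
          scaling$params$sd[s]
      }
      out
    },
    per_measurement_minmax = {
      rng <- range(tensor)
      if (rng[1] == rng[2]) abort("constant tensor cannot be min-max scaled")
      (tensor - rng[1]) / (rng[2] - rng[1])
    }
  )
}

baseline_ratio <- function(tensor) {
  out <- tensor
  for (s in seq_len(MEAS_DIM[["sensor"]])) {
    baseline <- mean(tensor[, 1, s])
    if (baseline == 0) {
      abort(sprintf("zero baseline (cycle 0) mean for sensor %d", s - 1L))
    }
    out[, , s] <- tensor[, , s] / baseline
  }
  out
}
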