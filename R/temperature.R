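#' Sensor temperature schedule of one measurement cycle
#'
#' The micro-hotplate sensors are cycled between 260 and 340 degrees Celsius
#' in 32 evenly spaced steps, then cooled back along the mirrored sequence,
#' so one cycle visits 64 temperature values. Only the endpoints and step
#' count are fixed by the instrument protocol; the schedule is taken as
#' evenly spaced between them.
#'
#' @return A tibble with columns `step` (0-based index, 0-63), `temperature`
#'   (degrees Celsius) and `phase` (`"heating"` or `"cooling"`).
#' @examples
#' sched <- make_temperature_schedule()
#' range(sched$temperature) # 260 340
#' @export
make_temperature_schedule <- function() {
  ascending <- seq(260, 340, length.out = 32L)
  temps <- c(ascending, rev(ascending))
  tibble(
    step = 0:63,
    temperature = temps,
    phase = rep(c("heating", "cooling"), each = 32L)
  )
}
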