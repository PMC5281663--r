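#' Validate a long-format measurement table and its patient metadata
#'
#' A cohort is carried as two tibbles. `measurements` is long format with one
#' row per conductivity reading: columns `patient_id`, `cycle` (0-35), `step`
#' (0-63), `sensor` (0-2) and `conductivity` (arbitrary conductance units,
#' strictly positive before preprocessing). `metadata` has one row per
#' patient: `patient_id`, `label`, `device_serial` (one of 259, 309, 315,
#' 362, 379), `age`, `sex`, `food_intake_lt4h`, `currently_smoking`,
#' `pack_years`, `tumor_stage`.
#'
#' Every patient must contribute exactly one reading per (cycle, step,
#' sensor) cell — 64 x 36 x 3 = 6912 readings; missing or duplicated cells,
#' unknown device serials and non-positive or non-finite conductivities are
#' rejected with a message naming the offending patient and index.
#'
#' @param measurements long-format measurement tibble.
#' @param metadata patient metadata tibble.
#' @return Invisibly, a list with the two validated tibbles.
#' @export
validate_measurements <- function(measurements, metadata) {
  need_m <- c("patient_id", "cycle", "step", "sensor", "conductivity")
  if (!all(need_m %in% names(measurements))) {
    abort(sprintf(
      "measurement table must have columns %s",
      paste(need_m, collapse = ", ")
    ))
  }
  need_d <- c("patient_id", "label", "device_serial")
  if (!all(need_d %in% names(metadata))) {
    abort(sprintf(
      "metadata table must have columns %s",
      paste(need_d, collapse = ", ")
    ))
  }
  if (anyDuplicated(metadata$patient_id)) {
    dup <- metadata$patient_id[duplicated(metadata$patient_id)][1]
    abort(sprintf("duplicate patient_id in metadata: '%s'", dup))
  }
  bad_serial <- setdiff(unique(metadata$device_serial), DEVICE_SERIALS)
  if (length(bad_serial)) {
    pid <- metadata$patient_id[match(bad_serial[1], metadata$device_serial)]
    abort(sprintf(
      "unknown device serial %s for patient '%s' (known: %s)",
      bad_serial[1], pid, paste(DEVICE_SERIALS, collapse = ", ")
    ))
  }
  only_meas <- setdiff(unique(measurements$patient_id), metadata$patient_id)
  only_meta <- setdiff(metadata$patient_id, measurements$patient_id)
  if (length(only_meas)) {
    abort(sprintf("patient '%s' has measurements but no metadata", only_meas[1]))
  }
  if (length(only_meta)) {
    abort(sprintf("patient '%s' has metadata but no measurements", only_meta[1]))
  }

  bad_idx <- !(measurements$cycle %in% 0:35) | !(measurements$step %in% 0:63) |
    !(measurements$sensor %in% 0:2)
  if (any(bad_idx)) {
    i <- which(bad_idx)[1]
    abort(sprintf(
      "out-of-range index for patient '%s' (cycle %s, step %s, sensor %s)",
      measurements$patient_id[i], measurements$cycle[i],
      measurements$step[i], measurements$sensor[i]
    ))
  }
  bad_val <- !is.finite(measurements$conductivity) | measurements$conductivity <= 0
  if (any(bad_val)) {
    i <- which(bad_val)[1]
    abort(sprintf(
      "non-positive or non-finite conductivity for patient '%s' (cycle %d, step %d, sensor %d)",
      measurements$patient_id[i], measurements$cycle[i],
      measurements$step[i], measurements$sensor[i]
    ))
  }

  # completeness: each patient covers every (cycle, step, sensor) exactly once
  cell <- cell_index(measurements$step, measurements$cycle, measurements$sensor)
  n_cells <- prod(MEAS_DIM)
  by_patient <- split(cell, measurements$patient_id)
  for (pid in names(by_patient)) {
    cells <- by_patient[[pid]]
    if (anyDuplicated(cells)) {
      i <- cells[duplicated(cells)][1]
      abort(sprintf(
        "duplicate cell for patient '%s': %s", pid, describe_cell(i)
      ))
    }
    if (length(cells) != n_cells) {
      missing <- setdiff(seq_len(n_cells), cells)[1]
      abort(sprintf(
        "patient '%s' has %d of %d cells; first missing cell: %s",
        pid, length(cells), n_cells, describe_cell(missing)
      ))
    }
  }
  invisible(list(measurements = measurements, metadata = metadata))
}

# 1-based linear index into the (step, cycle, sensor) array from 0-based
# file indices
cell_index <- function(step, cycle, sensor) {
  1L + step + MEAS_DIM[["step"]] * (cycle + MEAS_DIM[["cycle"]] * sensor)
}

describe_cell <- function(i) {
  i0 <- i - 1L
  step <- i0 %% MEAS_DIM[["step"]]
  rest <- i0 %/% MEAS_DIM[["step"]]
  cycle <- rest %% MEAS_DIM[["cycle"]]
  sensor <- rest %/% MEAS_DIM[["cycle"]]
  sprintf("(cycle %d, step %d, sensor %d)", cycle, step, sensor)
}

#' Convert a long measurement table to per-patient 3-way arrays
#'
#' @param measurements long-format measurement tibble (see
#'   [validate_measurements()]).
#' @return A named list (by `patient_id`) of 64 x 36 x 3 arrays with
#'   dimensions (temperature step, cycle, sensor).
#' @export
measurement_tensors <- function(measurements) {
  idx <- cell_index(measurements$step, measurements$cycle, measurements$sensor)
  # ordering by cell index within patient makes the vector fill the array
  # in (step, cycle, sensor) order
  ord <- order(measurements$patient_id, idx)
  by_patient <- split(measurements$conductivity[ord], measurements$patient_id[ord])
  lapply(by_patient, function(v) array(v, dim = unname(MEAS_DIM)))
}

#' Convert per-patient arrays back to a long measurement table
#'
#' @param tensors named list of 64 x 36 x 3 arrays.
#' @return A long-format measurement tibble ordered by patient, sensor,
#'   cycle, step.
#' @export
tensors_to_measurements <- function(tensors) {
  stopifnot(is.list(tensors), !is.null(names(tensors)))
  n_cells <- prod(MEAS_DIM)
  grid <- expand.grid(
    step = 0:(MEAS_DIM[["step"]] - 1L),
    cycle = 0:(MEAS_DIM[["cycle"]] - 1L),
    sensor = 0:(MEAS_DIM[["sensor"]] - 1L)
  )
  tibble(
    patient_id = rep(names(tensors), each = n_cells),
    cycle = rep(grid$cycle, times = length(tensors)),
    step = rep(grid$step, times = length(tensors)),
    sensor = rep(grid$sensor, times = length(tensors)),
    conductivity = unlist(lapply(tensors, as.vector), use.names = FALSE)
  )
}

#' Read a measurement file and metadata file
#'
#' Both files are plain comma-delimited text in the layout documented in
#' [validate_measurements()]. The pair is validated and joined on
#' `patient_id` before being returned.
#'
#' @param path path to the measurement CSV.
#' @param metadata_path path to the metadata CSV.
#' @return A list with elements `measurements` and `metadata` (tibbles).
#' @export
read_measurements <- function(path, metadata_path) {
  measurements <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      cycle = readr::col_integer(),
      step = readr::col_integer(),
      sensor = readr::col_integer(),
      conductivity = readr::col_double()
    ),
    progress = FALSE
  )
  metadata <- readr::read_csv(
    metadata_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      label = readr::col_character(),
      device_serial = readr::col_integer(),
      age = readr::col_double(),
      sex = readr::col_character(),
      food_intake_lt4h = readr::col_logical(),
      currently_smoking = readr::col_logical(),
      pack_years = readr::col_double(),
      tumor_stage = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_measurements(measurements, metadata)
  list(measurements = measurements, metadata = metadata)
}

#' Write a cohort to measurement and metadata files
#'
#' Values are written as decimal text at full double precision, so a
#' write-then-read round trip reproduces every conductivity to better than
#' nine significant digits and every metadata field exactly.
#'
#' @param measurements long-format measurement tibble.
#' @param metadata patient metadata tibble.
#' @param path measurement CSV path.
#' @param metadata_path metadata CSV path.
#' @return Invisibly, the two paths.
#' @export
write_measurements <- function(measurements, metadata, path, metadata_path) {
  readr::write_csv(measurements, path, progress = FALSE)
  readr::write_csv(metadata, metadata_path, progress = FALSE)
  invisible(c(path, metadata_path))
}
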