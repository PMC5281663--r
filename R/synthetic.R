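#' Configuration of a synthetic breath-measurement cohort
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes, standing in for undeposited patient data: a shared smooth
#' baseline conductivity surface per sensor, class-dependent perturbations
#' of low multilinear rank (the "redox signature" of each diagnosis),
#' per-device multiplicative effects for the five interchangeable devices,
#' and multiplicative log-normal sensor noise. Defaults mirror the study
#' design: class sizes 100 (HNSCC), 40 (bladder), 28 (colon); device-serial
#' allocation proportions per class following the reported cohort tables;
#' metadata distributions (age, sex, smoking, pack-years, stage)
#' approximating the reported baseline characteristics.
#'
#' @param classes named integer vector of class sizes.
#' @param amplitude dimensionless class-effect size: the peak magnitude of
#'   the class-specific perturbation relative to the mean baseline
#'   conductivity (0 = no class signal).
#' @param signature_ranks integer triple — multilinear rank of the class
#'   perturbations.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal sensor noise.
#' @param device_sdlog log-scale SD of the per-serial device multipliers.
#' @param serial_props named list (by class) of length-5 proportion vectors
#'   over the device serials 259, 309, 315, 362, 379.
#' @param metadata_params named list (by class) of metadata distributions:
#'   `age_mean`, `age_sd`, `p_male`, `p_food`, `p_smoking`,
#'   `pack_years_mean`, `stage_probs` (length 5, stages 0-4).
#' @param seed integer master seed of the cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(classes = c(HNSCC = 100L, bladder = 40L, colon = 28L),
                          amplitude = 0.15,
                          signature_ranks = c(1L, 1L, 1L),
                          noise_cv = 0.05,
                          device_sdlog = 0.1,
                          serial_props = NULL,
                          metadata_params = NULL,
                          seed = 1L) {
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    abort("`classes` must be a named vector of class sizes")
  }
  if (any(classes < 1) || any(classes != round(classes))) {
    abort("class sizes must be positive integers")
  }
  stopifnot(amplitude >= 0, noise_cv >= 0, device_sdlog >= 0)
  ranks <- as.integer(signature_ranks)
  if (length(ranks) != 3L || any(ranks < 1) || any(ranks > unname(MEAS_DIM))) {
    abort("`signature_ranks` must be three positive integers within 64, 36, 3")
  }

  default_props <- list(
    HNSCC = c(27, 18, 18, 18, 19) / 100,
    bladder = c(5, 5, 8, 13, 9) / 40,
    colon = c(6, 2, 10, 5, 5) / 28
  )
  if (is.null(serial_props)) {
    serial_props <- lapply(names(classes), function(cl) {
      default_props[[cl]] %||% rep(1 / 5, 5)
    })
    names(serial_props) <- names(classes)
  }
  for (cl in names(classes)) {
    p <- serial_props[[cl]]
    if (is.null(p) || length(p) != 5L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("serial proportions for class '%s' must be 5 values summing to 1", cl))
    }
  }

  default_meta <- list(
    HNSCC = list(age_mean = 64, age_sd = 10, p_male = 0.74, p_food = 0.23,
                 p_smoking = 0.57, pack_years_mean = 34,
                 stage_probs = c(3, 26, 20, 16, 35) / 100),
    bladder = list(age_mean = 68, age_sd = 10, p_male = 0.70, p_food = 0.60,
                   p_smoking = 0.25, pack_years_mean = 27,
                   stage_probs = c(21, 6, 9, 2, 2) / 40),
    colon = list(age_mean = 69, age_sd = 10, p_male = 0.64, p_food = 0.82,
                 p_smoking = 0.14, pack_years_mean = 17,
                 stage_probs = c(0, 6, 8, 11, 3) / 28)
  )
  generic_meta <- list(age_mean = 65, age_sd = 10, p_male = 0.6, p_food = 0.5,
                       p_smoking = 0.3, pack_years_mean = 25,
                       stage_probs = rep(1 / 5, 5))
  if (is.null(metadata_params)) {
    metadata_params <- lapply(names(classes), function(cl) {
      default_meta[[cl]] %||% generic_meta
    })
    names(metadata_params) <- names(classes)
  }

  structure(
    list(
      classes = setNames(as.integer(classes), names(classes)),
      amplitude = amplitude,
      signature_ranks = ranks,
      noise_cv = noise_cv,
      device_sdlog = device_sdlog,
      serial_props = serial_props,
      metadata_params = metadata_params,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# orthonormal matrix of smooth columns: random coefficients over a
# low-order cosine basis, orthonormalised
smooth_orthonormal <- function(n, r, n_basis = NULL) {
  n_basis <- n_basis %||% max(6L, r)
  t01 <- seq(0, 1, length.out = n)
  basis <- vapply(seq_len(n_basis), function(j) cos(pi * j * t01), numeric(n))
  coef <- matrix(rnorm(n_basis * r), n_basis, r)
  fix_signs(qr.Q(qr(basis %*% coef))[, seq_len(r), drop = FALSE])
}

#' Build per-class response signatures
#'
#' Every class shares one smooth positive baseline surface per sensor
#' (products of low-order trends in temperature step and cycle). Class
#' identity enters as an additive perturbation of multilinear rank
#' `signature_ranks`: the classes share the factor matrices (smooth in
#' step and cycle) and differ only in their core coefficients, so the
#' difference between any two class templates has multilinear rank at most
#' `signature_ranks` — the structure Tucker3 compression is matched to.
#' The perturbations share one scale, chosen so the largest of them peaks
#' at `amplitude` times the mean baseline conductivity.
#'
#' @param config a [cohort_config()].
#' @return A `class_signatures` object: named list of 64 x 36 x 3 template
#'   arrays (all entries strictly positive) plus the shared baseline and
#'   factors.
#' @export
build_signatures <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ranks <- config$signature_ranks
  n_class <- length(config$classes)

  step01 <- seq(0, 1, length.out = MEAS_DIM[["step"]])
  cyc <- seq_len(MEAS_DIM[["cycle"]]) - 1L
  f_step <- 1 + 0.4 * sin(pi * step01)
  g_cycle <- 1 + 0.2 * exp(-cyc / 10)
  sensor_level <- c(10, 14, 18)
  baseline <- array(0, unname(MEAS_DIM))
  for (s in 1:3) baseline[, , s] <- sensor_level[s] * outer(f_step, g_cycle)

  set.seed(derive_seed(config$seed, "signatures"))
  u <- smooth_orthonormal(MEAS_DIM[["step"]], ranks[1])
  v <- smooth_orthonormal(MEAS_DIM[["cycle"]], ranks[2])
  w <- fix_signs(qr.Q(qr(matrix(rnorm(9), 3, 3)))[, seq_len(ranks[3]), drop = FALSE])

  unit_core <- function() {
    g <- array(rnorm(prod(ranks)), ranks)
    g / sqrt(sum(g^2))
  }
  g0 <- unit_core()
  class_coef <- if (n_class == 1) 0 else seq(-1, 1, length.out = n_class)
  cores <- lapply(seq_len(n_class), function(j) {
    class_coef[j] * g0 + 0.3 * unit_core()
  })

  perts <- lapply(cores, function(g) {
    pert <- g
    pert <- ttm(pert, u, 1)
    pert <- ttm(pert, v, 2)
    ttm(pert, w, 3)
  })
  # one shared scale across classes (preserves relative class spacing and
  # the low-rank structure of template differences): the largest class
  # perturbation peaks at `amplitude` times the mean baseline conductivity
  peak <- max(vapply(perts, function(p) max(abs(p)), numeric(1)))
  scale0 <- if (peak > 0) config$amplitude * mean(baseline) / peak else 0
  templates <- lapply(perts, function(pert) {
    tpl <- baseline + scale0 * pert
    if (any(tpl <= 0)) {
      abort("class-effect amplitude too large: template not strictly positive")
    }
    tpl
  })
  names(templates) <- names(config$classes)
  structure(
    list(templates = templates, baseline = baseline,
         factors = list(u, v, w), cores = cores,
         amplitude = config$amplitude, ranks = ranks),
    class = "class_signatures"
  )
}

#' Simulate one measurement tensor from a class template
#'
#' The tensor is the template times a device multiplier times element-wise
#' log-normal noise with the given coefficient of variation; the noise is
#' mean-corrected (`E[noise] = 1`), so the template is recovered in
#' expectation.
#'
#' @param template strictly positive 64 x 36 x 3 array.
#' @param device_factor positive scalar multiplier of the device.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return A 64 x 36 x 3 conductivity array.
#' @export
simulate_measurement <- function(template, device_factor = 1, noise_cv = 0,
                                 seed = 1L) {
  check_tensor(template, "template")
  if (any(template <= 0)) abort("template must be strictly positive")
  if (device_factor <= 0) abort("device factor must be positive")
  stopifnot(noise_cv >= 0)
  out <- template * device_factor
  if (noise_cv > 0) {
    set.seed(seed)
    sigma <- sqrt(log(1 + noise_cv^2))
    noise <- exp(rnorm(length(out), -sigma^2 / 2, sigma))
    out <- out * array(noise, dim(out))
  }
  out
}

# largest-remainder apportionment of n into proportions p (ties to the
# earlier index), so exact counts are reproduced whenever n * p is integral
allocate_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(-(raw - counts), seq_along(p))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic cohort of measurements and metadata
#'
#' Draws exactly the configured number of patients per class; device
#' serials are apportioned deterministically by the configured proportions
#' (largest remainder) and shuffled across patients within class; metadata
#' fields are sampled from the per-class distributions; measurement tensors
#' come from [simulate_measurement()] applied to the class templates. The
#' whole cohort is a pure function of the configuration, including its
#' seed.
#'
#' @param config a [cohort_config()].
#' @return A list with `measurements` (long tibble) and `metadata`
#'   (tibble), ready for [double_cross_validate()] or
#'   [write_measurements()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sigs <- build_signatures(config)

  set.seed(derive_seed(config$seed, "devices"))
  device_factors <- exp(rnorm(5, 0, config$device_sdlog))
  names(device_factors) <- as.character(DEVICE_SERIALS)

  n_total <- sum(config$classes)
  ids <- sprintf("P%04d", seq_len(n_total))
  meta_rows <- vector("list", length(config$classes))
  offset <- 0L
  for (ci in seq_along(config$classes)) {
    cl <- names(config$classes)[ci]
    n_c <- config$classes[[ci]]
    pid <- ids[offset + seq_len(n_c)]
    offset <- offset + n_c

    counts <- allocate_counts(n_c, config$serial_props[[cl]])
    serials <- rep(DEVICE_SERIALS, counts)
    set.seed(derive_seed(config$seed, "serials", ci))
    serials <- serials[sample.int(n_c)]

    mp <- config$metadata_params[[cl]]
    set.seed(derive_seed(config$seed, "metadata", ci))
    meta_rows[[ci]] <- tibble(
      patient_id = pid,
      label = cl,
      device_serial = serials,
      age = round(rnorm(n_c, mp$age_mean, mp$age_sd), 1),
      sex = ifelse(runif(n_c) < mp$p_male, "male", "female"),
      food_intake_lt4h = runif(n_c) < mp$p_food,
      currently_smoking = runif(n_c) < mp$p_smoking,
      pack_years = round(stats::rgamma(n_c, shape = 2,
                                       scale = mp$pack_years_mean / 2), 1),
      tumor_stage = sample(0:4, n_c, replace = TRUE, prob = mp$stage_probs)
    )
  }
  metadata <- dplyr::bind_rows(meta_rows)

  tensors <- vector("list", n_total)
  names(tensors) <- metadata$patient_id
  for (i in seq_len(n_total)) {
    tensors[[i]] <- simulate_measurement(
      sigs$templates[[metadata$label[i]]],
      device_factor = device_factors[[as.character(metadata$device_serial[i])]],
      noise_cv = config$noise_cv,
      seed = derive_seed(config$seed, "measurement", i)
    )
  }
  list(
    measurements = tensors_to_measurements(tensors),
    metadata = metadata
  )
}

#' Randomly reassign class labels (null-model cohort)
#'
#' Permutes the label column of a metadata table while leaving every other
#' field and all measurements untouched; the label multiset is preserved.
#' Used to build null cohorts for permutation checks of the pipeline.
#'
#' @param metadata patient metadata tibble.
#' @param seed integer seed.
#' @return The metadata tibble with permuted labels.
#' @export
permute_labels <- function(metadata, seed = 1L) {
  set.seed(derive_seed(seed, "permute_labels"))
  metadata$label <- metadata$label[sample.int(nrow(metadata))]
  metadata
}
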