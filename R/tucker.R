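#' Unfold (matricise) a 3-way array along one mode
#'
#' The mode-`m` unfolding places mode `m` on the rows and the remaining two
#' modes, in increasing order, on the columns. `refold()` is its exact
#' inverse.
#'
#' @param tensor a 3-way array.
#' @param mode mode to place on the rows (1, 2 or 3).
#' @return `unfold()`: a matrix with `dim(tensor)[mode]` rows. `refold()`:
#'   the original array.
#' @export
unfold <- function(tensor, mode) {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3L, mode %in% 1:3)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(tensor, perm), nrow = dim(tensor)[mode])
}

#' @rdname unfold
#' @param mat a matrix produced by [unfold()].
#' @param shape the dimensions of the original array.
#' @export
refold <- function(mat, mode, shape) {
  stopifnot(is.matrix(mat), length(shape) == 3L, mode %in% 1:3)
  perm <- c(mode, setdiff(1:3, mode))
  if (nrow(mat) != shape[mode] || ncol(mat) != prod(shape[-mode])) {
    abort("matrix dimensions do not match `shape` for this mode")
  }
  aperm(array(mat, dim = shape[perm]), order(perm))
}

# mode-m product: tensor x_m t(U) when transpose = TRUE (projection), or
# tensor x_m U otherwise
ttm <- function(tensor, u, mode, transpose = FALSE) {
  shape <- dim(tensor)
  m <- if (transpose) crossprod(u, unfold(tensor, mode)) else u %*% unfold(tensor, mode)
  shape[mode] <- nrow(m)
  refold(m, mode, shape)
}

# fix the sign of each factor column: largest-magnitude entry positive
# (reproducible across SVD backends)
fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

check_ranks <- function(ranks, shape) {
  if (length(ranks) != 3L || any(ranks < 1) || any(ranks != round(ranks))) {
    abort("`ranks` must be three positive integers")
  }
  if (any(ranks > shape)) {
    abort(sprintf(
      "ranks (%s) exceed tensor dimensions (%s)",
      paste(ranks, collapse = ","), paste(shape, collapse = ",")
    ))
  }
  as.integer(ranks)
}

# relative reconstruction error from the explicit residual; the norm
# identity sqrt(1 - ||G||^2/||T||^2) would bottom out at sqrt(eps) ~ 1e-8
# and mask exact recoveries
tucker_rel_error <- function(tensor, factors, core) {
  recon <- core
  for (m in 1:3) recon <- ttm(recon, factors[[m]], m)
  tnorm <- sqrt(sum(tensor^2))
  if (tnorm == 0) return(0)
  sqrt(sum((tensor - recon)^2)) / tnorm
}

new_tucker_model <- function(factors, core, tensor, ranks, iterations,
                             converged, method) {
  rel_err <- tucker_rel_error(tensor, factors, core)
  structure(
    list(
      factors = factors, core = core, ranks = ranks,
      rel_error = rel_err, iterations = iterations,
      converged = converged, method = method
    ),
    class = "tucker_model"
  )
}

#' Truncated higher-order SVD (HOSVD) of a 3-way array
#'
#' Each factor matrix holds the leading left singular vectors of the
#' corresponding unfolding; the core is the tensor contracted with the
#' factor transposes. HOSVD is quasi-optimal and serves as the
#' initialisation for [hooi()].
#'
#' @param tensor a 3-way array.
#' @param ranks integer vector `(r1, r2, r3)` of core dimensions.
#' @return A `tucker_model`: orthonormal factors `A` (I1 x r1), `B`
#'   (I2 x r2), `C` (I3 x r3), core array `G` (r1 x r2 x r3), the relative
#'   reconstruction error and fit metadata.
#' @export
hosvd <- function(tensor, ranks) {
  shape <- dim(tensor)
  ranks <- check_ranks(ranks, shape)
  factors <- lapply(1:3, function(m) {
    u <- svd(unfold(tensor, m), nu = ranks[m], nv = 0)$u
    fix_signs(u)
  })
  core <- project_core(tensor, factors)
  new_tucker_model(
    factors, core, tensor, ranks,
    iterations = 0L, converged = TRUE, method = "hosvd"
  )
}

project_core <- function(tensor, factors) {
  g <- tensor
  for (m in 1:3) g <- ttm(g, factors[[m]], m, transpose = TRUE)
  g
}

#' Tucker3 decomposition by higher-order orthogonal iteration (HOOI)
#'
#' Alternating least squares over the three factor matrices, initialised
#' from [hosvd()]. Each sweep updates one factor to the leading left
#' singular vectors of the tensor projected onto the other two factors, so
#' the fit is monotonically non-decreasing; iteration stops when the
#' improvement in relative fit drops below `tol` or after `max_iter`
#' sweeps (non-convergence is flagged, not an error).
#'
#' @inheritParams hosvd
#' @param tol stopping tolerance on the change in relative reconstruction
#'   error between sweeps.
#' @param max_iter maximum number of sweeps.
#' @return A `tucker_model` (see [hosvd()]); its reconstruction error never
#'   exceeds the HOSVD error at the same ranks.
#' @export
hooi <- function(tensor, ranks, tol = 1e-7, max_iter = 200L) {
  stopifnot(tol > 0, max_iter >= 1)
  shape <- dim(tensor)
  ranks <- check_ranks(ranks, shape)
  factors <- hosvd(tensor, ranks)$factors
  err_prev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (m in 1:3) {
      y <- tensor
      for (o in setdiff(1:3, m)) y <- ttm(y, factors[[o]], o, transpose = TRUE)
      factors[[m]] <- fix_signs(svd(unfold(y, m), nu = ranks[m], nv = 0)$u)
    }
    core <- project_core(tensor, factors)
    err <- tucker_rel_error(tensor, factors, core)
    if (err_prev - err < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    err_prev <- err
  }
  new_tucker_model(factors, core, tensor, ranks, iter, converged, "hooi")
}

#' Reconstruct a tensor from a Tucker model
#'
#' @param model a `tucker_model`.
#' @return The rank-`(r1,r2,r3)` reconstruction as a 3-way array.
#' @export
tucker_reconstruct <- function(model) {
  stopifnot(inherits(model, "tucker_model"))
  g <- model$core
  for (m in 1:3) g <- ttm(g, model$factors[[m]], m)
  g
}

#' Fit a shared Tucker compressor on a set of training tensors
#'
#' Factor matrices are estimated once per training set from the
#' concatenation of all training tensors (sample-mode augmentation): for
#' each measurement mode the factor holds the leading eigenvectors of that
#' mode's scatter matrix, summed over training tensors, optionally refined
#' by alternating sweeps in the style of [hooi()] with the sample mode left
#' untouched. Held-out tensors are then projected onto the same factors, so
#' test data never enter factor estimation.
#'
#' @param tensors list of preprocessed 64 x 36 x 3 training arrays.
#' @param ranks integer vector `(r1, r2, r3)`.
#' @param max_iter alternating refinement sweeps after the scatter-matrix
#'   initialisation (0 gives plain group HOSVD).
#' @param tol stopping tolerance on relative fit improvement.
#' @return A `tucker_compressor` holding the three orthonormal factors, the
#'   ranks and the mean relative reconstruction error on the training set.
#' @seealso [compress()]
#' @export
fit_compressor <- function(tensors, ranks, max_iter = 10L, tol = 1e-7) {
  if (!length(tensors)) abort("no training tensors")
  lapply(tensors, check_tensor)
  shape <- unname(MEAS_DIM)
  ranks <- check_ranks(ranks, shape)

  mode_factor <- function(tensor_list, m, project = NULL) {
    scatter <- matrix(0, shape[m], shape[m])
    for (t in tensor_list) {
      y <- t
      if (!is.null(project)) {
        for (o in setdiff(1:3, m)) y <- ttm(y, project[[o]], o, transpose = TRUE)
      }
      u <- unfold(y, m)
      scatter <- scatter + tcrossprod(u)
    }
    e <- eigen(scatter, symmetric = TRUE)
    fix_signs(e$vectors[, seq_len(ranks[m]), drop = FALSE])
  }

  factors <- lapply(1:3, function(m) mode_factor(tensors, m))
  total_norm2 <- sum(vapply(tensors, function(t) sum(t^2), numeric(1)))
  fit_err <- function(factors) {
    core_norm2 <- sum(vapply(
      tensors, function(t) sum(project_core(t, factors)^2), numeric(1)
    ))
    sqrt(max(0, 1 - core_norm2 / total_norm2))
  }
  err_prev <- fit_err(factors)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (m in 1:3) factors[[m]] <- mode_factor(tensors, m, project = factors)
    err <- fit_err(factors)
    if (err_prev - err < tol) {
      err_prev <- err
      break
    }
    err_prev <- err
  }
  structure(
    list(factors = factors, ranks = ranks, rel_error = err_prev,
         iterations = iter, n_train = length(tensors)),
    class = "tucker_compressor"
  )
}

#' Compress a measurement tensor to a fixed-length feature vector
#'
#' Projects the tensor onto the compressor's factor matrices and vectorises
#' the resulting core, yielding `r1 * r2 * r3` features per measurement.
#'
#' @param compressor a `tucker_compressor` from [fit_compressor()].
#' @param tensor a 64 x 36 x 3 array (already preprocessed the same way as
#'   the training tensors).
#' @return A numeric vector of length `prod(ranks)`, named `f0`, `f1`, ...
#' @export
compress <- function(compressor, tensor) {
  stopifnot(inherits(compressor, "tucker_compressor"))
  check_tensor(tensor)
  g <- as.vector(project_core(tensor, compressor$factors))
  names(g) <- paste0("f", seq_along(g) - 1L)
  g
}

#' Compress a set of tensors to a feature tibble
#'
#' @param compressor a `tucker_compressor`.
#' @param tensors named list of preprocessed arrays (names are patient ids).
#' @param metadata optional metadata tibble supplying a `label` column.
#' @return A tibble with `patient_id`, optionally `label`, and feature
#'   columns `f0` ... `f(k-1)`.
#' @export
compress_features <- function(compressor, tensors, metadata = NULL) {
  feats <- t(vapply(
    tensors, function(t) compress(compressor, t),
    numeric(prod(compressor$ranks))
  ))
  out <- tibble(patient_id = names(tensors))
  if (!is.null(metadata)) {
    out$label <- metadata$label[match(out$patient_id, metadata$patient_id)]
  }
  dplyr::bind_cols(out, as_tibble(feats))
}

#' @export
print.tucker_model <- function(x, ...) {
  cat(sprintf(
    "Tucker3 model (%s): ranks (%s), relative error %.3g, %d iteration(s)%s\n",
    x$method, paste(x$ranks, collapse = ","), x$rel_error, x$iterations,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' @export
print.tucker_compressor <- function(x, ...) {
  cat(sprintf(
    "Tucker3 compressor: ranks (%s), %d training tensors, mean relative error %.3g\n",
    paste(x$ranks, collapse = ","), x$n_train, x$rel_error
  ))
  invisible(x)
}
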