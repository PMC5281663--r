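# Independent oracles used across the suite. Each reimplements the checked
# quantity through different primitives than the package code path.

# ---- Tucker oracle: HOOI via eigen-decomposition of scatter matrices ----
# Own unfolding by index arithmetic (no shared code with unfold()).
oracle_unfold <- function(tensor, mode) {
  d <- dim(tensor)
  out <- matrix(0, d[mode], prod(d[-mode]))
  other <- setdiff(1:3, mode)
  col <- 0L
  for (k in seq_len(d[other[2]])) {
    for (j in seq_len(d[other[1]])) {
      col <- col + 1L
      idx <- list(NULL, NULL, NULL)
      idx[[other[1]]] <- j
      idx[[other[2]]] <- k
      for (i in seq_len(d[mode])) {
        idx[[mode]] <- i
        out[i, col] <- tensor[idx[[1]], idx[[2]], idx[[3]]]
      }
    }
  }
  out
}

oracle_project <- function(tensor, factors) {
  # contract each mode with t(U) using plain matrix algebra on unfoldings
  d <- dim(tensor)
  cur <- tensor
  for (m in 1:3) {
    u <- factors[[m]]
    unf <- oracle_unfold(cur, m)
    proj <- t(u) %*% unf
    dnew <- dim(cur)
    dnew[m] <- ncol(u)
    perm <- c(m, setdiff(1:3, m))
    cur <- aperm(array(proj, dnew[perm]), order(perm))
  }
  cur
}

# relative fit (1 - rel. reconstruction error) by eigen-based HOOI
oracle_tucker_fit <- function(tensor, ranks, iters = 100, tol = 1e-12) {
  factors <- lapply(1:3, function(m) {
    s <- oracle_unfold(tensor, m)
    e <- eigen(s %*% t(s), symmetric = TRUE)
    e$vectors[, seq_len(ranks[m]), drop = FALSE]
  })
  tnorm2 <- sum(tensor^2)
  err_prev <- Inf
  for (it in seq_len(iters)) {
    for (m in 1:3) {
      fac <- factors
      fac[[m]] <- diag(dim(tensor)[m])
      y <- oracle_project(tensor, fac)
      s <- oracle_unfold(y, m)
      e <- eigen(s %*% t(s), symmetric = TRUE)
      factors[[m]] <- e$vectors[, seq_len(ranks[m]), drop = FALSE]
    }
    core <- oracle_project(tensor, factors)
    err <- sqrt(max(0, 1 - sum(core^2) / tnorm2))
    if (err_prev - err < tol) break
    err_prev <- err
  }
  1 - err
}

# same eigen-based HOOI oracle with its own aperm-based matricisation
# (fast enough for full 64 x 36 x 3 tensors; the algorithmic path — eigen
# decompositions of scatter matrices, ALS sweeps — stays independent of the
# package's svd-based implementation)
oracle_unfold_fast <- function(tensor, mode) {
  d <- dim(tensor)
  other <- setdiff(1:3, mode)
  matrix(aperm(tensor, c(mode, other)), d[mode], prod(d[other]))
}

oracle_tucker_fit_fast <- function(tensor, ranks, iters = 200, tol = 1e-13) {
  d <- dim(tensor)
  contract <- function(cur, u, mode) {
    other <- setdiff(1:3, mode)
    unf <- oracle_unfold_fast(cur, mode)
    dn <- dim(cur)
    dn[mode] <- ncol(u)
    aperm(array(t(u) %*% unf, dn[c(mode, other)]), order(c(mode, other)))
  }
  factors <- lapply(1:3, function(m) {
    s <- oracle_unfold_fast(tensor, m)
    eigen(s %*% t(s), symmetric = TRUE)$vectors[, seq_len(ranks[m]), drop = FALSE]
  })
  tnorm2 <- sum(tensor^2)
  err_prev <- Inf
  for (it in seq_len(iters)) {
    for (m in 1:3) {
      y <- tensor
      for (o in setdiff(1:3, m)) y <- contract(y, factors[[o]], o)
      s <- oracle_unfold_fast(y, m)
      factors[[m]] <- eigen(s %*% t(s), symmetric = TRUE)$vectors[, seq_len(ranks[m]), drop = FALSE]
    }
    core <- tensor
    for (m in 1:3) core <- contract(core, factors[[m]], m)
    err <- sqrt(max(0, 1 - sum(core^2) / tnorm2))
    if (err_prev - err < tol) break
    err_prev <- err
  }
  1 - err
}

# ---- confusion-matrix oracle: explicit counting loop ----
oracle_confusion <- function(truth, value, positive, threshold = 0) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    predicted_positive <- value[i] >= threshold
    actually_positive <- truth[i] == positive
    if (predicted_positive && actually_positive) tp <- tp + 1L
    if (predicted_positive && !actually_positive) fp <- fp + 1L
    if (!predicted_positive && !actually_positive) tn <- tn + 1L
    if (!predicted_positive && actually_positive) fn <- fn + 1L
  }
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       mcc = if (den == 0) 0 else num / den)
}

# ---- AUC oracle: Mann-Whitney pair counting ----
oracle_auc <- function(truth, value, positive) {
  vp <- value[truth == positive]
  vn <- value[truth != positive]
  concordant <- 0
  for (p in vp) {
    for (n in vn) {
      if (p > n) concordant <- concordant + 1
      else if (p == n) concordant <- concordant + 0.5
    }
  }
  concordant / (length(vp) * length(vn))
}

# ---- judge search oracle: independent full enumeration ----
# enumerates gate x C(top_m, 3)^2 with nested loops and direct scoring
oracle_best_assembly_score <- function(oof, labels, folds = NULL, m = 8) {
  p <- ncol(oof)
  fold_mcc <- function(values) {
    score_one <- function(lab, val) {
      oc <- oracle_confusion(lab, val, positive = 1)
      oc$mcc
    }
    if (is.null(folds)) return(score_one(labels, values))
    mean(vapply(
      unique(sort(folds)),
      function(f) score_one(labels[folds == f], values[folds == f]),
      numeric(1)
    ))
  }
  single <- vapply(seq_len(p), function(j) fold_mcc(oof[, j]), numeric(1))
  m <- min(m, p)
  top <- sort(order(-single, seq_len(p))[seq_len(m)])
  combs <- combn(top, 3)
  best <- -Inf
  for (g in seq_len(p)) {
    for (i in seq_len(ncol(combs))) {
      for (j in seq_len(ncol(combs))) {
        val <- numeric(nrow(oof))
        for (r in seq_len(nrow(oof))) {
          branch <- if (oof[r, g] >= 0) combs[, i] else combs[, j]
          val[r] <- mean(oof[r, branch])
        }
        s <- fold_mcc(val)
        if (s > best) best <- s
      }
    }
  }
  best
}

# ---- fixtures ----
make_small_cohort <- function(n_a = 20L, n_b = 12L, amplitude = 0.15,
                              noise_cv = 0.05, seed = 1L, ...) {
  generate_cohort(cohort_config(
    classes = c(A = n_a, B = n_b), amplitude = amplitude,
    noise_cv = noise_cv, seed = seed, ...
  ))
}

random_tucker_tensor <- function(shape, ranks, seed) {
  set.seed(seed)
  core <- array(rnorm(prod(ranks)), ranks)
  out <- core
  for (m in 1:3) {
    u <- qr.Q(qr(matrix(rnorm(shape[m] * ranks[m]), shape[m], ranks[m])))
    unf <- matrix(aperm(out, c(m, setdiff(1:3, m))), nrow = dim(out)[m])
    proj <- u %*% unf
    dnew <- dim(out)
    dnew[m] <- shape[m]
    perm <- c(m, setdiff(1:3, m))
    out <- aperm(array(proj, dnew[perm]), order(perm))
  }
  out
}
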