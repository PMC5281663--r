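#' Loss and analytic gradient of the small tanh network
#'
#' The classifier is a one-hidden-layer perceptron with `tanh` activations
#' on both the hidden layer and the single output unit, trained on labels
#' coded -1/+1 with mean squared error, so the output is a bounded
#' predictive value in \[-1, 1\] whose natural decision boundary is 0.
#' This function evaluates the loss and its exact gradient for a given
#' parameter set; it is the single gradient path used by the trainer, and
#' the object checked against finite differences in the test suite.
#'
#' @param par list with elements `W1` (k x h), `b1` (h), `W2` (h x 1), `b2`
#'   (scalar).
#' @param x numeric matrix of features (n x k).
#' @param y numeric vector of labels in `{-1, +1}`.
#' @return A list with `loss` (mean squared error) and `grad` (same shape
#'   as `par`).
#' @export
mlp_gradient <- function(par, x, y) {
  n <- nrow(x)
  z1 <- sweep(x %*% par$W1, 2, par$b1, "+")
  h <- tanh(z1)
  o <- tanh(h %*% par$W2 + par$b2)
  resid <- o - y
  loss <- sum(resid^2) / n
  d <- resid * (1 - o^2) * (2 / n)
  dh <- (d %*% t(par$W2)) * (1 - h^2)
  list(
    loss = loss,
    grad = list(
      W1 = crossprod(x, dh),
      b1 = colSums(dh),
      W2 = crossprod(h, d),
      b2 = sum(d)
    )
  )
}

#' Train a small feed-forward network by full-batch gradient descent
#'
#' Weights are initialised from `seed` (Glorot-uniform), then updated by
#' deterministic full-batch gradient descent on the mean squared error for
#' a fixed number of epochs — no early stopping, no stochastic batching —
#' so training is bit-reproducible given (data, ordering, seed,
#' hyperparameters). That determinism is what makes the surrounding
#' brute-force model search and double cross-validation reproducible
#' end-to-end.
#'
#' @param x numeric feature matrix (n x k), or a data frame of features.
#' @param y labels coded -1/+1 (a factor or a vector coercible to it).
#' @param hidden number of hidden units.
#' @param epochs number of full-batch epochs.
#' @param learning_rate gradient-descent step size.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `mlp_model` carrying the weights, the
#'   hyperparameters, the final training loss and the loss trace.
#' @export
train_mlp <- function(x, y, hidden = 8L, epochs = 2000L, learning_rate = 0.01,
                      seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) abort("labels must be coded -1/+1")
  if (length(unique(y)) < 2L) abort("training set contains a single class")
  if (min(table(y)) < 2L) abort("need at least 2 samples per class")
  if (!all(is.finite(x))) abort("features must be finite")
  stopifnot(nrow(x) == length(y), hidden >= 1, epochs >= 1, learning_rate > 0)

  k <- ncol(x)
  set.seed(seed)
  lim1 <- sqrt(6 / (k + hidden))
  lim2 <- sqrt(6 / (hidden + 1))
  par <- list(
    W1 = matrix(runif(k * hidden, -lim1, lim1), k, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(runif(hidden, -lim2, lim2), hidden, 1),
    b2 = 0
  )
  loss_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    g <- mlp_gradient(par, x, y)
    loss_trace[e] <- g$loss
    par$W1 <- par$W1 - learning_rate * g$grad$W1
    par$b1 <- par$b1 - learning_rate * g$grad$b1
    par$W2 <- par$W2 - learning_rate * g$grad$W2
    par$b2 <- par$b2 - learning_rate * g$grad$b2
  }
  structure(
    list(
      par = par, input_size = k, hidden = as.integer(hidden),
      epochs = as.integer(epochs), learning_rate = learning_rate,
      seed = as.integer(seed), final_loss = mlp_gradient(par, x, y)$loss,
      loss_trace = loss_trace
    ),
    class = "mlp_model"
  )
}

#' Predictive values of a trained network
#'
#' @param object an `mlp_model`.
#' @param newdata feature matrix or data frame with `input_size` columns.
#' @param ... unused.
#' @return Numeric vector of predictive values in \[-1, 1\].
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- if (is.numeric(newdata) && is.null(dim(newdata))) {
    matrix(newdata, nrow = 1)
  } else {
    as.matrix(newdata)
  }
  if (ncol(x) != object$input_size) {
    abort(sprintf(
      "feature length %d does not match network input size %d",
      ncol(x), object$input_size
    ))
  }
  par <- object$par
  h <- tanh(sweep(x %*% par$W1, 2, par$b1, "+"))
  as.vector(tanh(h %*% par$W2 + par$b2))
}

#' Serialise / restore a trained network as JSON
#'
#' @param model an `mlp_model`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `mlp_to_json()`: the path (or JSON string) invisibly;
#'   `mlp_from_json()`: the restored `mlp_model`.
#' @export
mlp_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  payload <- list(
    input_size = model$input_size, hidden = model$hidden,
    epochs = model$epochs, learning_rate = model$learning_rate,
    seed = model$seed, final_loss = model$final_loss,
    W1 = as.vector(model$par$W1), b1 = model$par$b1,
    W2 = as.vector(model$par$W2), b2 = model$par$b2
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname mlp_to_json
#' @param json a JSON string or file path produced by [mlp_to_json()].
#' @export
mlp_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  structure(
    list(
      par = list(
        W1 = matrix(p$W1, p$input_size, p$hidden),
        b1 = p$b1,
        W2 = matrix(p$W2, p$hidden, 1),
        b2 = p$b2
      ),
      input_size = as.integer(p$input_size), hidden = as.integer(p$hidden),
      epochs = as.integer(p$epochs), learning_rate = p$learning_rate,
      seed = as.integer(p$seed), final_loss = p$final_loss,
      loss_trace = numeric(0)
    ),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "MLP %d-%d-1 (tanh), %d epochs @ lr %g, seed %d, final loss %.4g\n",
    x$input_size, x$hidden, x$epochs, x$learning_rate, x$seed, x$final_loss
  ))
  invisible(x)
}
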