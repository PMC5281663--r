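#' Train a pool of candidate networks over a hyperparameter grid
#'
#' One network is trained per (hidden size, seed) grid point on the same
#' feature matrix; each carries a unique provenance tag (`"h<hidden>_s<seed>"`)
#' so the brute-force search over assemblies is auditable and reproducible.
#' A grid point whose training fails is recorded and excluded rather than
#' aborting the whole pool.
#'
#' @param x feature matrix (n x k).
#' @param y labels coded -1/+1.
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param seeds integer vector of initialisation seeds.
#' @param epochs,learning_rate passed to [train_mlp()].
#' @return An object of class `ann_pool`: a list of `mlp_model`s plus a
#'   provenance tibble (tag, hidden, seed, failure message if any).
#' @export
build_pool <- function(x, y, hidden_sizes = c(4L, 8L), seeds = c(1L, 2L),
                       epochs = 2000L, learning_rate = 0.01) {
  if (!length(hidden_sizes)) abort("`hidden_sizes` must be non-empty")
  if (!length(seeds)) abort("`seeds` must be non-empty")
  grid <- expand.grid(hidden = as.integer(hidden_sizes),
                      seed = as.integer(seeds))
  models <- vector("list", nrow(grid))
  failed <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      train_mlp(x, y, hidden = grid$hidden[i], epochs = epochs,
                learning_rate = learning_rate, seed = grid$seed[i]),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed[i] <- conditionMessage(fit)
    } else {
      models[[i]] <- fit
    }
  }
  tags <- sprintf("h%d_s%d", grid$hidden, grid$seed)
  keep <- !vapply(models, is.null, logical(1))
  if (!any(keep)) abort("every pool candidate failed to train")
  structure(
    list(
      models = setNames(models[keep], tags[keep]),
      provenance = tibble(
        tag = tags[keep], hidden = grid$hidden[keep], seed = grid$seed[keep]
      ),
      failures = tibble(tag = tags[!keep], message = failed[!keep])
    ),
    class = "ann_pool"
  )
}

#' Predictive values of every pool member on a feature matrix
#'
#' @param pool an `ann_pool`.
#' @param x feature matrix.
#' @return n x pool-size matrix of predictive values, columns named by
#'   provenance tag.
#' @export
pool_predict <- function(pool, x) {
  stopifnot(inherits(pool, "ann_pool"))
  preds <- lapply(pool$models, function(m) predict(m, x))
  do.call(cbind, preds)
}

#' Assemble a judge model from pool members
#'
#' The judge is a gated ensemble of seven networks: one gating network
#' splits samples into a positive and a negative group (gate output >= 0
#' routes to the positive branch, ties included); the sample is then scored
#' by the corresponding committee of three distinct networks and the three
#' outputs are averaged, giving a predictive value in \[-1, 1\].
#'
#' @param gate an `mlp_model`.
#' @param positive_committee,negative_committee lists of exactly three
#'   `mlp_model`s (distinct within each committee; reuse across the gate
#'   and the two committees is allowed).
#' @param provenance optional list recording the scaling option, Tucker
#'   ranks and member tags the judge was built from.
#' @return An object of class `judge_model`.
#' @export
judge_model <- function(gate, positive_committee, negative_committee,
                        provenance = list()) {
  stopifnot(inherits(gate, "mlp_model"))
  if (length(positive_committee) != 3L || length(negative_committee) != 3L) {
    abort("each committee must contain exactly three networks")
  }
  for (m in c(positive_committee, negative_committee)) {
    stopifnot(inherits(m, "mlp_model"))
    if (m$input_size != gate$input_size) {
      abort("all judge members must share one feature length")
    }
  }
  structure(
    list(
      gate = gate,
      positive_committee = positive_committee,
      negative_committee = negative_committee,
      provenance = provenance
    ),
    class = "judge_model"
  )
}

#' Predictive value of a judge model
#'
#' @param judge a `judge_model`.
#' @param x feature matrix (n x k) or single feature vector.
#' @return Numeric vector of predictive values in \[-1, 1\].
#' @export
judge_predict <- function(judge, x) {
  stopifnot(inherits(judge, "judge_model"))
  g <- predict(judge$gate, x)
  committee_mean <- function(committee) {
    rowMeans(matrix(
      vapply(committee, function(m) predict(m, x), numeric(length(g))),
      nrow = length(g)
    ))
  }
  ifelse(g >= 0, committee_mean(judge$positive_committee),
         committee_mean(judge$negative_committee))
}

# judge predictive values computed from a matrix of member predictions
# (columns indexed by pool position); used by the brute-force search where
# the members' out-of-fold predictions are precomputed
judge_values_from_matrix <- function(pred, gate, pos_idx, neg_idx) {
  g <- pred[, gate]
  ifelse(
    g >= 0,
    rowMeans(pred[, pos_idx, drop = FALSE]),
    rowMeans(pred[, neg_idx, drop = FALSE])
  )
}

#' Brute-force selection of the best judge assembly
#'
#' Exhaustively enumerates candidate (gate, positive committee, negative
#' committee) assemblies and returns the one maximising the selection
#' metric computed from out-of-fold predictive values, so only inner-fold
#' information ever enters model selection. To keep the enumeration
#' bounded, committees are drawn from the top-`m` pool members ranked by
#' their individual out-of-fold score, while the gate ranges over the full
#' pool; the search is then exhaustive over `pool x C(m,3)^2` assemblies.
#' Ties are broken lexicographically by provenance (column) order, so
#' selection is deterministic.
#'
#' @param oof numeric matrix (n x pool size) of out-of-fold predictive
#'   values, one column per pool member.
#' @param labels vector of true labels coded -1/+1.
#' @param folds optional integer vector of inner-fold ids; when supplied the
#'   score is the mean metric over folds, otherwise the pooled metric.
#' @param m committee candidates are the top `m` members by individual
#'   score (capped at the pool size).
#' @param metric `"mcc"` (default, the reported model-quality measure) or
#'   `"accuracy"`.
#' @return An object of class `judge_selection`: gate index, committee
#'   index vectors, the winning score, the per-member scores and the number
#'   of assemblies enumerated.
#' @export
brute_force_select <- function(oof, labels, folds = NULL, m = 8L,
                               metric = c("mcc", "accuracy")) {
  metric <- match.arg(metric)
  oof <- as.matrix(oof)
  labels <- as.numeric(labels)
  stopifnot(nrow(oof) == length(labels), all(labels %in% c(-1, 1)))
  p <- ncol(oof)
  if (p < 1L) abort("empty pool")
  if (p < 3L) abort("need at least 3 pool members to form a committee")

  score_values <- function(values) {
    if (is.null(folds)) {
      score_metric(labels, values, metric)
    } else {
      mean(vapply(
        split(seq_along(labels), folds),
        function(i) score_metric(labels[i], values[i], metric),
        numeric(1)
      ))
    }
  }

  member_scores <- apply(oof, 2, score_values)
  m <- min(as.integer(m), p)
  if (m < 3L) m <- 3L
  top <- sort(head(order(-member_scores, seq_len(p)), m))
  committees <- combn(top, 3L)

  best <- NULL
  best_score <- -Inf
  n_assemblies <- 0L
  for (gate in seq_len(p)) {
    for (ip in seq_len(ncol(committees))) {
      pos_idx <- committees[, ip]
      for (ineg in seq_len(ncol(committees))) {
        neg_idx <- committees[, ineg]
        n_assemblies <- n_assemblies + 1L
        s <- score_values(judge_values_from_matrix(oof, gate, pos_idx, neg_idx))
        if (s > best_score) {
          best_score <- s
          best <- list(gate = gate, positive = pos_idx, negative = neg_idx)
        }
      }
    }
  }
  structure(
    list(
      gate = best$gate, positive = best$positive, negative = best$negative,
      score = best_score, metric = metric, member_scores = member_scores,
      m = m, n_assemblies = n_assemblies,
      tags = colnames(oof) %||% as.character(seq_len(p))
    ),
    class = "judge_selection"
  )
}

# threshold-0 metric of predictive values against -1/+1 labels
score_metric <- function(labels, values, metric) {
  pred <- ifelse(values >= 0, 1, -1)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == -1 & labels == -1)
  fp <- sum(pred == 1 & labels == -1)
  fn <- sum(pred == -1 & labels == 1)
  if (metric == "accuracy") {
    return((tp + tn) / length(labels))
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
}

#' Build a judge model from a pool and a selection
#'
#' @param pool an `ann_pool` whose members were refitted on the full
#'   training set.
#' @param selection a `judge_selection` (indices refer to pool positions).
#' @param provenance optional provenance list stored on the judge.
#' @return A `judge_model`.
#' @export
assemble_judge <- function(pool, selection, provenance = list()) {
  stopifnot(inherits(pool, "ann_pool"), inherits(selection, "judge_selection"))
  provenance$gate_tag <- selection$tags[selection$gate]
  provenance$positive_tags <- selection$tags[selection$positive]
  provenance$negative_tags <- selection$tags[selection$negative]
  provenance$selection_score <- selection$score
  judge_model(
    gate = pool$models[[selection$gate]],
    positive_committee = pool$models[selection$positive],
    negative_committee = pool$models[selection$negative],
    provenance = provenance
  )
}

#' @export
print.judge_selection <- function(x, ...) {
  cat(sprintf(
    "Judge selection: gate %s, positive {%s}, negative {%s}; %s = %.4f over %d assemblies\n",
    x$tags[x$gate], paste(x$tags[x$positive], collapse = ","),
    paste(x$tags[x$negative], collapse = ","), x$metric, x$score,
    x$n_assemblies
  ))
  invisible(x)
}

#' @export
print.judge_model <- function(x, ...) {
  cat("Gated judge ensemble: 1 gate + 2 committees of 3 networks\n")
  if (length(x$provenance)) {
    cat(sprintf("  gate: %s\n", x$provenance$gate_tag %||% "?"))
  }
  invisible(x)
}

#' Serialise a judge model (seven networks plus provenance) as JSON
#'
#' @param judge a `judge_model`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @return The path (or JSON string), invisibly.
#' @export
judge_to_json <- function(judge, path = NULL) {
  stopifnot(inherits(judge, "judge_model"))
  payload <- list(
    gate = jsonlite::fromJSON(mlp_to_json(judge$gate)),
    positive_committee = lapply(judge$positive_committee, function(m) {
      jsonlite::fromJSON(mlp_to_json(m))
    }),
    negative_committee = lapply(judge$negative_committee, function(m) {
      jsonlite::fromJSON(mlp_to_json(m))
    }),
    provenance = judge$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
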