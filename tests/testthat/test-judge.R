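judge_values_from_matrix_test <- function(pred, gate, pos, neg) {
  ifelse(pred[, gate] >= 0,
         rowMeans(pred[, pos, drop = FALSE]),
         rowMeans(pred[, neg, drop = FALSE]))
}

make_pool_fixture <- function(n = 30, k = 3, hidden = c(2L, 3L), seeds = 1:2,
                              seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k)
  y <- rep(c(-1, 1), length.out = n)
  pool <- build_pool(x, y, hidden_sizes = hidden, seeds = seeds, epochs = 30)
  list(x = x, y = y, pool = pool)
}

test_that("pool size, tags and reproducibility follow the grid", {
  fx <- make_pool_fixture()
  expect_s3_class(fx$pool, "ann_pool")
  expect_length(fx$pool$models, 4)
  expect_equal(sort(names(fx$pool$models)),
               sort(c("h2_s1", "h2_s2", "h3_s1", "h3_s2")))
  expect_false(anyDuplicated(fx$pool$provenance$tag) > 0)

  again <- build_pool(fx$x, fx$y, hidden_sizes = c(2L, 3L), seeds = 1:2,
                      epochs = 30)
  expect_equal(lapply(again$models, `[[`, "par"),
               lapply(fx$pool$models, `[[`, "par"), tolerance = 0)

  expect_error(build_pool(fx$x, fx$y, seeds = integer(0)), "non-empty")
})

test_that("judge prediction averages the routed committee and stays in [-1, 1]", {
  fx <- make_pool_fixture(seed = 2)
  nets <- fx$pool$models
  j <- judge_model(nets[[1]], nets[c(1, 2, 3)], nets[c(2, 3, 4)])
  v <- judge_predict(j, fx$x)
  expect_true(all(v >= -1 & v <= 1))

  gate_out <- predict(nets[[1]], fx$x)
  pos_mean <- rowMeans(sapply(nets[c(1, 2, 3)], function(m) predict(m, fx$x)))
  neg_mean <- rowMeans(sapply(nets[c(2, 3, 4)], function(m) predict(m, fx$x)))
  expect_equal(v, ifelse(gate_out >= 0, pos_mean, neg_mean))

  # all members identical -> judge equals the single net, any gate branch
  j_same <- judge_model(nets[[2]], nets[c(1, 1, 1)], nets[c(1, 1, 1)])
  expect_error(j_same, NA)
  expect_equal(judge_predict(j_same, fx$x), predict(nets[[1]], fx$x))

  expect_error(judge_model(nets[[1]], nets[c(1, 2)], nets[c(2, 3, 4)]),
               "exactly three")
})

test_that("committee averaging follows the arithmetic mean and gate ties go positive", {
  # hand-built constant nets: output = tanh(b2) regardless of input
  const_net <- function(value) {
    structure(
      list(par = list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
                      W2 = matrix(0, 2, 1), b2 = atanh(value)),
           input_size = 2L, hidden = 2L, epochs = 0L, learning_rate = 0,
           seed = 0L, final_loss = NA_real_, loss_trace = numeric(0)),
      class = "mlp_model"
    )
  }
  x <- matrix(0, 1, 2)
  pos <- lapply(c(0.2, 0.4, 0.6), const_net)
  neg <- lapply(c(-0.5, -0.5, -0.5), const_net)
  # gate output exactly 0 -> positive branch
  j <- judge_model(const_net(0), pos, neg)
  expect_equal(judge_predict(j, x), 0.4)
  j_neg <- judge_model(const_net(-0.1), pos, neg)
  expect_equal(judge_predict(j_neg, x), -0.5)
})

test_that("brute force is exhaustive: score matches independent full enumeration", {
  set.seed(4)
  for (rep in 1:3) {
    n <- 24
    oof <- matrix(runif(n * 6, -1, 1), n, 6)
    colnames(oof) <- sprintf("n%d", 1:6)
    y <- rep(c(-1, 1), length.out = n)
    folds <- rep(1:3, length.out = n)
    sel <- brute_force_select(oof, y, folds = folds, m = 5)
    expect_equal(sel$score, oracle_best_assembly_score(oof, y, folds, m = 5))
    expect_equal(sel$n_assemblies, 6 * choose(5, 3)^2)
  }
})

test_that("a planted perfectly separating net dominates the selection", {
  set.seed(5)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  oof <- matrix(runif(n * 10, -0.05, 0.05), n, 10)
  oof[, 7] <- 0.9 * y
  sel <- brute_force_select(oof, y, m = 5)
  expect_equal(sel$score, 1)
  members <- c(sel$positive, sel$negative)
  expect_true(7 %in% members)
  # selection only attains MCC 1 through assemblies dominated by the plant
  vals <- judge_values_from_matrix_test(oof, sel$gate, sel$positive, sel$negative)
  expect_equal(ifelse(vals >= 0, 1, -1), y)
})

test_that("ties break to the lexicographically earliest assembly", {
  # two identical perfect columns: assemblies using either score identically;
  # the earliest (gate 1, committees from the lowest indices) must win
  n <- 12
  y <- rep(c(-1, 1), length.out = n)
  oof <- cbind(y, y, y, y)
  colnames(oof) <- sprintf("n%d", 1:4)
  sel <- brute_force_select(oof, y, m = 4)
  expect_equal(sel$gate, 1L)
  expect_equal(sel$positive, c(1L, 2L, 3L))
  expect_equal(sel$negative, c(1L, 2L, 3L))
})

test_that("single-candidate pools and degenerate inputs behave as declared", {
  n <- 10
  y <- rep(c(-1, 1), length.out = n)
  oof1 <- matrix(y * 0.5, n, 3)
  sel <- brute_force_select(oof1, y, m = 3)
  expect_equal(sel$positive, c(1L, 2L, 3L))
  expect_error(brute_force_select(matrix(0, 5, 0), rep(1, 5)), "empty pool")
})

test_that("judge serialisation keeps all seven members", {
  fx <- make_pool_fixture(seed = 7)
  nets <- fx$pool$models
  j <- judge_model(nets[[1]], nets[c(1, 2, 3)], nets[c(2, 3, 4)],
                   provenance = list(scaling = "log_baseline_ratio"))
  parsed <- jsonlite::fromJSON(judge_to_json(j), simplifyVector = FALSE)
  expect_length(parsed$positive_committee, 3)
  expect_length(parsed$negative_committee, 3)
  expect_equal(parsed$provenance$scaling, "log_baseline_ratio")
})
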