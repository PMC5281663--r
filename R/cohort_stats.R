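#' Two-sample t-test for a continuous baseline characteristic
#'
#' Welch's unequal-variance test by default; the pooled-variance Student
#' test is available with `var_equal = TRUE`.
#'
#' @param sample_a,sample_b numeric vectors (each length >= 2, finite).
#' @param var_equal assume equal variances (pooled test)?
#' @return A one-row tibble: `statistic`, `df`, `p_value`, group means and
#'   the method label.
#' @export
t_test_independent <- function(sample_a, sample_b, var_equal = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b))) {
    abort("samples must be finite")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    abort("both samples have zero variance; t statistic undefined")
  }
  fit <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_a = mean(sample_a),
    mean_b = mean(sample_b),
    method = if (var_equal) "pooled t" else "Welch t"
  )
}

#' Fisher's exact test for a 2x2 table, by full enumeration
#'
#' The two-sided p-value follows the probability method: conditioning on
#' both margins, every feasible table's hypergeometric probability is
#' enumerated and those no more probable than the observed table are
#' summed. The odds ratio is the sample `ad/bc` (0 or `Inf` at zero
#' cells).
#'
#' @param table 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return A one-row tibble: `odds_ratio`, `p_value`, and the number of
#'   feasible tables enumerated.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) abort("`table` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all margins must be positive")
  }
  enum <- fisher_enumeration(tab)
  p_obs <- enum$prob[enum$a == tab[1, 1]]
  p <- sum(enum$prob[enum$prob <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble(
    odds_ratio = or,
    p_value = min(p, 1),
    n_tables = nrow(enum)
  )
}

#' Hypergeometric enumeration underlying the exact test
#'
#' All 2x2 tables with the given margins, with their conditional
#' (hypergeometric) probabilities; the probabilities sum to 1.
#'
#' @param table 2x2 matrix of counts (only its margins are used).
#' @return A tibble with the top-left count `a` of each feasible table and
#'   its probability `prob`.
#' @export
fisher_enumeration <- function(table) {
  tab <- as.matrix(table)
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a <- max(0L, c1 - r2):min(r1, c1)
  tibble(a = a, prob = stats::dhyper(a, r1, r2, c1))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Statistic `sum((O - E)^2 / E)` with expected counts from the margins,
#' `(r-1)(c-1)` degrees of freedom, upper-tail chi-square p-value. No
#' continuity correction by default; `correct = TRUE` applies the Yates
#' correction on 2x2 tables.
#'
#' @param table r x c matrix of non-negative counts with no all-zero row
#'   or column.
#' @param correct apply the Yates continuity correction (2x2 only)?
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) abort("`table` must be at least 2x2")
  if (any(tab < 0)) abort("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("table has an all-zero row or column")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - expected)
  if (correct && all(dim(tab) == c(2L, 2L))) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  tibble(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE)
  )
}

#' Baseline-characteristics comparison of two classes
#'
#' Reproduces the usual cohort table: for each baseline variable of the
#' metadata, a per-group summary and the appropriate test — independent t
#' for continuous variables (age, pack-years), Fisher's exact test for
#' binary variables (sex, food intake, current smoking), Pearson
#' chi-square for the multi-level variables (device serial, tumor stage).
#'
#' @param metadata patient metadata tibble.
#' @param groups length-2 character vector of class labels to compare.
#' @return A tibble with one row per characteristic: `variable`,
#'   per-group summaries (count or mean), `test` symbol and `p_value`.
#' @export
baseline_table <- function(metadata, groups = NULL) {
  if (is.null(groups)) {
    groups <- sort(unique(metadata$label))
    if (length(groups) != 2L) {
      abort("`groups` must name exactly two classes")
    }
  }
  for (g in groups) {
    if (!any(metadata$label == g)) abort(sprintf("group '%s' is empty", g))
  }
  a <- metadata[metadata$label == groups[1], , drop = FALSE]
  b <- metadata[metadata$label == groups[2], , drop = FALSE]

  safe_p <- function(expr) {
    tryCatch(expr, error = function(e) NA_real_)
  }
  binary_row <- function(variable, xa, xb) {
    tab <- rbind(c(sum(xa), sum(!xa)), c(sum(xb), sum(!xb)))
    tibble(
      variable = variable,
      summary_a = as.numeric(sum(xa)), summary_b = as.numeric(sum(xb)),
      test = "Fisher",
      p_value = safe_p(fisher_exact_2x2(tab)$p_value)
    )
  }
  continuous_row <- function(variable, xa, xb) {
    tibble(
      variable = variable,
      summary_a = mean(xa), summary_b = mean(xb),
      test = "t",
      p_value = safe_p(t_test_independent(xa, xb)$p_value)
    )
  }
  multilevel_row <- function(variable, xa, xb, levels) {
    tab <- cbind(
      vapply(levels, function(l) sum(xa == l), numeric(1)),
      vapply(levels, function(l) sum(xb == l), numeric(1))
    )
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    tibble(
      variable = variable,
      summary_a = as.numeric(length(xa)), summary_b = as.numeric(length(xb)),
      test = "chi-square",
      p_value = safe_p(pearson_chi_square(tab)$p_value)
    )
  }

  dplyr::bind_rows(
    tibble(
      variable = "n", summary_a = as.numeric(nrow(a)),
      summary_b = as.numeric(nrow(b)), test = NA_character_,
      p_value = NA_real_
    ),
    continuous_row("age", a$age, b$age),
    binary_row("sex_male", a$sex == "male", b$sex == "male"),
    binary_row("food_intake_lt4h", a$food_intake_lt4h, b$food_intake_lt4h),
    binary_row("currently_smoking", a$currently_smoking, b$currently_smoking),
    continuous_row("pack_years", a$pack_years, b$pack_years),
    multilevel_row("device_serial", a$device_serial, b$device_serial,
                   DEVICE_SERIALS),
    multilevel_row("tumor_stage", a$tumor_stage, b$tumor_stage, 0:4)
  )
}
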