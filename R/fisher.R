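# Exact and asymptotic tests of independence for 2x2 contingency tables.
# Fisher's exact test is computed from the hypergeometric null with fixed
# margins, via log-factorials; the two-sided p sums the probabilities of all
# feasible tables no more probable than the observed one.

#' Construct a 2x2 contingency table of core counts
#'
#' Cells follow the hypothesis-engine orientation: columns split cores by the
#' classifier (Core Collection A = hypothesis-describing values, Core
#' Collection B = complementary values), rows by the dependent property, so
#' the column-wise value distributions are the D1/D2 distributions the test
#' compares.
#'
#' @param n11 Cores with classifier and dependent both in their
#'   hypothesis-describing value sets.
#' @param n12 Classifier in complement, dependent in hypothesis set.
#' @param n21 Classifier in hypothesis set, dependent in complement.
#' @param n22 Both in complement.
#' @return An integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("cell counts must be non-negative integers",
      class = "tmatriad_domain_error"
    )
  }
  m <- matrix(as.integer(round(cells)), 2, 2,
    byrow = TRUE,
    dimnames = list(
      dependent = c("hypothesis", "complement"),
      classifier = c("hypothesis", "complement")
    )
  )
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Hypergeometric probability of a 2x2 table cell
#'
#' Probability that the top-left cell equals `a` when margins are fixed:
#' `P(A = a) = C(c1, a) C(n - c1, r1 - a) / C(n, r1)`, computed with
#' log-factorials for overflow safety.
#'
#' @param a Top-left cell count.
#' @param row1_total,col1_total First row / column margin.
#' @param n Table total.
#' @return A probability.
#' @export
hypergeometric_pmf <- function(a, row1_total, col1_total, n) {
  if (row1_total > n || col1_total > n || a < 0 ||
    a > min(row1_total, col1_total) ||
    a < row1_total + col1_total - n) {
    rlang::abort("infeasible cell count for the given margins",
      class = "tmatriad_domain_error"
    )
  }
  exp(
    lchoose(col1_total, a) + lchoose(n - col1_total, row1_total - a) -
      lchoose(n, row1_total)
  )
}

# pmf over the whole feasible range of the top-left cell, given margins
hypergeometric_support <- function(row1_total, col1_total, n) {
  lo <- max(0L, row1_total + col1_total - n)
  hi <- min(row1_total, col1_total)
  a <- lo:hi
  pmf <- exp(
    lchoose(col1_total, a) + lchoose(n - col1_total, row1_total - a) -
      lchoose(n, row1_total)
  )
  list(a = a, pmf = pmf)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test of independence under the hypergeometric null with fixed
#' margins. The two-sided p-value uses the probability-mass rule: it sums the
#' null probabilities of every feasible table whose probability does not
#' exceed the observed table's (with a 1e-7 relative tolerance absorbing
#' floating-point ties). One-sided alternatives sum the tail at or beyond the
#' observed top-left cell.
#'
#' @param table A [contingency_2x2()], or a 2x2 matrix / length-4 vector
#'   (row-major) of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of the top-left cell).
#' @return A tibble of class `tma_test_result` with columns `method`,
#'   `statistic` (NA for the exact test), `p_value` and a `table` attribute.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- as_table_matrix(table)
  n <- sum(m)
  if (n < 1) {
    rlang::abort("all-zero table: nothing to test",
      class = "tmatriad_domain_error"
    )
  }
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  sup <- hypergeometric_support(r1, c1, n)
  p_obs <- sup$pmf[sup$a == m[1, 1]]
  p <- switch(alternative,
    two.sided = sum(sup$pmf[sup$pmf <= p_obs * (1 + 1e-7)]),
    greater = sum(sup$pmf[sup$a >= m[1, 1]]),
    less = sum(sup$pmf[sup$a <= m[1, 1]])
  )
  test_result(
    method = paste0("Fisher's exact test (", alternative, ")"),
    statistic = NA_real_, p_value = min(p, 1), table = m
  )
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson statistic `sum((|O - E| - c)^2 / E)` with `c = 0.5` under the
#' Yates continuity correction (the correction term is floored so it never
#' exceeds `|O - E|`), referred to the chi-square distribution with one
#' degree of freedom.
#'
#' @inheritParams fisher_exact
#' @param yates_correction Apply the continuity correction (default off).
#' @return A `tma_test_result` tibble.
#' @export
chi_square <- function(table, yates_correction = FALSE) {
  m <- as_table_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("chi-square test requires all margins > 0",
      class = "tmatriad_domain_error"
    )
  }
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  dev <- abs(m - expected)
  if (yates_correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  test_result(
    method = paste0(
      "Pearson chi-square",
      if (yates_correction) " (Yates-corrected)" else ""
    ),
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    table = m
  )
}

as_table_matrix <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    m <- unclass(table)
  } else if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    m <- table
  } else if (is.numeric(table) && length(table) == 4) {
    m <- matrix(table, 2, 2, byrow = TRUE)
  } else {
    rlang::abort("expected a 2x2 table of counts",
      class = "tmatriad_domain_error"
    )
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    rlang::abort("cell counts must be non-negative integers",
      class = "tmatriad_domain_error"
    )
  }
  storage.mode(m) <- "double"
  m
}

test_result <- function(method, statistic, p_value, table) {
  out <- tibble::tibble(
    method = method, statistic = statistic, p_value = p_value
  )
  attr(out, "table") <- table
  class(out) <- c("tma_test_result", class(out))
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname fisher_exact
#' @param x A `tma_test_result`.
#' @param ... Unused.
#' @export
tidy.tma_test_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p.value = x$p_value
  )
}
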