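#' @keywords internal
test_result <- function(test, statistic, df = NA_real_, n = NA_integer_,
                        p_value = NA_real_, exact = NA) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), n = n, p_value = unname(p_value),
                 exact = exact),
            class = "bc_test")
}

#' @export
print.bc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g%s\n", x$test, x$statistic,
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}

# Exact null distribution of the rank sum of n1 items among N ranks:
# counts[s + 1] = number of size-n1 subsets of 1..N with sum s.
rank_sum_counts <- function(n1, N) {
  smax <- sum((N - n1 + 1):N)
  W <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  W[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, n1)))) {
      shifted <- c(rep(0, r), W[k, seq_len(smax + 1L - r)])
      W[k + 1L, ] <- W[k + 1L, ] + shifted
    }
  }
  W[n1 + 1L, ]
}

# Exact null distribution of the Wilcoxon signed-rank statistic for n
# untied ranks: counts[v + 1] = number of sign assignments with positive
# rank sum v.
signed_rank_counts <- function(n) {
  smax <- n * (n + 1) / 2
  counts <- numeric(smax + 1L)
  counts[1L] <- 1
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(smax + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

two_sided_from_counts <- function(counts, stat) {
  total <- sum(counts)
  pl <- sum(counts[seq_len(stat + 1L)]) / total
  pg <- sum(counts[(stat + 1L):length(counts)]) / total
  min(1, 2 * min(pl, pg))
}

#' Mann-Whitney / Wilcoxon rank tests (two-sided)
#'
#' Unpaired: the Mann-Whitney U test. The exact null distribution
#' (dynamic-programming enumeration of rank subsets) is used when
#' `n1 * n2 <= 400` and there are no ties; otherwise a normal
#' approximation with tie-corrected variance (no continuity correction).
#' Paired: the Wilcoxon signed-rank test (the conventional reading of a
#' "paired Mann-Whitney"), zero differences dropped, exact enumeration for
#' `n <= 50` untied absolute differences, tie-corrected normal
#' approximation otherwise. Always two-sided.
#'
#' @param x,y Numeric samples; equal lengths required when `paired`.
#' @param paired Use the signed-rank procedure on `x - y`.
#' @return A `bc_test` result: `test`, `statistic` (U, or V for paired),
#'   `n`, `p_value`, `exact`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values in samples")
  if (paired) {
    if (length(x) != length(y))
      stop("paired samples must have equal lengths")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
      return(test_result("Wilcoxon signed-rank", 0, n = 0L, p_value = 1,
                         exact = TRUE))
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    tied <- anyDuplicated(abs(d)) > 0L
    if (!tied && n <= 50L) {
      p <- two_sided_from_counts(signed_rank_counts(n), as.integer(V))
      return(test_result("Wilcoxon signed-rank", V, n = n, p_value = p,
                         exact = TRUE))
    }
    tie_tab <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sig2)
    return(test_result("Wilcoxon signed-rank", V, n = n,
                       p_value = min(1, 2 * stats::pnorm(-abs(z))),
                       exact = FALSE))
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tied <- anyDuplicated(c(x, y)) > 0L
  if (!tied && n1 * n2 <= 400L) {
    counts <- rank_sum_counts(n1, N)
    # shift from rank-sum to U
    offset <- n1 * (n1 + 1) / 2
    counts <- counts[(offset + 1L):length(counts)]
    p <- two_sided_from_counts(counts, as.integer(U))
    return(test_result("Mann-Whitney U", U, n = c(n1 = n1, n2 = n2),
                       p_value = p, exact = TRUE))
  }
  tie_tab <- table(r)
  mu <- n1 * n2 / 2
  sig2 <- (n1 * n2 / 12) *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 <= 0) stop("all observations identical; test undefined")
  z <- (U - mu) / sqrt(sig2)
  test_result("Mann-Whitney U", U, n = c(n1 = n1, n2 = n2),
              p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Friedman rank test for repeated measures (two-sided)
#'
#' Chi-squared-approximated Friedman statistic with tie correction over a
#' complete subjects-by-conditions matrix; `df = k - 1`. Missing cells are
#' an error (no imputation).
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions.
#' @return A `bc_test` result.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells in Friedman matrix")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(mat, 1L, rank))
  tie_term <- sum(apply(r, 1L, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {  # every row fully tied
    return(test_result("Friedman", 0, df = k - 1, n = n, p_value = 1,
                       exact = FALSE))
  }
  stat <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  test_result("Friedman", stat, df = k - 1, n = n,
              p_value = stats::pchisq(stat, df = k - 1,
                                      lower.tail = FALSE),
              exact = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sequentially rejective multiple-test correction: sorted p-values are
#' multiplied by `m, m-1, ..., 1`, enforced monotone non-decreasing,
#' capped at 1, and returned in the input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pearson chi-squared test with Yates continuity correction (2x2)
#'
#' `X^2 = sum((|O - E| - 0.5)^2 / E)` with the correction floored so that
#' `|O - E| - 0.5` is never negative (no over-correction on near-balanced
#' tables); `df = 1`, two-sided p from the chi-squared distribution.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A `bc_test` result.
#' @export
chi_squared_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  E <- outer(rs, cs) / sum(table)
  stat <- sum(pmax(0, abs(table - E) - 0.5)^2 / E)
  test_result("Pearson chi-squared (Yates)", stat, df = 1,
              n = sum(table),
              p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              exact = FALSE)
}

#' Holm-adjusted report over families of tests
#'
#' Applies [holm_bonferroni()] within each declared family (typically one
#' family per figure panel) and returns a tidy table.
#'
#' @param tests Data frame with at least columns `family` and `p_raw`;
#'   other columns (labels, statistics) are carried through.
#' @return The input with a `p_adjusted` column, ordered by family.
#' @export
family_report <- function(tests) {
  if (!nrow(tests)) {
    tests$p_adjusted <- numeric(0)
    return(tests)
  }
  stopifnot(all(c("family", "p_raw") %in% names(tests)))
  out <- do.call(rbind, lapply(split(tests, tests$family), function(s) {
    s$p_adjusted <- holm_bonferroni(s$p_raw)
    s
  }))
  rownames(out) <- NULL
  out
}
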