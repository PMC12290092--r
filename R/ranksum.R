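# Wilcoxon rank-sum (Mann-Whitney) comparison of per-session scalars.
# Small samples get an exact permutation p-value valid under ties (dynamic
# programming over the midrank multiset); larger samples use the normal
# approximation with tie-corrected variance and continuity correction.

# Exact null distribution of the rank-sum of the first sample: counts of
# subsets of size n1 of the pooled midranks attaining each possible sum.
# Midranks are multiples of 1/2, so doubling makes them integers and the DP
# is exact. Returns list(sums = attainable doubled sums, counts).
ranksum_exact_distribution <- function(ranks2, n1) {
  n <- length(ranks2)
  max_sum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  # dp[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, n1 + 1L, max_sum + 1L)
  dp[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in kmax:1L) {
      shifted <- c(rep(0, r), dp[k, seq_len(max_sum + 1L - r)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  sums <- which(dp[n1 + 1L, ] > 0) - 1L
  list(sums = sums, counts = dp[n1 + 1L, sums + 1L])
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test on two samples of per-session scalars. Midranks
#' handle ties. When `n1 + n2 <= exact_limit` the two-sided p-value is exact
#' under the permutation null (full distribution of the rank-sum over all
#' reassignments of the pooled values, correct also with ties); otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used. Two-sided p = `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_limit Use the exact distribution when `length(x) +
#'   length(y)` is at most this (default 25).
#' @return A list of class `ranksum_result`: `statistic` (rank-sum W of
#'   `x`), `p_two_sided`, `method` ("exact" or "normal_approx"), `n1`, `n2`.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
ranksum_test <- function(x, y, exact_limit = 25) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be nonempty.")
  if (any(!is.finite(c(x, y)))) abort("samples must be finite.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))           # midranks
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    dist <- ranksum_exact_distribution(ranks2, n1)
    total <- choose(n, n1)
    w2 <- as.integer(round(2 * w))
    p_lo <- sum(dist$counts[dist$sums <= w2]) / total
    p_hi <- sum(dist$counts[dist$sums >= w2]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    # continuity correction toward the mean
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = w, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s, n = %d vs %d)\n",
              x$statistic, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' Tidy a rank-sum result
#' @param x A `ranksum_result`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `method`, `n1`, `n2`.
#' @export
tidy.ranksum_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_two_sided,
         method = x$method, n1 = x$n1, n2 = x$n2)
}

#' @rdname tidy.ranksum_result
#' @export
glance.ranksum_result <- function(x, ...) tidy.ranksum_result(x)

#' Per-group mean and standard error
#'
#' @param values Numeric vector of per-session scalars.
#' @return One-row tibble: `mean`, `sem` (sample SD / sqrt(n), `NA` when
#'   n = 1), `n`.
#' @export
group_summary <- function(values) {
  n <- length(values)
  if (n < 1L) abort("group_summary needs at least one value.")
  tibble(mean = mean(values),
         sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
         n = n)
}
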