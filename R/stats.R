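#' Median and quartiles of a sample
#'
#' Quartiles by linear interpolation of order statistics at positions
#' `1 + (n - 1) p` (quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @return List of class `summary_stats` with `n`, `median`,
#'   `lower_quartile`, `upper_quartile`.
#' @export
#' @examples
#' summarize_values(c(1, 2, 3, 4, 5))
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("need a non-empty numeric vector without NA", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values), median = q[2L],
                 lower_quartile = q[1L], upper_quartile = q[3L]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, median = %g [Q1 %g, Q3 %g]\n",
              x$n, x$median, x$lower_quartile, x$upper_quartile))
  invisible(x)
}

# Exact null distribution of the rank sum: number of k-subsets of the
# given integer rank weights with each possible total. Midranks are
# handled by doubling (2 * midrank is always an integer), so the
# distribution is the conditional permutation distribution given the
# observed tie structure. Counts indexed by total 0..sum(weights).
rank_sum_counts <- function(weights, k) {
  maxsum <- sum(weights)
  f <- matrix(0, nrow = k + 1L, ncol = maxsum + 1L)
  f[1L, 1L] <- 1
  for (r in weights) {
    for (j in seq(k, 1L)) {
      cols <- seq(r + 1L, maxsum + 1L)
      f[j + 1L, cols] <- f[j + 1L, cols] + f[j, cols - r]
    }
  }
  f[k + 1L, ]
}

# Exact null distribution of W+ over all 2^n sign assignments of the
# given integer rank weights (product of polynomials 1 + z^r), indexed
# by W+ = 0..sum(weights). Ties enter through doubled midranks.
signed_rank_counts <- function(weights) {
  maxsum <- sum(weights)
  f <- numeric(maxsum + 1L)
  f[1L] <- 1
  for (r in weights) {
    shifted <- c(numeric(r), f[seq_len(maxsum + 1L - r)])
    f <- f + shifted
  }
  f
}

two_sided_from_counts <- function(counts, w) {
  total <- sum(counts)
  idx <- w + 1L  # counts indexed from statistic value 0
  lower <- sum(counts[seq_len(idx)]) / total
  upper <- sum(counts[seq(idx, length(counts))]) / total
  min(1, 2 * min(lower, upper))
}

normal_two_sided <- function(stat, mu, sigma2, continuity) {
  if (sigma2 <= 0) return(list(z = 0, p = 1))
  dev <- abs(stat - mu)
  if (continuity) dev <- max(dev - 0.5, 0)
  z <- dev / sqrt(sigma2)
  list(z = z, p = min(1, 2 * pnorm(-z)))
}

wilcoxon_result <- function(test, method, statistic, n, m = NULL,
                            continuity, tie_correction, p) {
  structure(list(test = test, method = method, statistic = statistic,
                 n = n, m = m, continuity_correction = continuity,
                 tie_correction = tie_correction,
                 p_two_sided = p),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon %s test (%s): statistic = %g, n = %d%s, p = %.3g\n",
              sub("_", "-", x$test), x$method, x$statistic, x$n,
              if (!is.null(x$m)) sprintf(", m = %d", x$m) else "",
              x$p_two_sided))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided two-sample location test on midranks. The statistic is the
#' rank sum W of the first sample. Exact mode evaluates the full
#' `choose(n + m, n)` labelling distribution; under ties it is the
#' conditional permutation distribution given the observed midrank
#' multiset. The normal approximation uses mean
#' `n (n + m + 1) / 2` and variance `n m (n + m + 1) / 12` minus the
#' standard tie correction `n m sum(t^3 - t) / (12 (n+m) (n+m-1))`, with
#' an optional 0.5 continuity correction toward the mean.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param method `"auto"` (exact when tie-free and `n + m <= 30`),
#'   `"exact"`, or `"normal_approx"`.
#' @param continuity Apply the continuity correction (normal mode).
#' @param tie_correction Apply the tie variance correction (normal mode).
#' @return A `wilcoxon_result` with the two-sided p-value.
#' @export
rank_sum_test <- function(x, y,
                          method = c("auto", "exact", "normal_approx"),
                          continuity = TRUE, tie_correction = TRUE) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L || anyNA(c(x, y)))
    stop("both samples must be non-empty and NA-free", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)

  if (method == "auto")
    method <- if (!has_ties && N <= 30L) "exact" else "normal_approx"

  if (method == "exact") {
    # doubled midranks keep the statistic integral under ties; the
    # distribution is then conditional on the observed tie structure
    counts <- rank_sum_counts(as.integer(round(2 * r)), n)
    p <- two_sided_from_counts(counts, as.integer(round(2 * W)))
    return(wilcoxon_result("rank_sum", "exact", W, n, m,
                           continuity = FALSE, tie_correction = has_ties,
                           p))
  }
  mu <- n * (N + 1) / 2
  sigma2 <- n * m * (N + 1) / 12
  if (tie_correction && has_ties)
    sigma2 <- sigma2 - n * m * sum(ties^3 - ties) / (12 * N * (N - 1))
  res <- normal_two_sided(W, mu, sigma2, continuity)
  wilcoxon_result("rank_sum", "normal_approx", W, n, m,
                  continuity, tie_correction, res$p)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test. Differences `d = x - y` (or `x` itself when
#' `y` is `NULL`); zero differences are dropped with a message. The
#' statistic is W+ , the sum of the midranks of `|d|` carrying positive
#' differences. Exact mode evaluates the full `2^n` sign-assignment
#' distribution (under tied magnitudes: conditionally on the observed
#' midranks); the normal approximation uses mean `n (n + 1) / 4`
#' and variance `n (n + 1) (2n + 1) / 24` minus the tie correction
#' `sum(t^3 - t) / 48` when `tie_correction` is on, with an optional 0.5
#' continuity correction toward the mean.
#'
#' @param x Numeric vector: first members of the pairs, or the paired
#'   differences when `y` is `NULL`.
#' @param y Optional numeric vector of second pair members.
#' @param method `"auto"` (exact when tie-free and `n <= 30`),
#'   `"exact"`, or `"normal_approx"`.
#' @param continuity Apply the continuity correction (normal mode).
#' @param tie_correction Apply the tie variance correction (normal mode).
#' @return A `wilcoxon_result` with the two-sided p-value.
#' @export
signed_rank_test <- function(x, y = NULL,
                             method = c("auto", "exact", "normal_approx"),
                             continuity = TRUE, tie_correction = TRUE) {
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) == 0L || anyNA(d))
    stop("need non-empty NA-free paired differences", call. = FALSE)
  nzero <- sum(d == 0)
  if (nzero > 0L) {
    message(nzero, " zero difference(s) dropped")
    d <- d[d != 0]
  }
  if (length(d) == 0L)
    stop("no nonzero pairs", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  Wplus <- sum(r[d > 0])
  ties <- table(abs(d))
  has_ties <- any(ties > 1L)

  if (method == "auto")
    method <- if (!has_ties && n <= 30L) "exact" else "normal_approx"

  if (method == "exact") {
    counts <- signed_rank_counts(as.integer(round(2 * r)))
    p <- two_sided_from_counts(counts, as.integer(round(2 * Wplus)))
    return(wilcoxon_result("signed_rank", "exact", Wplus, n,
                           continuity = FALSE, tie_correction = has_ties,
                           p = p))
  }
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  if (tie_correction && has_ties)
    sigma2 <- sigma2 - sum(ties^3 - ties) / 48
  res <- normal_two_sided(Wplus, mu, sigma2, continuity)
  wilcoxon_result("signed_rank", "normal_approx", Wplus, n,
                  continuity = continuity, tie_correction = tie_correction,
                  p = res$p)
}
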