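# Self-contained exact small-sample tests. Arm sizes in PDX trials are 4-7
# mice, so the exact enumeration path is the one real analyses take; the
# asymptotic path exists for larger pooled comparisons.

# Number of m-subsets of ranks 1..N attaining each rank sum, by subset-sum
# dynamic programming; column t+1 holds the count for rank sum t.
rank_sum_counts <- function(m, N) {
  max_sum <- sum((N - m + 1):N)
  dp <- matrix(0, nrow = m + 1, ncol = max_sum + 1)
  dp[1, 1] <- 1
  for (k in seq_len(N)) {
    for (i in min(m, k):1) {
      nz <- which(dp[i, ] > 0)
      nz <- nz[nz + k <= max_sum + 1]
      dp[i + 1, nz + k] <- dp[i + 1, nz + k] + dp[i, nz]
    }
  }
  dp[m + 1, ]
}

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# (m, n): probabilities for U = 0..m*n.
u_null_distribution <- function(m, n) {
  counts <- rank_sum_counts(m, m + n)
  # U = rank sum of x minus its minimum m(m+1)/2
  lo <- m * (m + 1) / 2
  p <- counts[(lo + 1):(lo + m * n + 1)]
  p / sum(p)
}

#' Two-tailed Mann-Whitney U test
#'
#' U counts the pairs `(x_i, y_j)` with `x_i > y_j`, plus half the tied
#' pairs. For tie-free data with combined sample size at most `exact_max_n`
#' the p-value is exact, from the full permutation distribution of U
#' (two-sided p = twice the smaller tail probability, capped at 1).
#' Otherwise a normal approximation with midranks, tie-corrected variance
#' and continuity correction is used; tied data below the switchover fall
#' back to the asymptotic path with a warning.
#'
#' @param x,y numeric samples.
#' @param exact_max_n largest combined sample size for the exact path
#'   (default 20).
#' @return list of class `pdx_test`: `statistic` (U of `x` versus `y`),
#'   `p_two_sided`, `method` (`"exact"` or `"asymptotic"`), `n_per_group`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.10
#' @export
mann_whitney <- function(x, y, exact_max_n = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    pdx_validation_error("both samples must be non-empty")
  if (anyNA(x) || anyNA(y))
    pdx_validation_error("samples must not contain missing values")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # = #(x>y) + 0.5 #(x==y)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && N <= exact_max_n) {
    pu <- u_null_distribution(m, n)
    u <- as.integer(round(U))
    p_lower <- sum(pu[seq_len(u + 1)])
    p_upper <- sum(pu[(u + 1):length(pu)])
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    if (ties && N <= exact_max_n)
      warning("ties present: falling back to the asymptotic Mann-Whitney path")
    mu <- m * n / 2
    tie_sizes <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
    if (sigma2 <= 0) {
      # all observations identical
      p <- 1
    } else {
      cc <- if (abs(U - mu) > 0.5) 0.5 else 0  # continuity correction
      z <- (abs(U - mu) - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "asymptotic"
  }
  structure(list(statistic = U, p_two_sided = p, method = method,
                 n_per_group = c(m, n), test = "Mann-Whitney U (two-tailed)"),
            class = "pdx_test")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by minimum-likelihood summation: with margins fixed,
#' the p-value is the total hypergeometric probability of every table whose
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance against floating-point noise).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list of class `pdx_test`: `statistic` (sample odds ratio),
#'   `p_two_sided`, `method = "exact"`, `n_per_group` (row totals).
#' @examples
#' fisher_exact(matrix(c(0, 5, 5, 0), 2))  # p = 2/252
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    pdx_validation_error("Fisher test requires a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || !all(is_whole(tab)))
    pdx_validation_error("table entries must be non-negative integers")
  tab <- round(tab)
  n <- sum(tab)
  if (n == 0) pdx_validation_error("table total must be positive")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  k <- max(0, r1 + c1 - n):min(r1, c1)     # support of the (1,1) cell
  pr <- dhyper(k, c1, n - c1, r1)
  p_obs <- pr[match(tab[1, 1], k)]
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(statistic = or, p_two_sided = p, method = "exact",
                 n_per_group = rowSums(tab), test = "Fisher's exact (two-sided)"),
            class = "pdx_test")
}

#' Compare responder rates between two treatments
#'
#' Applies [fisher_exact()] to a 2x2 responder / non-responder table, e.g.
#' from [orr_matrix()].
#'
#' @param tab 2x2 counts, rows = treatments, columns = responders /
#'   non-responders.
#' @return as [fisher_exact()].
#' @export
compare_orr <- function(tab) fisher_exact(tab)

#' @export
print.pdx_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (%s; n = %s)\n",
              x$test, x$statistic, x$p_two_sided, x$method,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}
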