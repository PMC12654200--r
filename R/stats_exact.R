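#' Mann-Whitney U statistic (first sample)
#'
#' `U = sum over pairs (a_i, b_j) of [a_i > b_j] + 0.5 * [a_i == b_j]` —
#' the tie-aware count of first-sample wins.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return U, a half-integer in `[0, n1*n2]`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

#' Exact two-sided Mann-Whitney p-value by enumeration
#'
#' Enumerates all `choose(n1+n2, n1)` assignments of the pooled observed
#' values to the two groups, computes the tie-aware U for each, and returns
#' `min(1, 2 * min(P(U <= u_obs), P(U >= u_obs)))`. Ties are handled
#' naturally through the observed-value enumeration. Restricted to
#' `n1 + n2 <= 20`; larger samples need a normal approximation, which is out
#' of scope here.
#'
#' @param a,b Numeric vectors.
#' @return Exact two-sided p-value.
#' @export
exact_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n > 20)
    stop("enumeration limited to n1 + n2 <= 20; use a large-sample approximation",
         call. = FALSE)
  pool <- c(a, b)
  u_obs <- mann_whitney_u(a, b)
  us <- enumerate_u(pool, n1)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# U statistic for every assignment of n1 of the pooled values to sample 1
enumerate_u <- function(pool, n1) {
  idx <- utils::combn(length(pool), n1)
  apply(idx, 2L, function(i) mann_whitney_u(pool[i], pool[-i]))
}

#' Rank-biserial correlation from U
#'
#' Effect size `r = 1 - 2U/(n1*n2)`: +1 when every first-sample value
#' exceeds every second-sample value, -1 for the reverse, 0 at the null
#' center.
#'
#' @param u U statistic of the first sample.
#' @param n1,n2 Sample sizes.
#' @return r in `[-1, 1]`.
#' @export
rank_biserial <- function(u, n1, n2) {
  stopifnot(u >= 0, u <= n1 * n2)
  1 - 2 * u / (n1 * n2)
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  tab
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Two-sided p by the point-probability rule: with margins fixed, sum the
#' hypergeometric probabilities of every table whose point probability does
#' not exceed that of the observed table (within a small relative slack for
#' floating-point equality of symmetric tables).
#'
#' @param tab 2x2 matrix of non-negative integer counts, positive margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-12) + 1e-300])
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic without continuity correction,
#' `X^2 = N (ad - bc)^2 / (row and column margins product)`, referred to the
#' chi-square distribution with 1 df.
#'
#' @param tab 2x2 matrix of non-negative counts, positive margins.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
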