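#' @import data.table
#' @importFrom stats dhyper pchisq rbinom rlnorm rpois runif setNames
#' @importFrom utils packageVersion
NULL

# Relative tolerance used when deciding whether an alternative table's
# hypergeometric probability is <= that of the observed table.  Without it
# the two-sided sum is platform-dependent at exact ties.
.FISHER_REL_TOL <- 1e-12

.check_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (length(v) != 4L || anyNA(v) || !is.numeric(v))
    stop("contingency table must be four numeric counts", call. = FALSE)
  if (any(v < 0)) stop("contingency table entries must be non-negative", call. = FALSE)
  if (any(v != round(v))) stop("contingency table entries must be integers", call. = FALSE)
  if (!all(is.finite(v))) stop("contingency table entries must be finite", call. = FALSE)
  as.numeric(round(v))
}

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided P-value for independence in a 2x2 table of
#' counts by summing, over all tables sharing the observed margins, the
#' hypergeometric probabilities that do not exceed the probability of the
#' observed table (ties compared with a relative tolerance of `1e-12`).
#' This is the probability-mass definition used throughout the package for
#' differential splicing, differential expression and term enrichment.
#'
#' @param table a 2x2 matrix, or a numeric vector `c(a, b, c, d)` read
#'   row-wise: row 1 is the control (CK) group, row 2 the stressed (S)
#'   group; column 1 holds the event/inclusion/hit count, column 2 the
#'   complement.
#' @return the two-sided P-value, a number in `[0, 1]`.  An all-zero table
#'   carries no evidence and returns 1.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' fisher_exact_2x2(c(5, 5, 5, 5))
#' @export
fisher_exact_2x2 <- function(table) {
  x <- if (is.matrix(table)) c(t(table)) else table
  x <- .check_2x2(x[1L], x[2L], x[3L], x[4L])
  a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  if (lo == hi) return(1)
  k <- lo:hi
  pr <- dhyper(k, r1, n - r1, c1)
  p_obs <- pr[a - lo + 1L]
  p <- sum(pr[pr <= p_obs * (1 + .FISHER_REL_TOL)])
  min(1, p)
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' One-degree-of-freedom Pearson chi-squared test of homogeneity.  The
#' continuity correction is off by default; it can be enabled where a more
#' conservative approximation is wanted.  Tables in which any expected cell
#' count is zero are degenerate for this statistic and raise an error
#' directing the caller to [fisher_exact_2x2()].
#'
#' @inheritParams fisher_exact_2x2
#' @param correct apply the Yates continuity correction?
#' @return a list with elements `statistic` and `p.value`.
#' @examples
#' chisq_2x2(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  x <- if (is.matrix(table)) c(t(table)) else table
  x <- .check_2x2(x[1L], x[2L], x[3L], x[4L])
  a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (n == 0 || any(e == 0))
    stop("degenerate table: an expected count is zero; use fisher_exact_2x2()",
         call. = FALSE)
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  dev <- abs(o - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: with p-values ranked increasingly,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values aligned with `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value collection", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Combine two P-values by a weighted arithmetic mean
#'
#' Returns `(w1 * p1 + w2 * p2) / (w1 + w2)`.  Used to merge the
#' junction-count and coverage Fisher tests of one splicing event into a
#' single score.  Weights default to equal; they are normalized internally
#' so only their ratio matters.
#'
#' @param p1,p2 p-values in `[0, 1]` (vectorized; recycled to a common
#'   length).
#' @param w1,w2 non-negative weights, not both zero.
#' @return the combined p-value(s) in `[0, 1]`.
#' @examples
#' combine_pvalues(0.2, 0.4)
#' @export
combine_pvalues <- function(p1, p2, w1 = 0.5, w2 = 0.5) {
  if (anyNA(c(w1, w2)) || w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop("invalid weights: need w1, w2 >= 0 and w1 + w2 > 0", call. = FALSE)
  if (anyNA(c(p1, p2)) || any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  (w1 * p1 + w2 * p2) / (w1 + w2)
}

#' Log2 fold change with pseudocount
#'
#' `log2((x_treat + pseudocount) / (x_ctrl + pseudocount))`.  Inputs must
#' already be depth-normalized by the caller; the pseudocount is always
#' applied, keeping the statistic finite and continuous at zero.
#'
#' @param x_treat,x_ctrl non-negative normalized expression values
#'   (vectorized).
#' @param pseudocount positive stabilizer added to both values.
#' @return the log2 fold change (treatment over control).
#' @examples
#' log2_fold_change(8, 2, pseudocount = 1e-9)
#' log2_fold_change(0, 4, 1)
#' @export
log2_fold_change <- function(x_treat, x_ctrl, pseudocount = 1) {
  if (anyNA(c(x_treat, x_ctrl)) || any(x_treat < 0) || any(x_ctrl < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (is.na(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  log2((x_treat + pseudocount) / (x_ctrl + pseudocount))
}
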