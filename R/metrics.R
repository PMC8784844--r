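#' Contingency table of two labelings
#'
#' @param a,b Equal-length label vectors (any atomic type).
#' @return Integer matrix of co-occurrence counts.
#' @export
contingency <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(a), length(b)))
  }
  unclass(table(a, b))
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two clusterings
#'
#' `I(a; b)` divided by the arithmetic mean of the two marginal entropies
#' (natural logs). Two degenerate single-cluster labelings agree perfectly
#' (returns 1); a single-cluster labeling against a non-trivial one carries
#' no information (returns 0).
#'
#' @param a,b Equal-length label vectors.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  if (n < 1L) stop("empty labelings")
  pa <- rowSums(ct) / n
  pb <- colSums(ct) / n
  ha <- .entropy(pa)
  hb <- .entropy(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pj <- ct / n
  mi <- 0
  nz <- which(pj > 0, arr.ind = TRUE)
  mi <- sum(pj[nz] * log(pj[nz] / (pa[nz[, 1L]] * pb[nz[, 2L]])))
  max(0, mi / mean(c(ha, hb)))
}

#' Hubert-Arabie adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance
#' under the permutation model:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`. Identical
#' partitions give 1; the expected value under random labelings is 0 (the
#' index can be negative). Degenerate cases where the denominator vanishes
#' (both all-singletons or both single-cluster) return 1.
#'
#' @param a,b Equal-length label vectors.
#' @return ARI, at most 1.
#' @export
ari <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(ct))
  sum_a <- sum(ch2(rowSums(ct)))
  sum_b <- sum(ch2(colSums(ct)))
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
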