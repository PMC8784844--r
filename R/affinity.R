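#' Pairwise Euclidean distances between cells
#'
#' Computes the full n x n Euclidean distance matrix over the gene
#' dimension, using the cross-product expansion
#' `d^2(i,j) = |x_i|^2 + |x_j|^2 - 2 x_i . x_j` so the heavy lifting is a
#' single BLAS `tcrossprod`. Exact (no nearest-neighbour approximation) for
#' the cell counts this package targets.
#'
#' @param X cells x genes numeric matrix.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 cells")
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0                       # numerical underflow guard
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Local scales: distance to the K-th nearest neighbour
#'
#' The self-tuning bandwidth of each cell is its distance to its K-th
#' nearest *other* cell (self excluded; K = 5 by default). A zero scale can
#' arise from duplicated cells; it is repaired with the smallest positive
#' distance in that cell's row, or a global epsilon if the whole row is
#' zero, with a warning.
#'
#' @param D Symmetric distance matrix.
#' @param K Neighbour rank defining the scale (default 5).
#' @return Strictly positive numeric vector of length n.
#' @export
local_scales <- function(D, K = 5L) {
  n <- nrow(D)
  if (K >= n) stop("K must be at most n - 1")
  sigma <- vapply(seq_len(n), function(i) {
    sort(D[i, -i], partial = K)[K]
  }, numeric(1))
  if (any(sigma == 0)) {
    eps <- 1e-12 * max(D)
    fix <- which(sigma == 0)
    for (i in fix) {
      pos <- D[i, ][D[i, ] > 0]
      sigma[i] <- if (length(pos)) min(pos) else eps
    }
    if (any(sigma == 0)) sigma[sigma == 0] <- max(eps, .Machine$double.eps)
    warning(length(fix), " cell(s) had zero local scale (duplicates); ",
            "replaced by the smallest positive distance")
  }
  names(sigma) <- rownames(D)
  sigma
}

#' Local-scaling affinity matrix
#'
#' Builds the self-tuned similarity
#' `W(i,j) = exp(-d^2(i,j) / (sigma_i * sigma_j))`. Because each distance is
#' measured relative to the geometric mean of the two local bandwidths, the
#' affinity is invariant to a uniform rescaling of the input coordinates and
#' adapts to local density. The diagonal is 1 by construction.
#'
#' @param D Symmetric distance matrix.
#' @param sigma Strictly positive local scales, length n.
#' @return An object of class `lssd_affinity`: a list with `W` (n x n
#'   symmetric, entries in (0, 1]), `sigma`, and `K_scale` (if `sigma`
#'   carries it).
#' @export
local_scaling_affinity <- function(D, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive; repair upstream")
  if (length(sigma) != nrow(D)) stop("sigma length must equal nrow(D)")
  W <- exp(-(D^2) / tcrossprod(sigma))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- dimnames(D)
  structure(list(W = W, sigma = sigma,
                 K_scale = attr(sigma, "K_scale", exact = TRUE)),
            class = "lssd_affinity")
}

#' Local-scaling affinity straight from an expression matrix
#'
#' Convenience wrapper: distances, local scales at rank `k_scale`, then the
#' self-tuned kernel.
#'
#' @param X cells x genes matrix.
#' @param k_scale Neighbour rank for the local bandwidth (default 5).
#' @return An `lssd_affinity` object; see [local_scaling_affinity()].
#' @export
affinity_graph <- function(X, k_scale = 5L) {
  D <- pairwise_euclidean(X)
  sigma <- local_scales(D, K = k_scale)
  attr(sigma, "K_scale") <- as.integer(k_scale)
  local_scaling_affinity(D, sigma)
}

#' @export
print.lssd_affinity <- function(x, ...) {
  cat(sprintf("Local-scaling affinity: %d cells, K_scale = %s\n",
              nrow(x$W), x$K_scale %||% "?"))
  cat(sprintf("  sigma range [%.4g, %.4g]\n", min(x$sigma), max(x$sigma)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.affinity_matrix <- function(W) {
  if (inherits(W, "lssd_affinity")) W$W else W
}
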