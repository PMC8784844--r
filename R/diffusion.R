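#' KNN-localized row-stochastic transition operator
#'
#' Restricts each cell's affinities to its `K_nn` strongest neighbours
#' (self excluded -- the diffusion's identity term restores
#' self-similarity) and row-normalizes, giving the transition probabilities
#' `P(i,j) = W(i,j) / sum_{k in knn(i)} W(i,k)` for `j` in `knn(i)` and 0
#' elsewhere. Zeroing similarities outside the neighbourhood encodes the
#' assumption that local neighbours are more reliable than remote ones.
#'
#' `K_nn` plays a different role from the `k_scale` of the bandwidths: one
#' tunes the kernel width, the other the support of the random walk. The
#' default `min(30, n - 1)` keeps the walk well connected at realistic cell
#' counts.
#'
#' @param W An `lssd_affinity` object or symmetric affinity matrix with
#'   strictly positive entries.
#' @param K_nn Neighbourhood size (default `min(30, n - 1)`).
#' @return An object of class `lssd_transition`: list with `P` (sparse
#'   `dgCMatrix`, rows sum to 1), `K_nn`, and `support` (per-row neighbour
#'   index list).
#' @export
build_transition <- function(W, K_nn = NULL) {
  Wm <- .affinity_matrix(W)
  n <- nrow(Wm)
  if (is.null(K_nn)) K_nn <- min(30L, n - 1L)
  K_nn <- as.integer(K_nn)
  if (K_nn < 1L || K_nn > n - 1L) stop("K_nn must be in [1, n - 1]")
  support <- vector("list", n)
  jj <- integer(n * K_nn)
  xx <- numeric(n * K_nn)
  for (i in seq_len(n)) {
    w <- Wm[i, ]
    w[i] <- -Inf
    nb <- sort.int(order(w, decreasing = TRUE)[seq_len(K_nn)])
    vals <- Wm[i, nb]
    tot <- sum(vals)
    stopifnot(tot > 0)    # cannot occur for a strictly positive kernel
    idx <- (i - 1L) * K_nn + seq_len(K_nn)
    jj[idx] <- nb
    xx[idx] <- vals / tot
    support[[i]] <- nb
  }
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), each = K_nn), j = jj, x = xx,
                            dims = c(n, n), dimnames = dimnames(Wm))
  structure(list(P = P, K_nn = K_nn, support = support),
            class = "lssd_transition")
}

#' Regularized self-diffusion of the affinity graph
#'
#' Iterates `S_{t+1} = tau * S_t %*% P + (1 - tau) * I` for `t` steps from
#' `S_0 = W`. Each step propagates similarity mass along the localized
#' random walk while the `(1 - tau) I` term anchors every cell to itself,
#' so within-cluster edges accumulate weight and weak spurious edges decay.
#' Too many steps over-smooth; `t = 4` is the default working point.
#'
#' @param W Initial similarity (an `lssd_affinity` or matrix).
#' @param P An `lssd_transition` (or row-stochastic matrix) on the same
#'   cells.
#' @param t Number of diffusion steps (non-negative integer; `t = 0`
#'   returns `W` unchanged). Default 4.
#' @param tau Regularization weight in (0, 1); default 0.8.
#' @return An object of class `lssd_diffusion`: list with `S` (n x n,
#'   non-negative, generally asymmetric), `t`, `tau`, `K_nn`.
#' @export
self_diffuse <- function(W, P, t = 4L, tau = 0.8) {
  Wm <- .affinity_matrix(W)
  K_nn <- if (inherits(P, "lssd_transition")) P$K_nn else NA_integer_
  Pm <- if (inherits(P, "lssd_transition")) P$P else P
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly inside (0, 1)")
  if (t < 0L) stop("t must be non-negative")
  n <- nrow(Wm)
  S <- Wm
  if (t >= 1L) {
    for (step in seq_len(t)) {
      S <- tau * as.matrix(S %*% Pm)
      diag(S) <- diag(S) + (1 - tau)
    }
    dimnames(S) <- dimnames(Wm)
  }
  structure(list(S = S, t = as.integer(t), tau = tau, K_nn = K_nn),
            class = "lssd_diffusion")
}

#' Symmetrize a diffused similarity
#'
#' The diffusion output is asymmetric because `P` is row-normalized;
#' spectral analysis needs a symmetric input, so this returns
#' `(S + t(S)) / 2`.
#'
#' @param S An `lssd_diffusion` object or a square matrix.
#' @return Symmetric matrix of the same size.
#' @export
symmetrize <- function(S) {
  Sm <- if (inherits(S, "lssd_diffusion")) S$S else S
  if (nrow(Sm) != ncol(Sm)) stop("matrix must be square")
  (Sm + t(Sm)) / 2
}

#' @export
print.lssd_diffusion <- function(x, ...) {
  cat(sprintf("Self-diffused graph: %d cells, t = %d, tau = %.2f, K_nn = %s\n",
              nrow(x$S), x$t, x$tau, x$K_nn))
  invisible(x)
}
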