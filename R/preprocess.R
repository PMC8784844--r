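#' Select highly variable genes by the variance-to-mean ratio
#'
#' Ranks genes by their dispersion (variance / mean, computed across cells
#' on the matrix as given, i.e. on the count scale) and keeps the `n_top`
#' most dispersed. Genes with zero mean are treated as uninformative
#' (dispersion 0) and never selected while a variable gene remains. Ties are
#' broken toward the smaller gene index, and the original gene order is
#' preserved among the kept set, so the selection is deterministic and
#' idempotent.
#'
#' @param X cells x genes matrix.
#' @param n_top Number of genes to keep.
#' @return `X` restricted to the selected genes.
#' @export
select_hvg_vmr <- function(X, n_top) {
  if (n_top < 1L) stop("n_top must be >= 1")
  Xd <- as.matrix(X)
  mu <- colMeans(Xd)
  v <- apply(Xd, 2L, stats::var)   # unbiased, n - 1 denominator
  disp <- ifelse(mu > 0, v / mu, 0)
  informative <- sum(disp > 0)
  if (n_top > informative) {
    stop(sprintf("requested %d genes but only %d have positive dispersion",
                 n_top, informative))
  }
  keep <- sort(order(-disp, seq_along(disp))[seq_len(n_top)])
  X[, keep, drop = FALSE]
}

#' Shifted-log transform of an expression matrix
#'
#' Elementwise `log(x + pseudo_count)`; a standard variance-stabilizing
#' option before Euclidean distance computation on counts.
#'
#' @param X cells x genes matrix of non-negative values.
#' @param pseudo_count Positive shift added before the log (default 1, so
#'   zeros map to zero).
#' @return Transformed matrix, same shape and dimnames.
#' @export
log1p_transform <- function(X, pseudo_count = 1) {
  if (pseudo_count <= 0) stop("pseudo_count must be positive")
  Xd <- as.matrix(X)
  if (any(Xd < 0)) stop("negative entries: log transform expects counts or non-negative expression")
  out <- log(Xd + pseudo_count)
  dimnames(out) <- dimnames(Xd)
  out
}
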