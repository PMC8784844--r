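#' Spectral clustering on a (diffused) similarity graph
#'
#' Normalized-cut spectral clustering: the `C` smallest eigenvectors of the
#' symmetric normalized Laplacian are row-normalized to the unit sphere and
#' partitioned with k-means (25 restarts under a fixed seed). Labels are
#' relabeled to first-appearance order so the output is deterministic given
#' `(S_sym, C, seed)`.
#'
#' @param S_sym Symmetric non-negative similarity with positive degrees
#'   (typically `symmetrize(self_diffuse(...))`).
#' @param C Number of clusters (>= 2).
#' @param seed RNG seed for the k-means restarts (default 0).
#' @param method Eigen-solver passed to [laplacian_eigenvectors()].
#' @return An object of class `lssd_clusters`: list with `labels` (integer
#'   vector in 1..C, named by cell), `C`, `seed`, and `provenance`.
#' @export
spectral_cluster <- function(S_sym, C, seed = 0L, method = "auto") {
  n <- nrow(S_sym)
  if (C < 2L) stop("C must be at least 2")
  if (C > n) stop("C cannot exceed the number of cells")
  # a few extra eigenvalues so extra connected components are detectable
  V <- laplacian_eigenvectors(S_sym, min(n, C + 3L), method = method)
  vals <- attr(V, "values")
  n_comp <- sum(vals > 1 - 1e-8)
  if (n_comp > C) {
    warning("graph has at least ", n_comp, " connected components but C = ", C)
  }
  U <- .row_normalize(V[, seq_len(C), drop = FALSE])
  km <- NULL
  for (attempt in 0:4) {
    km <- .with_preserved_seed(as.integer(seed) + attempt, {
      stats::kmeans(U, centers = C, nstart = 25L, iter.max = 100L)
    })
    if (all(tabulate(km$cluster, C) > 0L)) break
  }
  labels <- .first_appearance_relabel(km$cluster)
  names(labels) <- rownames(S_sym)
  structure(list(labels = labels, C = as.integer(C), seed = as.integer(seed),
                 provenance = list(method = method)),
            class = "lssd_clusters")
}

# relabel so cluster ids appear in order of first occurrence (determinism)
.first_appearance_relabel <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  as.integer(out)
}

#' @export
print.lssd_clusters <- function(x, ...) {
  cat(sprintf("Cluster solution: %d cells in %d clusters\n",
              length(x$labels), x$C))
  print(table(cluster = x$labels))
  if (!is.null(x$curve)) cat("chosen C =", x$curve$chosen_C,
                             "(separation-cost estimate)\n")
  invisible(x)
}
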