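#' Full LSSD clustering of an expression matrix
#'
#' Runs the whole method in memory: optional gene filtering and log
#' transform, local-scaling affinity, KNN-localized transition operator,
#' regularized self-diffusion, symmetrization, optional cluster-number
#' estimation by separation cost, and spectral clustering.
#'
#' @param X cells x genes expression matrix.
#' @param k_scale Neighbour rank of the local bandwidth (default 5).
#' @param knn Transition-operator support size (default `min(30, n - 1)`).
#' @param tau Diffusion regularization in (0, 1) (default 0.8).
#' @param steps Diffusion iterations (default 4).
#' @param n_clusters Number of clusters; if `NULL`, estimated by
#'   [estimate_C()] over `[cmin, cmax]`.
#' @param cmin,cmax Candidate range for the estimate (defaults 2, 15).
#' @param hvg If non-`NULL`, keep this many highly variable genes by
#'   variance-to-mean ratio before anything else.
#' @param log1p Apply [log1p_transform()] before distance computation
#'   (default `FALSE`: distances are computed on the matrix as given).
#' @param seed Seed for the k-means stage (default 0).
#' @param return_graph Keep the diffused symmetric graph in the result
#'   (default `FALSE`; it is n x n).
#' @return An `lssd_clusters` object with `labels`, `C`, `curve` (when
#'   estimated), `provenance` (all parameters), and optionally `S`.
#' @export
lssd_cluster <- function(X, k_scale = 5L, knn = NULL, tau = 0.8, steps = 4L,
                         n_clusters = NULL, cmin = 2L, cmax = 15L,
                         hvg = NULL, log1p = FALSE, seed = 0L,
                         return_graph = FALSE) {
  if (!is.null(hvg)) X <- select_hvg_vmr(X, hvg)
  if (log1p) X <- log1p_transform(X)
  W <- affinity_graph(X, k_scale = k_scale)
  P <- build_transition(W, K_nn = knn)
  S <- symmetrize(self_diffuse(W, P, t = steps, tau = tau))
  curve <- NULL
  if (is.null(n_clusters)) {
    curve <- estimate_C(S, C_min = cmin, C_max = cmax)
    n_clusters <- curve$chosen_C
  }
  out <- spectral_cluster(S, C = n_clusters, seed = seed)
  out$curve <- curve
  out$provenance <- list(k_scale = as.integer(k_scale), K_nn = P$K_nn,
                         tau = tau, steps = as.integer(steps),
                         hvg = hvg, log1p = log1p, seed = as.integer(seed))
  if (return_graph) out$S <- S
  out
}

#' Assemble and validate a pipeline run configuration
#'
#' @param input Path readable by [read_expression()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @param orientation Input layout, see [read_expression()].
#' @param write_graph_file Also export the diffused graph as dense TSV.
#' @param write_curve Also export the separation-cost curve as TSV.
#' @inheritParams lssd_cluster
#' @return Validated list of class `lssd_config`.
#' @export
lssd_config <- function(input, out_dir, orientation = "cells_as_rows",
                        k_scale = 5L, knn = NULL, tau = 0.8, steps = 4L,
                        n_clusters = NULL, cmin = 2L, cmax = 15L,
                        hvg = NULL, log1p = FALSE, seed = 0L,
                        write_graph_file = FALSE, write_curve = FALSE) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly inside (0, 1)")
  if (steps < 0) stop("steps must be non-negative")
  if (!is.null(n_clusters) && n_clusters < 2) stop("n_clusters must be >= 2")
  structure(as.list(environment()), class = "lssd_config")
}

#' Run the pipeline from files to files
#'
#' Reads the expression matrix, runs [lssd_cluster()], and writes the label
#' TSV, an optional diffused-graph export, an optional separation-cost
#' curve, and a JSON manifest recording every parameter, the package
#' version and the seed -- enough to reproduce the run. On any error the
#' partially written output directory is removed (if this call created it)
#' and the error is re-thrown.
#'
#' @param config An `lssd_config`.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lssd_config"))
  created <- !dir.exists(config$out_dir)
  if (created) dir.create(config$out_dir, recursive = TRUE)
  tryCatch({
    X <- read_expression(config$input, orientation = config$orientation)
    res <- lssd_cluster(X, k_scale = config$k_scale, knn = config$knn,
                        tau = config$tau, steps = config$steps,
                        n_clusters = config$n_clusters, cmin = config$cmin,
                        cmax = config$cmax, hvg = config$hvg,
                        log1p = config$log1p, seed = config$seed,
                        return_graph = isTRUE(config$write_graph_file))
    write_labels(res$labels, rownames(X), file.path(config$out_dir, "labels.tsv"))
    if (isTRUE(config$write_graph_file)) {
      write_graph(res$S, rownames(X), file.path(config$out_dir, "graph.tsv"),
                  format = "dense_tsv")
    }
    if (isTRUE(config$write_curve) && !is.null(res$curve)) {
      utils::write.table(
        data.frame(C = res$curve$candidates, J = res$curve$J_values),
        file.path(config$out_dir, "separation_cost.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- c(config[setdiff(names(config), c())],
                  list(C = res$C,
                       chosen_by_curve = !is.null(res$curve),
                       n_cells = nrow(X), n_genes = ncol(X),
                       package_version = as.character(utils::packageVersion("lssd"))))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
    invisible(config$out_dir)
  }, error = function(e) {
    if (created) unlink(config$out_dir, recursive = TRUE)
    stop(e)
  })
}
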