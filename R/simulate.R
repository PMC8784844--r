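#' Parameters for the grouped scRNA-seq count simulator
#'
#' Bundles and validates the generative parameters of [simulate_counts()].
#' The model follows the structure of the widely used parametric scRNA-seq
#' simulators: gamma-distributed baseline gene means, log-normal
#' differential-expression multipliers applied per group, log-normal library
#' sizes, negative-binomial counts, and logistic mean-dependent dropout.
#'
#' @param n_cells,n_genes,n_groups Dataset dimensions.
#' @param group_props Group proportions on the simplex (default uniform).
#' @param mean_shape,mean_rate Gamma prior on baseline gene means
#'   (defaults 0.6, 0.3).
#' @param de_prob Probability a gene is differentially expressed in a given
#'   group (default 0.1).
#' @param de_fac_loc,de_fac_scale Location/scale of the log-normal DE
#'   multiplier; the sign of the log-factor is random, so genes are up- or
#'   down-regulated symmetrically (defaults 1.0, 0.4).
#' @param lib_loc,lib_scale Log-normal library-size parameters
#'   (defaults 11, 0.2: mean depth around `exp(11) ~ 60k` reads).
#' @param bcv Biological coefficient of variation; the negative-binomial
#'   dispersion is `bcv^2`, constant across genes (default 0.2).
#' @param dropout_mid,dropout_shape Logistic dropout midpoint (on the
#'   log-mean scale) and slope (defaults 1.5, -1: low-mean entries are
#'   zeroed more often).
#' @param seed RNG seed; the simulation is fully determined by it.
#' @return A validated list of class `lssd_sim_params`.
#' @export
sim_params <- function(n_cells, n_genes, n_groups,
                       group_props = NULL,
                       mean_shape = 0.6, mean_rate = 0.3,
                       de_prob = 0.1, de_fac_loc = 1.0, de_fac_scale = 0.4,
                       lib_loc = 11, lib_scale = 0.2,
                       bcv = 0.2,
                       dropout_mid = 1.5, dropout_shape = -1,
                       seed = 0L) {
  if (is.null(group_props)) group_props <- rep(1 / n_groups, n_groups)
  if (length(group_props) != n_groups ||
      any(group_props < 0) || abs(sum(group_props) - 1) > 1e-8) {
    stop("group_props must be a length-n_groups vector summing to 1")
  }
  if (n_groups > n_cells) stop("more groups than cells")
  stopifnot(mean_shape > 0, mean_rate > 0, de_prob >= 0, de_prob <= 1,
            de_fac_scale > 0, lib_scale > 0, bcv > 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_groups = as.integer(n_groups), group_props = group_props,
                 mean_shape = mean_shape, mean_rate = mean_rate,
                 de_prob = de_prob, de_fac_loc = de_fac_loc,
                 de_fac_scale = de_fac_scale, lib_loc = lib_loc,
                 lib_scale = lib_scale, bcv = bcv,
                 dropout_mid = dropout_mid, dropout_shape = dropout_shape,
                 seed = as.integer(seed)),
            class = "lssd_sim_params")
}

#' Simulate grouped scRNA-seq counts with dropout
#'
#' Generative model, per [sim_params()]:
#' 1. baseline gene means `lambda_g ~ Gamma(mean_shape, rate = mean_rate)`;
#' 2. for each group, each gene is differentially expressed with
#'    probability `de_prob`, receiving multiplier
#'    `exp(s * N(de_fac_loc, de_fac_scale))` with random sign `s`;
#' 3. cell `c` in group `h` has expected expression proportional to
#'    `lambda_g * fac_{g,h}`, rescaled so its expected total equals the
#'    library size `L_c ~ LogNormal(lib_loc, lib_scale)`;
#' 4. counts `~ NB(mean = mu_gc, dispersion = bcv^2)`;
#' 5. dropout: each entry is zeroed with probability
#'    `plogis(dropout_shape * (log(mu_gc) - dropout_mid))`.
#'
#' @param params An `lssd_sim_params` object.
#' @return List of class `lssd_sim` with `counts` (cells x genes integer
#'   matrix with cell/gene ids), `labels` (integer group per cell, 1-based),
#'   and `params`.
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "lssd_sim_params"))
  p <- params
  .with_preserved_seed(p$seed, {
    lambda <- stats::rgamma(p$n_genes, shape = p$mean_shape, rate = p$mean_rate)
    labels <- sample(rep(seq_len(p$n_groups),
                         times = .group_sizes(p$n_cells, p$group_props)))
    fac <- matrix(1, p$n_genes, p$n_groups)
    for (h in seq_len(p$n_groups)) {
      is_de <- stats::runif(p$n_genes) < p$de_prob
      k <- sum(is_de)
      if (k > 0) {
        sgn <- sample(c(-1, 1), k, replace = TRUE)
        fac[is_de, h] <- exp(sgn * stats::rnorm(k, p$de_fac_loc, p$de_fac_scale))
      }
    }
    lib <- stats::rlnorm(p$n_cells, meanlog = p$lib_loc, sdlog = p$lib_scale)
    group_mean <- lambda * fac[, labels, drop = FALSE]       # genes x cells
    group_tot <- colSums(group_mean)
    mu <- sweep(group_mean, 2L, lib / group_tot, "*")
    size <- 1 / p$bcv^2                                      # NB: var = mu + bcv^2 mu^2
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                     p$n_genes, p$n_cells)
    drop_p <- stats::plogis(p$dropout_shape * (log(mu) - p$dropout_mid))
    keep <- matrix(stats::runif(length(mu)) >= drop_p, p$n_genes, p$n_cells)
    counts <- counts * keep
    counts <- t(counts)                                      # cells x genes
    dimnames(counts) <- list(sprintf("cell%04d", seq_len(p$n_cells)),
                             sprintf("gene%05d", seq_len(p$n_genes)))
    structure(list(counts = counts, labels = as.integer(labels), params = p),
              class = "lssd_sim")
  })
}

.group_sizes <- function(n, props) {
  sizes <- floor(n * props)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * props - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

#' @export
print.lssd_sim <- function(x, ...) {
  cat(sprintf("Simulated counts: %d cells x %d genes, %d groups, seed %d\n",
              nrow(x$counts), ncol(x$counts), x$params$n_groups,
              x$params$seed))
  cat(sprintf("  sparsity %.1f%%\n", 100 * mean(x$counts == 0)))
  invisible(x)
}

#' Sweep the number of diffusion steps on one simulated dataset
#'
#' Simulates once, builds the affinity and transition operator once, then
#' re-runs the diffusion, clustering and concordance metrics for each
#' requested step count. This is the experiment used to pick the working
#' number of iterations: concordance rises as diffusion denoises the graph
#' and falls again when it over-smooths.
#'
#' @param t_values Diffusion step counts to evaluate (default 2:15).
#' @param params An `lssd_sim_params` object.
#' @param k_scale,knn,tau Graph parameters (see [affinity_graph()],
#'   [build_transition()], [self_diffuse()]).
#' @param log1p Apply [log1p_transform()] to counts before distances
#'   (default FALSE: distances on counts as given).
#' @param seed Clustering seed.
#' @return `data.frame` with columns `t`, `nmi`, `ari`.
#' @export
step_sweep <- function(t_values = 2:15, params, k_scale = 5L, knn = NULL,
                       tau = 0.8, log1p = FALSE, seed = 0L) {
  stopifnot(length(t_values) > 0, all(t_values >= 1))
  sim <- simulate_counts(params)
  X <- if (log1p) log1p_transform(sim$counts) else sim$counts
  W <- affinity_graph(X, k_scale = k_scale)
  P <- build_transition(W, K_nn = knn)
  res <- lapply(t_values, function(t) {
    S <- symmetrize(self_diffuse(W, P, t = t, tau = tau))
    cl <- spectral_cluster(S, C = params$n_groups, seed = seed)
    data.frame(t = t, nmi = nmi(cl$labels, sim$labels),
               ari = ari(cl$labels, sim$labels))
  })
  do.call(rbind, res)
}

#' Sweep the number of cells at fixed generative parameters
#'
#' For each requested size, simulates a dataset, runs the full pipeline,
#' and records concordance with the planted labels plus wall time.
#'
#' @param sizes Cell counts to evaluate.
#' @param params Template `lssd_sim_params`; `n_cells` is overridden per
#'   size (seed offset by the size index so replicates differ).
#' @param k_scale,knn,tau,steps,log1p,seed Pipeline parameters.
#' @return `data.frame` with columns `n_cells`, `nmi`, `ari`, `seconds`.
#' @export
scaling_sweep <- function(sizes, params, k_scale = 5L, knn = NULL, tau = 0.8,
                          steps = 4L, log1p = FALSE, seed = 0L) {
  stopifnot(length(sizes) > 0)
  res <- lapply(seq_along(sizes), function(i) {
    p <- params
    p$n_cells <- as.integer(sizes[i])
    p$seed <- params$seed + i - 1L
    sim <- simulate_counts(p)
    t0 <- proc.time()[["elapsed"]]
    X <- if (log1p) log1p_transform(sim$counts) else sim$counts
    W <- affinity_graph(X, k_scale = k_scale)
    P <- build_transition(W, K_nn = knn)
    S <- symmetrize(self_diffuse(W, P, t = steps, tau = tau))
    cl <- spectral_cluster(S, C = p$n_groups, seed = seed)
    el <- proc.time()[["elapsed"]] - t0
    data.frame(n_cells = p$n_cells, nmi = nmi(cl$labels, sim$labels),
               ari = ari(cl$labels, sim$labels), seconds = el)
  })
  do.call(rbind, res)
}
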