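# Shared fixtures and independent oracles, all built in code.

# exact block-diagonal affinity with k equal all-ones blocks
block_affinity <- function(k, size = 20L) {
  n <- k * size
  W <- matrix(0, n, n)
  for (b in seq_len(k)) {
    idx <- ((b - 1L) * size + 1L):(b * size)
    W[idx, idx] <- 1
  }
  dimnames(W) <- list(paste0("c", seq_len(n)), paste0("c", seq_len(n)))
  W
}

# k Gaussian blobs at moderate separation; returns matrix + planted labels
blob_matrix <- function(k = 3L, per = 100L, d = 4L, sep = 3, seed = 7L) {
  centers <- sep * (seq_len(k) - (k + 1) / 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(m)
    matrix(rnorm(per * d, mean = m), ncol = d)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rownames(X) <- paste0("c", seq_len(k * per))
  colnames(X) <- paste0("g", seq_len(d))
  list(X = X, labels = rep(seq_len(k), each = per))
}

# noisy planted block similarity: strong within-block, weak between-block
# entries, moderate coupling (non-degenerate eigenstructure)
noisy_block_affinity <- function(k, size, seed, w_in = c(0.5, 0.9),
                                 w_bt = c(0.05, 0.2)) {
  n <- k * size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  W <- matrix(runif(n * n, w_bt[1], w_bt[2]), n)
  for (b in seq_len(k)) {
    idx <- ((b - 1L) * size + 1L):(b * size)
    W[idx, idx] <- runif(size^2, w_in[1], w_in[2])
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(paste0("c", seq_len(n)), paste0("c", seq_len(n)))
  W
}

# Hubert-Arabie ARI straight from pair counting, independent of any
# contingency-table code: classify every unordered pair of cells.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  grow <- function(labels) {
    if (length(labels) == n) return(list(labels))
    m <- max(labels)
    unlist(lapply(seq_len(m + 1L), function(v) grow(c(labels, v))),
           recursive = FALSE)
  }
  grow(1L)
}

# mean within-block / mean between-block similarity ratio
block_contrast <- function(S, labels) {
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(S[same & !is.na(same)]) / mean(S[!same & !is.na(same)])
}
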