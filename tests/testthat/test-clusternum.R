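test_that("Laplacian eigenvectors expose disconnected structure and stay orthonormal", {
  W <- block_affinity(2, size = 15)
  V <- laplacian_eigenvectors(W, 4)
  vals <- attr(V, "values")
  # two components: two unit eigenvalues of the normalized similarity
  expect_equal(vals[1:2], c(1, 1), tolerance = 1e-8)
  expect_lt(vals[3], 1 - 1e-6)
  expect_equal(crossprod(V), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Lanczos and dense eigensolvers agree on a random similarity", {
  set.seed(31)
  S <- crossprod(matrix(runif(100), 10, 10)) + diag(10)
  dimnames(S) <- list(paste0("c", 1:10), paste0("c", 1:10))
  Vd <- laplacian_eigenvectors(S, 3, method = "dense")
  Va <- laplacian_eigenvectors(S, 3, method = "arpack")
  expect_equal(attr(Va, "values"), attr(Vd, "values"), tolerance = 1e-8)
  # same invariant subspace: projectors match
  expect_equal(tcrossprod(Va), tcrossprod(Vd), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("zero-degree cells are reported by name", {
  S <- diag(c(1, 1, 0))
  dimnames(S) <- list(c("a", "b", "lonely"), c("a", "b", "lonely"))
  expect_error(laplacian_eigenvectors(S, 2), "lonely")
})

test_that("separation cost is minimal on indicators and counts every term", {
  set.seed(13)
  Z <- diag(4)[sample(1:4, 11, replace = TRUE), ]
  expect_equal(rotation_cost(Z), 11)
  expect_equal(rotation_cost(matrix(1, 7, 3)), 21)
  # row scaling cancels
  Z2 <- Z * runif(11, 0.1, 9)
  expect_equal(rotation_cost(Z2), 11)
  # invariant to column permutation and sign flips
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(rotation_cost(M[, c(3, 1, 2)]), rotation_cost(M))
  expect_equal(rotation_cost(M %*% diag(c(-1, 1, -1))), rotation_cost(M))
  expect_error(rotation_cost(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("rotation optimization recovers indicator structure", {
  set.seed(17)
  B <- diag(2)[sample(1:2, 40, replace = TRUE), ]   # exact indicator, unit rows
  res <- optimal_rotation(B)
  expect_equal(res$J, 40, tolerance = 1e-9)
  expect_equal(res$R, diag(2), tolerance = 1e-6)

  # a known 30-degree mixing is undone
  th <- pi / 6
  R30 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  res2 <- optimal_rotation(B %*% R30)
  expect_equal(res2$J, 40, tolerance = 1e-4)

  # never worse than the unrotated start
  X <- matrix(rnorm(60), 20, 3)
  X <- X / sqrt(rowSums(X^2))
  expect_lte(optimal_rotation(X)$J, rotation_cost(X) + 1e-9)
})

test_that("separation-cost curve recovers planted block counts", {
  for (k in c(2L, 3L, 6L)) {
    est <- estimate_C(block_affinity(k, 20), C_min = 2, C_max = 12)
    expect_identical(est$chosen_C, k)
    expect_true(all(est$J_values >= k * 20 - 1e-6))
    expect_true(est$chosen_C %in% est$candidates)
  }
})

test_that("chosen cluster count is invariant to cell permutation", {
  # moderate coupling: non-degenerate eigenstructure, stable under reordering
  W <- noisy_block_affinity(4, 20, seed = 14)
  est1 <- suppressWarnings(estimate_C(W, 2, 8))
  expect_identical(est1$chosen_C, 4L)
  set.seed(3)
  perm <- sample(nrow(W))
  est2 <- suppressWarnings(estimate_C(W[perm, perm], 2, 8))
  expect_identical(est1$chosen_C, est2$chosen_C)
})

test_that("candidate range is validated", {
  W <- block_affinity(2, 10)
  expect_error(estimate_C(W, 2, 15), "too large")
  expect_error(estimate_C(W, 5, 5), "C_min")
})
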