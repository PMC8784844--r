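test_that("transition operator is row-stochastic on the KNN support", {
  bl <- blob_matrix(k = 2, per = 25, sep = 3, seed = 4)
  W <- affinity_graph(bl$X)
  P <- build_transition(W, K_nn = 7)
  Pm <- as.matrix(P$P)
  expect_equal(unname(Matrix::rowSums(P$P)), rep(1, 50), tolerance = 1e-10)
  expect_true(all(rowSums(Pm > 0) <= 7))
  expect_equal(unname(diag(Pm)), rep(0, 50))  # self excluded from knn
  # zero exactly off-support
  for (i in c(1, 30)) {
    expect_true(all(Pm[i, -P$support[[i]]] == 0))
  }
})

test_that("transition matches a 3x3 hand computation and the full-support limit", {
  W <- matrix(c(1, .6, .2,
                .6, 1, .3,
                .2, .3, 1), 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  P <- as.matrix(build_transition(W, K_nn = 2)$P)
  # row 1: neighbours {2,3}, weights .6,.2 -> .75,.25
  expect_equal(unname(P[1, ]), c(0, .75, .25))
  expect_equal(unname(P[2, ]), c(.6 / .9, 0, .3 / .9))
  expect_equal(unname(P[3, ]), c(.2 / .5, .3 / .5, 0))

  # K_nn = n - 1 is exactly row-normalized W with zeroed diagonal
  Wz <- W; diag(Wz) <- 0
  expect_equal(as.matrix(build_transition(W, K_nn = 2)$P),
               Wz / rowSums(Wz))
  expect_error(build_transition(W, K_nn = 3), "K_nn")
})

test_that("diffusion honours the identity contract and the row-sum recursion", {
  bl <- blob_matrix(k = 2, per = 20, sep = 3, seed = 9)
  W <- affinity_graph(bl$X)
  P <- build_transition(W, K_nn = 10)

  expect_identical(self_diffuse(W, P, t = 0)$S, W$W)
  expect_error(self_diffuse(W, P, t = 4, tau = 1), "tau")
  expect_error(self_diffuse(W, P, t = 4, tau = 0), "tau")

  # independent recomputation of the recursion, step by step
  tau <- 0.7
  S <- W$W
  for (step in 1:5) {
    S_next <- self_diffuse(W, P, t = step, tau = tau)$S
    expect_equal(rowSums(S_next),
                 tau * rowSums(S %*% as.matrix(P$P)) + (1 - tau),
                 tolerance = 1e-9)
    expect_true(all(S_next >= 0))
    S <- S_next
  }
})

test_that("one step from the identity is the convex mix of P and I", {
  n <- 12
  set.seed(2)
  W <- diag(n)
  dimnames(W) <- list(paste0("c", 1:n), paste0("c", 1:n))
  Pm <- matrix(runif(n * n), n, n); diag(Pm) <- 0
  Pm <- Pm / rowSums(Pm)
  S1 <- self_diffuse(W, Pm, t = 1, tau = 0.5)$S
  expect_equal(unname(S1), unname(0.5 * Pm + 0.5 * diag(n)), tolerance = 1e-12)
  expect_equal(unname(rowSums(S1)), rep(1, n), tolerance = 1e-12)
})

test_that("diffusion is equivariant under cell permutation", {
  bl <- blob_matrix(k = 2, per = 15, sep = 3, seed = 12)
  run <- function(X) {
    W <- affinity_graph(X)
    symmetrize(self_diffuse(W, build_transition(W, K_nn = 8), t = 4))
  }
  S <- run(bl$X)
  perm <- sample(nrow(bl$X))
  S_perm <- run(bl$X[perm, ])
  expect_equal(unname(S_perm), unname(S[perm, perm]), tolerance = 1e-10)
})

test_that("diffusion sharpens planted two-block contrast", {
  # weak off-diagonal weights relative to the unit diagonal: the regime a
  # kernel affinity sits in, where self-mass flows only to within-block
  # neighbours and the contrast rises
  W <- noisy_block_affinity(2, 30, seed = 21,
                            w_in = c(0.15, 0.3), w_bt = c(0.02, 0.08))
  labels <- rep(1:2, each = 30)
  S <- symmetrize(self_diffuse(W, build_transition(W), t = 4))
  expect_gte(block_contrast(S, labels), block_contrast(W, labels))
})

test_that("symmetrize averages the matrix with its transpose", {
  M <- matrix(c(1, 3, 5, 7), 2)
  Sy <- symmetrize(M)
  expect_equal(Sy, (M + t(M)) / 2)
  expect_equal(Sy - t(Sy), matrix(0, 2, 2))
  expect_equal(symmetrize(Sy), Sy)
  expect_equal(Sy[1, 2], mean(c(M[1, 2], M[2, 1])))
  expect_error(symmetrize(matrix(0, 2, 3)), "square")
})
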