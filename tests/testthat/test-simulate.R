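test_that("simulation is fully determined by its seed", {
  p <- sim_params(80, 120, 3, seed = 5)
  s1 <- simulate_counts(p)
  s2 <- simulate_counts(p)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$labels, s2$labels)
  s3 <- simulate_counts(sim_params(80, 120, 3, seed = 6))
  expect_false(identical(s1$counts, s3$counts))
  # simulation does not disturb the session RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_counts(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("group sizes follow the proportions and bad simplices error", {
  p <- sim_params(100, 50, 4, group_props = c(.4, .3, .2, .1), seed = 1)
  sim <- simulate_counts(p)
  expect_equal(unname(table(sim$labels)), c(40, 30, 20, 10), ignore_attr = TRUE)
  expect_error(sim_params(100, 50, 3, group_props = c(.5, .5)), "group_props")
  expect_error(sim_params(100, 50, 3, group_props = c(.5, .4, .4)), "group_props")
  expect_error(sim_params(2, 50, 3), "more groups")
})

test_that("realized library sizes match the log-normal model", {
  # dropout pushed out of range so totals reflect the library-size draws
  p <- sim_params(2000, 400, 2, dropout_mid = -30, seed = 8)
  sim <- simulate_counts(p)
  expected <- exp(p$lib_loc + p$lib_scale^2 / 2)
  expect_lt(abs(mean(rowSums(sim$counts)) / expected - 1), 0.05)
})

test_that("dropout inflates zeros at matched parameters", {
  base <- simulate_counts(sim_params(200, 300, 2, dropout_mid = -30, seed = 4))
  drop <- simulate_counts(sim_params(200, 300, 2, dropout_mid = 1.5, seed = 4))
  expect_gt(mean(drop$counts == 0), mean(base$counts == 0))
})

test_that("a null model carries no group signal", {
  p0 <- sim_params(150, 200, 3, de_prob = 0, seed = 0)
  sim <- simulate_counts(p0)
  gm <- tapply(rowSums(sim$counts), sim$labels, mean)
  expect_lt(diff(range(gm)) / mean(gm), 0.1)

  # pipeline ARI against planted labels ~ 0 over seeds
  aris <- vapply(0:9, function(s) {
    sm <- simulate_counts(sim_params(120, 150, 3, de_prob = 0, seed = s))
    cl <- lssd_cluster(sm$counts, n_clusters = 3, seed = 0)
    ari(cl$labels, sm$labels)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("separable defaults are recovered by the full pipeline", {
  p <- sim_params(300, 500, 3, de_prob = 0.3, de_fac_loc = 1.5, seed = 0)
  for (s in 1:5) {
    p$seed <- s
    sim <- simulate_counts(p)
    cl <- lssd_cluster(sim$counts, n_clusters = 3, seed = 0)
    expect_gt(ari(cl$labels, sim$labels), 0.95)
  }
})

test_that("step sweep is consistent with a direct run and keeps its schema", {
  p <- sim_params(150, 200, 3, seed = 2)
  tab <- step_sweep(c(4), p, seed = 0)
  expect_equal(nrow(tab), 1L)
  sim <- simulate_counts(p)
  cl <- lssd_cluster(sim$counts, n_clusters = 3, steps = 4, seed = 0)
  expect_equal(tab$nmi, nmi(cl$labels, sim$labels))
  expect_equal(tab$ari, ari(cl$labels, sim$labels))

  tab2 <- step_sweep(c(2, 4, 8), p, seed = 0)
  expect_equal(tab2$t, c(2, 4, 8))
  expect_true(all(tab2$nmi >= 0 & tab2$nmi <= 1))
  # the best step over the sweep is at least as good as the earliest
  p_hard <- sim_params(150, 200, 3, de_fac_loc = 0.6, seed = 2)
  hard <- step_sweep(c(2, 4, 6, 8), p_hard, seed = 0)
  expect_gte(max(hard$nmi), hard$nmi[hard$t == 2])
})

test_that("scaling sweep reports one row per size with valid metrics", {
  p <- sim_params(200, 200, 3, seed = 3)
  tab <- scaling_sweep(c(120, 200), p, seed = 0)
  expect_equal(tab$n_cells, c(120, 200))
  expect_true(all(tab$nmi >= 0 & tab$nmi <= 1))
  expect_true(all(tab$ari <= 1))
  expect_true(all(tab$seconds >= 0))
})
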