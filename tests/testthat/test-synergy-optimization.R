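test_that("node counts follow the one-node-per-5%-of-cycle rule", {
  expect_identical(node_count(101), 21L)
  expect_identical(node_count(1), 1L)
  expect_identical(node_count(6), 2L)
  expect_identical(node_count(51), 11L)
  expect_error(node_count(0), "positive")
})

test_that("the clamped basis is a non-negative partition of unity", {
  B <- bspline_basis(41, 9, degree = 3, dt = 0.01)
  expect_true(all(B >= 0))
  expect_equal(rowSums(B), rep(1, 41), tolerance = 1e-12)
  # constant nodes -> constant curve
  C <- evaluate_synergy_activations(matrix(0.7, 9, 2), 41, dt = 0.01)
  expect_true(all(abs(C - 0.7) < 1e-12))
  # non-negative nodes -> non-negative curve
  nodes <- matrix(abs(sin(1:18)), 9, 2)
  expect_true(all(evaluate_synergy_activations(nodes, 41, dt = 0.01) >= 0))
  expect_error(bspline_basis(41, 3, degree = 3), "degree")
})

test_that("perturbing one node only changes the curve on its support", {
  f <- 41; p <- 9
  B <- bspline_basis(f, p, degree = 3, dt = 0.01)
  nodes <- matrix(0.5, p, 1)
  nodes2 <- nodes
  nodes2[5, 1] <- nodes2[5, 1] + 0.3
  dC <- evaluate_synergy_activations(nodes2, f, dt = 0.01) -
    evaluate_synergy_activations(nodes, f, dt = 0.01)
  support <- B[, 5] > 1e-12
  expect_true(all(abs(dC[!support, 1]) < 1e-12))
  expect_true(any(abs(dC[support, 1]) > 1e-6))
})

test_that("activation construction is the synergy matrix product", {
  C <- matrix(c(1, 0, 1, 0, 2, 1), 3, 2)
  V <- matrix(c(0.5, 0, 0.5, 0, 0, 0.25, 0, 0.75), 2, 4)
  expect_equal(construct_activations(C, V),
               matrix(c(0.5, 0, 0.5, 0.5, 0, 0.5, 0, 0.5, 0.25,
                        0, 1.5, 0.75), 3, 4))
  expect_equal(construct_activations(0 * C, V), matrix(0, 3, 4))
  a_uni <- construct_activations(matrix(1, 4, 1), matrix(1 / 5, 1, 5))
  expect_true(all(abs(a_uni - 1 / 5) < 1e-15))
  expect_error(construct_activations(C, t(V)), "mismatch")
})

test_that("the penalized tracking cost matches hand-computed values", {
  # perfect moment match, all activations zero -> every term vanishes
  expect_equal(syno_cost(matrix(0, 2, 3), matrix(1:4, 2), matrix(1:4, 2)), 0)
  # one frame/muscle/DOF, perfect match, a = 0.5 -> 0.25
  expect_equal(syno_cost(matrix(0.5), matrix(2), matrix(2)), 0.25)
  # a = 1.2 adds the out-of-bounds penalty: 1.44 + 1e5 * 0.04 = 4001.44
  expect_equal(syno_cost(matrix(1.2), matrix(2), matrix(2)), 4001.44)
  # an identically-zero DOF falls back to a unit normalizer with a warning
  expect_warning(
    cost <- syno_cost(matrix(0, 2, 1), matrix(c(1, 1), 2, 1),
                      matrix(0, 2, 1)),
    "normalizer")
  expect_equal(cost, 100 * 2) # beta * (1 - 0)^2 per frame
})

test_that("the packed objective agrees with the cost kernel", {
  fx <- make_fixture(m = 6, d = 2, f = 21, n_true = 2, seed = 8)
  n_s <- 2
  p <- node_count(21)
  set.seed(42)
  nodes <- matrix(runif(p * n_s), p, n_s)
  U <- matrix(rexp(n_s * 6), n_s, 6)
  design <- c(as.vector(nodes), as.vector(U))
  got <- syno_objective(design, fx$trial, fx$params, n_s)
  V <- U / rowSums(U)
  C <- evaluate_synergy_activations(nodes, 21, degree = 3,
                                    dt = fx$trial$dt)
  a <- construct_activations(C, V)
  forces <- compute_muscle_forces(a, fx$trial$lmt, fx$trial$vmt, fx$params)
  q_mt <- compute_joint_moments(forces, fx$trial$moment_arms)
  expect_equal(got, syno_cost(a, q_mt, fx$trial$q_id), tolerance = 1e-10)
})

test_that("the analytic gradient matches finite differences", {
  fx <- make_fixture(m = 5, d = 2, f = 16, n_true = 2, seed = 10)
  ctx <- synact:::syno_context(fx$trial, fx$params, 2, syno_config(),
                               hill_curves())
  set.seed(7)
  design <- c(runif(ctx$p * 2), rexp(2 * ctx$m) + 0.1)
  g <- ctx$gr(design)
  h <- 1e-6
  g_fd <- vapply(seq_along(design), function(i) {
    dp <- dm <- design
    dp[i] <- dp[i] + h
    dm[i] <- dm[i] - h
    (ctx$fn(dp) - ctx$fn(dm)) / (2 * h)
  }, numeric(1))
  expect_equal(g, g_fd, tolerance = 1e-4)
})

test_that("solved synergies satisfy the constraints and bound the truth", {
  fx <- make_fixture(m = 8, d = 3, f = 31, n_true = 2, seed = 21)
  cfg <- syno_config(n_multistarts = 3, maxit = 800)
  fit <- solve_syno(fx$trial, fx$params, 2, config = cfg)
  expect_true(all(abs(rowSums(fit$synergies$V) - 1) < 1e-6))
  expect_true(all(fit$synergies$V >= 0))
  expect_true(all(fit$synergies$C >= -1e-12))
  expect_true(all(fit$activations >= -1e-12))
  # the optimum can be no worse than starting at the spline-fitted truth
  ctx <- synact:::syno_context(fx$trial, fx$params, 2, cfg, hill_curves())
  nodes_gt <- synact:::fit_nodes(ctx$B, fx$gt$synergies$C)
  cost_gt <- ctx$fn(synact:::pack_design(nodes_gt,
                                         pmax(fx$gt$synergies$V, 1e-9)))
  expect_lte(fit$cost, cost_gt + 1e-6)
})

test_that("a padded start never degrades the achievable cost", {
  fx <- make_fixture(m = 6, d = 2, f = 21, n_true = 2, seed = 31)
  cfg <- syno_config(n_multistarts = 2, maxit = 500)
  fit2 <- solve_syno(fx$trial, fx$params, 2, config = cfg)
  fit3 <- solve_syno(fx$trial, fx$params, 3, config = cfg,
                     extra_starts = list(
                       synact:::pad_syno_start(fit2,
                                               length(fx$trial$muscle_labels))))
  expect_lte(fit3$cost, fit2$cost + 1e-8)
})
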