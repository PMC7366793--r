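test_that("the symmetric two-muscle frame matches the KKT closed form", {
  # two identical muscles, one DOF, r = 0.05 m, f_max = 1000 N, unit
  # curves: gain = 1000, constraint 50 (a1 + a2) = 30 -> a = (0.3, 0.3)
  params <- analytic_params(2, f_max = 1000, passive_enabled = FALSE)
  r_j <- matrix(0.05, 1, 2)
  a <- solve_so_frame(30, r_j, rep(0.3, 2), rep(0, 2), params,
                      curves = unit_hill_curves())
  expect_equal(as.numeric(a), c(0.3, 0.3), tolerance = 1e-8)
})

test_that("zero demand with passive force disabled gives zero activation", {
  params <- analytic_params(4, passive_enabled = FALSE)
  r_j <- matrix(c(0.05, -0.04, 0.03, 0.02), 1, 4)
  a <- solve_so_frame(0, r_j, rep(0.3, 4), rep(0, 4), params,
                      curves = unit_hill_curves())
  expect_equal(max(abs(a)), 0, tolerance = 1e-10)
})

test_that("demand beyond the muscles' moment capacity is infeasible", {
  params <- analytic_params(2, f_max = 1000, passive_enabled = FALSE)
  r_j <- matrix(0.05, 1, 2)
  # capacity = 2 * 0.05 * 1000 = 100 N.m
  expect_error(
    solve_so_frame(150, r_j, rep(0.3, 2), rep(0, 2), params,
                   curves = unit_hill_curves()),
    "residual")
})

test_that("activations scale with capacity on the symmetric instance", {
  r_j <- matrix(0.05, 1, 2)
  a1 <- solve_so_frame(30, r_j, rep(0.3, 2), rep(0, 2),
                       analytic_params(2, 1000, FALSE),
                       curves = unit_hill_curves())
  a2 <- solve_so_frame(15, r_j, rep(0.3, 2), rep(0, 2),
                       analytic_params(2, 2000, FALSE),
                       curves = unit_hill_curves())
  expect_equal(as.numeric(a2), as.numeric(a1) / 4, tolerance = 1e-7)
})

test_that("a stationary trial yields identical activations at every frame", {
  params <- analytic_params(3, passive_enabled = FALSE)
  f <- 8
  trial <- trial_data(dt = 0.01,
                      moment_arms = array(rep(c(0.05, 0.03, -0.02), each = f),
                                          c(f, 1, 3)),
                      lmt = matrix(0.3, f, 3), vmt = matrix(0, f, 3),
                      q_id = matrix(10, f, 1))
  fit <- solve_so(trial, params, curves = unit_hill_curves())
  expect_lt(max(apply(fit$activations, 2, function(x) diff(range(x)))),
            1e-8)
})

test_that("static optimization is exact on forward-consistent trials", {
  fx <- make_fixture(m = 10, d = 3, f = 31, n_true = 3, seed = 11)
  fit <- solve_so(fx$trial, fx$params)
  expect_gte(fit$vaf_mean, 99.99)
  expect_true(all(fit$activations >= -1e-9 & fit$activations <= 1 + 1e-9))
  tol <- 1e-6 * max(1, max(abs(fx$trial$q_id)))
  expect_lte(max(fit$residuals), tol)
})

test_that("warm-started frames agree with independent cold re-solves", {
  fx <- make_fixture(m = 8, d = 2, f = 15, seed = 6)
  fit <- solve_so(fx$trial, fx$params)
  for (j in c(4, 9, 15)) {
    r_j <- fx$trial$moment_arms[j, , , drop = FALSE]
    dim(r_j) <- c(2, 8)
    cold <- solve_so_frame(fx$trial$q_id[j, ], r_j, fx$trial$lmt[j, ],
                           fx$trial$vmt[j, ], fx$params)
    expect_equal(as.numeric(cold), as.numeric(fit$activations[j, ]),
                 tolerance = 1e-5)
  }
})

test_that("reserve-actuator mode trades residual against effort", {
  params <- analytic_params(2, f_max = 1000, passive_enabled = FALSE)
  r_j <- matrix(0.05, 1, 2)
  a <- solve_so_frame(30, r_j, rep(0.3, 2), rep(0, 2), params,
                      curves = unit_hill_curves(), reserve_weight = 1e6)
  expect_equal(as.numeric(a), c(0.3, 0.3), tolerance = 1e-3)
  # infeasible demand no longer errors: the reserve absorbs it
  a_inf <- solve_so_frame(150, r_j, rep(0.3, 2), rep(0, 2), params,
                          curves = unit_hill_curves(),
                          reserve_weight = 1e6)
  expect_true(all(a_inf <= 1 + 1e-9))
  expect_gt(attr(a_inf, "residual"), 1)
})
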