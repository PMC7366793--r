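test_that("VAF matches its definition on hand examples", {
  expect_equal(vaf(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(vaf(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_equal(vaf(c(2, 0, -2), c(3, 0, -2)), 87.5) # 100 * (1 - 1/8)
  expect_error(vaf(c(0, 0, 0), c(1, 2, 3)), "undefined")
  # centered variant uses variance around the reference mean
  expect_equal(vaf(c(1, 2, 3), c(1, 2, 3), centered = TRUE), 100)
  expect_equal(vaf(c(1, 2, 3), c(0, 2, 4), centered = TRUE), 0)
})

test_that("lagged correlation recovers injected delays", {
  t <- seq(0, 1.5, by = 0.01)
  x <- sin(2 * pi * 2 * t) + 0.5 * cos(2 * pi * 3 * t)
  expect_equal(lagged_pearson(x, x, dt = 0.01),
               list(r = 1, lag_ms = 0))
  # y delayed by 50 ms at dt = 10 ms -> best lag 50 ms with r = 1
  y <- c(rep(x[1], 5), x[seq_len(length(x) - 5)])
  lp <- lagged_pearson(x, y, dt = 0.01, max_lag_ms = 100)
  expect_equal(lp$lag_ms, 50)
  expect_gt(lp$r, 0.999)
  expect_error(lagged_pearson(rep(1, 50), rnorm(50), dt = 0.01),
               "constant")
})

test_that("independent noise stays below the multiple-lag null bound", {
  t <- seq(0, 1, by = 0.01)
  x <- sin(2 * pi * 2 * t)
  set.seed(99)
  y <- rnorm(length(t))
  lp <- lagged_pearson(x, y, dt = 0.01, max_lag_ms = 100)
  expect_lt(abs(lp$r), 0.5)
  # permutation oracle: the observed max-lag r is typical of the null
  null_max <- vapply(1:100, function(i) {
    lagged_pearson(x, sample(y), dt = 0.01, max_lag_ms = 100)$r
  }, numeric(1))
  expect_lt(lp$r, max(null_max) + 0.1)
})

test_that("activation similarity is an affine-invariant mean squared r", {
  set.seed(4)
  a <- matrix(runif(60), 20, 3)
  expect_equal(activation_similarity_r2(a, a)$mean_r2, 1)
  expect_equal(activation_similarity_r2(a, 2 * a + 3)$mean_r2, 1)
  # orthogonal-in-time columns, swapped: per-column r2 from the formula
  u <- c(1, 0, 1, 0); v <- c(0, 1, 0, 1)
  A <- cbind(u, v); B <- cbind(v, u)
  expect_equal(activation_similarity_r2(A, B)$mean_r2,
               cor(u, v)^2)
  # constant columns are skipped and counted
  A2 <- cbind(u, rep(0.3, 4))
  r <- activation_similarity_r2(A2, A2)
  expect_equal(r$n_skipped, 1)
  expect_equal(r$mean_r2, 1)
})

test_that("permutation matching identifies reordered synergy vectors", {
  set.seed(12)
  V <- matrix(rexp(4 * 7), 4, 7)
  V <- V / rowSums(V)
  perm <- c(3, 1, 4, 2)
  ms <- match_synergy_vectors(V[perm, ], V)
  expect_equal(ms$permutation, perm)
  expect_equal(ms$mean_cosine, 1, tolerance = 1e-12)
})

test_that("the comparison report covers every DOF and channel", {
  fx <- make_fixture(m = 8, d = 2, f = 31, n_true = 2, seed = 17)
  so <- solve_so(fx$trial, fx$params)
  syno <- list(`2` = solve_syno(fx$trial, fx$params, 2,
                                config = syno_config(n_multistarts = 2,
                                                     maxit = 400),
                                so_activations = so$activations))
  sonmf <- list(`2` = analyze_sonmf(fx$trial, fx$params, so$activations, 2,
                                    seed = 1))
  emg <- synthesize_emg(fx$gt, dt = fx$trial$dt,
                        channel_map = c(e1 = "muscle_01",
                                        e2 = "muscle_03"),
                        delays = 0.02, noise_sd = 0.05, seed = 9)
  env <- process_emg(emg)
  rep <- build_comparison_report(fx$trial, so, syno, sonmf, emg = env)
  expect_setequal(unique(rep$moment_vaf$dof), fx$trial$dof_labels)
  expect_setequal(unique(rep$moment_vaf$method), c("SO", "SynO", "SO-NMF"))
  expect_setequal(unique(rep$emg_correlation$channel), c("e1", "e2"))
  so_rows <- dplyr::filter(rep$moment_vaf, method == "SO")
  expect_true(all(so_rows$vaf >= 99.99))
  nmf_rows <- dplyr::filter(rep$moment_vaf, method == "SO-NMF")
  expect_true(all(nmf_rows$vaf <= so_rows$vaf + 1e-9))
  # a channel map naming a muscle absent from the trial is rejected
  env_bad <- env
  env_bad$channel_map <- c(e1 = "nope")
  expect_error(build_comparison_report(fx$trial, so, emg = env_bad),
               "absent")
})
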