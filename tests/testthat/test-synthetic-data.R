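test_that("plant generation is deterministic under a fixed seed", {
  p1 <- generate_plant(m = 10, d = 3, f = 31, seed = 7)
  p2 <- generate_plant(m = 10, d = 3, f = 31, seed = 7)
  expect_identical(p1$moment_arms, p2$moment_arms)
  expect_identical(p1$lmt, p2$lmt)
  expect_identical(p1$vmt, p2$vmt)
  p3 <- generate_plant(m = 10, d = 3, f = 31, seed = 8)
  expect_false(identical(p1$moment_arms, p3$moment_arms))
})

test_that("plant arrays have the contracted shapes and bounds", {
  p <- generate_plant(m = 2, d = 1, f = 10, seed = 1)
  expect_equal(dim(p$moment_arms), c(10, 1, 2))
  expect_true(all(abs(p$moment_arms) <= 0.08))
  expect_true(all(p$lmt > 0))
  expect_error(generate_plant(m = 0, d = 1, f = 10), "count")
  expect_error(generate_plant(m = 3, d = 5, f = 10), ">=")
})

test_that("vmt is the time derivative of lmt (central-difference oracle)", {
  p <- generate_plant(m = 6, d = 2, f = 101, dt = 0.01, seed = 3)
  cd <- (p$lmt[3:101, ] - p$lmt[1:99, ]) / (2 * 0.01)
  err <- max(abs(p$vmt[2:100, ] - cd))
  expect_lt(err, 0.01 * max(abs(p$vmt)))
})

test_that("ground truth has sum-to-one vectors and exact factorization", {
  for (seed in 1:4) {
    gt <- generate_ground_truth(3, 41, 9, seed = seed)
    expect_true(all(abs(rowSums(gt$synergies$V) - 1) < 1e-12))
    expect_true(all(gt$activations >= 0 & gt$activations <= 1))
    expect_lt(max(abs(gt$activations -
                        gt$synergies$C %*% gt$synergies$V)), 1e-12)
    sv <- svd(gt$activations)$d
    expect_equal(sum(sv > 1e-10 * sv[1]), 3) # numerical rank = n_true
  }
  expect_error(generate_ground_truth(10, 41, 9), "<=")
})

test_that("single-synergy activations are rank-1 with proportional rows", {
  gt <- generate_ground_truth(1, 21, 5, seed = 2)
  a <- gt$activations
  # every muscle column proportional to the single synergy activation
  for (i in 2:5) {
    ratio <- a[, i] / a[, 1]
    expect_lt(diff(range(ratio)), 1e-10)
  }
})

test_that("forward-consistent trials reproduce the model's moments exactly", {
  fx <- make_fixture(m = 8, d = 2, f = 21, n_true = 2, seed = 5)
  forces <- compute_muscle_forces(fx$gt$activations, fx$trial$lmt,
                                  fx$trial$vmt, fx$params)
  expect_equal(fx$trial$q_id, compute_joint_moments(forces,
                                                    fx$trial$moment_arms))
})

test_that("zero activations with passive force disabled give zero moments", {
  fx <- make_fixture(m = 6, d = 2, f = 11, seed = 2,
                     passive_enabled = FALSE)
  gt0 <- fx$gt
  gt0$activations[] <- 0
  gt0$synergies$C[] <- 0
  trial0 <- forward_consistent_trial(fx$plant, gt0, fx$params)
  expect_equal(max(abs(trial0$q_id)), 0)
})

test_that("synthesized EMG is a delayed image of the true activation", {
  fx <- make_fixture(m = 6, d = 2, f = 101, seed = 4)
  # identity channel: no delay, no noise -> r = 1 at lag 0
  emg <- synthesize_emg(fx$gt, dt = 0.01, channel_map = c(e1 = "muscle_01"),
                        delays = 0, noise_sd = 0, seed = 1)
  env <- process_emg(emg)
  env_f <- resample_to_frames(env, 101, 0.01)
  lp <- lagged_pearson(fx$gt$activations[, 1], env_f[, 1], dt = 0.01)
  expect_gt(lp$r, 0.99)
  expect_equal(lp$lag_ms, 0)

  # 40 ms delay recovered by the lagged correlation
  emg40 <- synthesize_emg(fx$gt, dt = 0.01, channel_map = c(e1 = "muscle_01"),
                          delays = 0.04, noise_sd = 0, seed = 1)
  env40 <- resample_to_frames(process_emg(emg40), 101, 0.01)
  lp40 <- lagged_pearson(fx$gt$activations[, 1], env40[, 1], dt = 0.01)
  expect_equal(lp40$lag_ms, 40)

  # crosstalk contaminates the channel: correlation with its own source drops
  ct <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  emg_ct <- synthesize_emg(fx$gt, dt = 0.01,
                           channel_map = c(e1 = "muscle_01",
                                           e2 = "muscle_02"),
                           delays = 0, noise_sd = 0, crosstalk = ct,
                           seed = 1)
  env_ct <- resample_to_frames(process_emg(emg_ct), 101, 0.01)
  lp_ct <- lagged_pearson(fx$gt$activations[, 1], env_ct[, 1], dt = 0.01)
  expect_lt(lp_ct$r, lp$r)
})

test_that("unknown muscles in the channel map are rejected", {
  gt <- generate_ground_truth(2, 21, 4, seed = 1)
  expect_error(synthesize_emg(gt, dt = 0.01,
                              channel_map = c(e1 = "not_a_muscle")),
               "unknown muscle")
})
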