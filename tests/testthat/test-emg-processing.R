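make_emg <- function(signals, rate = 1000,
                     channel_map = stats::setNames(
                       sprintf("muscle_%02d", seq_len(ncol(signals))),
                       sprintf("e%d", seq_len(ncol(signals))))) {
  structure(list(signals = signals, sample_rate = rate,
                 channel_map = channel_map, delays = rep(0, ncol(signals)),
                 noise_sd = 0, crosstalk = diag(ncol(signals))),
            class = "emg_set")
}

test_that("zero-phase Butterworth passes 5 Hz and suppresses 50 Hz", {
  t <- seq(0, 2, by = 1e-3)
  mid <- 500:1500 # steady-state region away from the edges
  tone5 <- sin(2 * pi * 5 * t)
  tone50 <- sin(2 * pi * 50 * t)
  y5 <- butterworth_lowpass(tone5, 1000, cutoff = 15, order = 5)
  y50 <- butterworth_lowpass(tone50, 1000, cutoff = 15, order = 5)
  expect_gte(sd(y5[mid]) / sd(tone5[mid]), 0.95)
  expect_lte(sd(y50[mid]) / sd(tone50[mid]), 0.05)
})

test_that("a constant positive signal processes to a unit envelope", {
  emg <- make_emg(matrix(2.5, 600, 1))
  env <- process_emg(emg)
  expect_true(all(abs(env$values - 1) < 1e-9))
})

test_that("processing is symmetric under sign flips (rectification)", {
  x <- matrix(sin(2 * pi * 3 * seq(0, 1, 1e-3)) +
                0.2 * sin(2 * pi * 40 * seq(0, 1, 1e-3)), ncol = 1)
  e1 <- process_emg(make_emg(x))
  e2 <- process_emg(make_emg(-x))
  expect_equal(e1$values, e2$values)
})

test_that("cutoff at or above Nyquist and all-zero channels are handled", {
  emg <- make_emg(cbind(rep(0, 400), abs(sin(seq_len(400) * 0.01))))
  expect_error(process_emg(emg, cutoff = 500), "Nyquist")
  expect_warning(env <- process_emg(emg), "all-zero")
  expect_true(env$zero_channels[1])
  expect_false(env$zero_channels[2])
  expect_true(all(env$values[, 1] == 0))
  expect_true(all(env$values >= 0 & env$values <= 1))
})

test_that("SSA smoothing approximates the Butterworth envelope", {
  # burst-like envelope buried in broadband noise: both smoothers should
  # recover the same underlying shape
  set.seed(3)
  t <- seq(0, 1.2, by = 1e-3)
  shape <- exp(-((t - 0.4) / 0.12)^2) + 0.7 * exp(-((t - 0.9) / 0.1)^2)
  emg <- make_emg(matrix(shape + 0.25 * rnorm(length(t)), ncol = 1))
  bw <- process_emg(emg, method = "butterworth")
  ssa <- process_emg(emg, method = "ssa", ssa_window = 250)
  expect_gt(cor(bw$values[, 1], ssa$values[, 1]), 0.9)
  expect_gt(cor(ssa$values[, 1], shape), 0.9)
  # SSA of a constant reconstructs the constant
  expect_equal(max(abs(ssa_smooth(rep(3, 500)) - 3)), 0, tolerance = 1e-8)
})

test_that("resampling to frames is exact for aligned and linear inputs", {
  # aligned clocks: identity
  vals <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  env <- structure(list(values = vals, sample_rate = 100,
                        channel_map = c(e1 = "muscle_01"),
                        zero_channels = FALSE), class = "envelope_set")
  expect_equal(drop(resample_to_frames(env, 21, 0.01)), drop(vals))
  # a linear ramp downsampled 10x stays linear with the same endpoints
  ramp <- matrix(seq(0, 1, length.out = 201), ncol = 1)
  env2 <- structure(list(values = ramp, sample_rate = 1000,
                         channel_map = c(e1 = "muscle_01"),
                         zero_channels = FALSE), class = "envelope_set")
  out <- drop(resample_to_frames(env2, 21, 0.01))
  expect_equal(out, seq(0, 1, length.out = 21), tolerance = 1e-12)
  # constants are fixed points at any frame count
  env3 <- env2
  env3$values[] <- 0.4
  expect_true(all(resample_to_frames(env3, 7, 0.02) == 0.4))
  # trial longer than the recording is an error
  expect_error(resample_to_frames(env2, 500, 0.01), "exceeds")
})

test_that("EMG CSV reading infers the rate and keeps channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = seq(0, 0.099, by = 1e-3),
                   e1 = abs(sin(1:100 / 5)), e2 = abs(cos(1:100 / 7)))
  readr::write_csv(df, path)
  emg <- read_emg(path, c(e1 = "muscle_01", e2 = "muscle_02"))
  expect_equal(emg$sample_rate, 1000)
  expect_equal(dim(emg$signals), c(100, 2))
})
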