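# Synthetic gait-like trial generation.
#
# The generators stand in for gait-lab data: smooth periodic moment arms
# and musculotendon kinematics parameterized by low-order Fourier series
# in gait-cycle phase, ground-truth activations with a known synergy
# structure, inverse-dynamics moments produced by pushing those
# activations through the muscle model (so a feasible solution to the
# redundancy problem exists by construction), and EMG channels that are
# delayed/noisy/crosstalk-mixed images of the true activations.

# smooth periodic signal in phase [0,1): sum of <= n_harm harmonics,
# scaled to max |.| = 1 (coefficients drawn from the active RNG stream)
fourier_wave <- function(phase, n_harm = 4) {
  w <- numeric(length(phase))
  for (h in seq_len(n_harm)) {
    amp <- stats::runif(1, 0, 1) / h
    ph <- stats::runif(1, 0, 2 * pi)
    w <- w + amp * cos(2 * pi * h * phase + ph)
  }
  mx <- max(abs(w))
  if (mx < 1e-12) w else w / mx
}

#' Generate a synthetic musculoskeletal plant
#'
#' Builds the "plant" half of a trial — moment arms and musculotendon
#' kinematics — for one gait cycle. Each muscle spans 1-3 degrees of
#' freedom with a fixed sign and a smooth periodic modulation (Fourier
#' series with at most 4 harmonics in gait-cycle phase); the first
#' `2 d` muscles are assigned deterministically so that every DOF has
#' at least one agonist and one antagonist. Musculotendon lengths are
#' smooth, periodic and positive, and velocities are the exact analytic
#' time derivative of the lengths.
#'
#' @param m Number of muscles (default 43, a full lower-limb set).
#' @param d Number of degrees of freedom (default 6: three at the hip,
#'   knee flexion/extension, two at the ankle).
#' @param f Number of frames across the cycle (default 101, 0-100%).
#' @param dt Seconds per frame (default 0.01, i.e. 100 Hz motion data).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param max_moment_arm Bound on |moment arm|, m (default 0.08).
#' @return A [trial_data] plant without `q_id`.
#' @export
generate_plant <- function(m = 43, d = 6, f = 101, dt = 0.01, seed = 1L,
                           max_moment_arm = 0.08) {
  assert_that(is_count(m) && is_count(d) && is_count(f, min = 2),
              "`m`, `d` must be positive counts and `f` >= 2")
  assert_that(m >= d, "`m` must be >= `d` (redundant actuation)")
  assert_that(is_number(dt) && dt > 0, "`dt` must be > 0")

  phase <- (seq_len(f) - 1) / (f - 1)
  with_seed(seed, {
    moment_arms <- array(0, dim = c(f, d, m))
    for (i in seq_len(m)) {
      if (i <= 2 * d) {
        # deterministic coverage: every DOF gets an agonist and an antagonist
        dofs <- ((i - 1) %/% 2) %% d + 1
        signs <- if (i %% 2 == 1) 1 else -1
      } else {
        n_dof <- sample(1:3, 1)
        dofs <- sample(seq_len(d), min(n_dof, d))
        signs <- sample(c(-1, 1), length(dofs), replace = TRUE)
      }
      for (jj in seq_along(dofs)) {
        amp <- stats::runif(1, 0.25, 1) * max_moment_arm / 1.35
        # mean level plus bounded modulation keeps the sign fixed
        moment_arms[, dofs[jj], i] <-
          signs[jj] * amp * (1 + 0.35 * fourier_wave(phase))
      }
    }

    # periodic lmt with analytic derivative: lmt = L (1 + eps * sum harmonics)
    lmt <- matrix(0, f, m)
    vmt <- matrix(0, f, m)
    cycle_t <- (f - 1) * dt
    for (i in seq_len(m)) {
      L <- stats::runif(1, 0.2, 0.5)
      n_harm <- 3
      amp <- stats::runif(n_harm, 0, 1) / seq_len(n_harm)
      ph <- stats::runif(n_harm, 0, 2 * pi)
      s <- numeric(f)
      ds <- numeric(f) # d/dphase
      for (h in seq_len(n_harm)) {
        s <- s + amp[h] * cos(2 * pi * h * phase + ph[h])
        ds <- ds - amp[h] * 2 * pi * h * sin(2 * pi * h * phase + ph[h])
      }
      scale <- 0.05 / max(max(abs(s)), 1e-9)
      lmt[, i] <- L * (1 + scale * s)
      vmt[, i] <- L * scale * ds / cycle_t
    }
    trial_data(dt = dt, moment_arms = moment_arms, lmt = lmt, vmt = vmt)
  })
}

#' Generate ground-truth synergies and activations
#'
#' Draws `n_true` burst-like synergy activation waveforms (Gaussian
#' bumps in gait-cycle phase) and non-negative synergy vectors with
#' rows summing to one (flat Dirichlet draws), then scales the
#' activation bursts so that all muscle activations `C V` stay at or
#' below a target peak.
#'
#' @param n_true Number of ground-truth synergies (1 <= n_true <= m).
#' @param f Number of frames.
#' @param m Number of muscles.
#' @param seed Integer seed.
#' @param peak Peak muscle activation after scaling (default 0.8).
#' @return A list of class `ground_truth` with elements `synergies`
#'   (a [synergy_set]), `activations` (`f x m`, in `[0, 1]`) and `seed`.
#' @export
generate_ground_truth <- function(n_true, f, m, seed = 1L, peak = 0.8) {
  assert_that(is_count(n_true) && is_count(f) && is_count(m),
              "`n_true`, `f`, `m` must be positive counts")
  assert_that(n_true <= m, "`n_true` must be <= `m`")
  assert_that(is_number(peak) && peak > 0 && peak <= 1,
              "`peak` must be in (0, 1]")
  phase <- if (f > 1) (seq_len(f) - 1) / (f - 1) else 0
  with_seed(seed, {
    centers <- ((seq_len(n_true) - 0.5) / n_true +
                  stats::runif(n_true, -0.05, 0.05)) %% 1
    widths <- stats::runif(n_true, 0.07, 0.15)
    C <- sapply(seq_len(n_true), function(s) {
      # wrap-around distance keeps bursts periodic in the cycle
      dist <- pmin(abs(phase - centers[s]), 1 - abs(phase - centers[s]))
      exp(-(dist / widths[s])^2)
    })
    C <- matrix(C, nrow = f)
    V <- matrix(stats::rexp(n_true * m), n_true, m) # flat Dirichlet rows
    V <- V / rowSums(V)
    a <- C %*% V
    C <- C * (peak / max(a))
    a <- C %*% V
    structure(list(synergies = synergy_set(C, V),
                   activations = a, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$synergies$n_s, " synergies, ",
      nrow(x$activations), " frames x ", ncol(x$activations),
      " muscles (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Make a plant forward-consistent with known activations
#'
#' Computes the inverse-dynamics joint moments a trial would have if
#' its muscles followed the ground-truth activations exactly: the
#' activations are pushed through the rigid-tendon muscle model and the
#' moment-arm Jacobian, and the resulting moments are installed as
#' `q_id`. Every trial built this way is feasible for the
#' equality-constrained static optimization — the ground truth itself
#' reproduces `q_id` exactly.
#'
#' @param plant A [trial_data] plant from [generate_plant()].
#' @param ground_truth A `ground_truth` object from
#'   [generate_ground_truth()] with matching `f` and `m`.
#' @param params A [muscle_params] table for the plant's muscles.
#' @param curves A [hill_curves] object.
#' @return A [trial_data] with `q_id` set.
#' @export
forward_consistent_trial <- function(plant, ground_truth, params,
                                     curves = hill_curves()) {
  assert_that(inherits(plant, "trial_data"), "`plant` must be a trial_data")
  assert_that(inherits(ground_truth, "ground_truth"),
              "`ground_truth` must come from generate_ground_truth()")
  a <- ground_truth$activations
  assert_that(all(dim(a) == dim(plant$lmt)),
              "ground truth dimensions do not match the plant")
  forces <- compute_muscle_forces(a, plant$lmt, plant$vmt, params, curves)
  q_id <- compute_joint_moments(forces, plant$moment_arms)
  trial_data(dt = plant$dt, moment_arms = plant$moment_arms,
             lmt = plant$lmt, vmt = plant$vmt, q_id = q_id,
             dof_labels = plant$dof_labels,
             muscle_labels = plant$muscle_labels)
}

#' Synthesize surface-EMG-like channels from true activations
#'
#' Each channel is built from the true activation of its mapped muscle:
#' resampled to the EMG rate, shifted by a per-channel
#' electromechanical delay, mixed across channels by a non-negative
#' crosstalk matrix, corrupted by additive Gaussian noise on the
#' envelope, and rectified. The result plays the role of a
#' rectified-but-unfiltered recording for the envelope pipeline.
#'
#' @param ground_truth A `ground_truth` object.
#' @param dt Motion frame period of the underlying trial, s.
#' @param sample_rate EMG sampling rate, Hz (default 1000).
#' @param channel_map Named character vector, channel name -> muscle
#'   label; default: the first `min(m, 8)` muscles, one channel each.
#' @param muscle_labels Muscle labels of the trial (default the
#'   standard synthetic labels).
#' @param delays Per-channel delay in seconds (recycled; the
#'   channel lags the activation by this amount).
#' @param noise_sd Noise standard deviation as a fraction of each
#'   channel's peak (default 0).
#' @param crosstalk Optional `c x c` non-negative mixing matrix
#'   (rows = output channels); default identity.
#' @param seed Integer seed for the noise.
#' @return A list of class `emg_set`: `signals` (samples x channels),
#'   `sample_rate`, `channel_map`, `delays`, `noise_sd`, `crosstalk`.
#' @export
synthesize_emg <- function(ground_truth, dt, sample_rate = 1000,
                           channel_map = NULL, muscle_labels = NULL,
                           delays = 0, noise_sd = 0, crosstalk = NULL,
                           seed = 1L) {
  assert_that(inherits(ground_truth, "ground_truth"),
              "`ground_truth` must come from generate_ground_truth()")
  assert_that(is_number(sample_rate) && sample_rate > 0,
              "`sample_rate` must be > 0")
  a <- ground_truth$activations
  f <- nrow(a)
  m <- ncol(a)
  muscle_labels <- muscle_labels %||% default_muscle_labels(m)
  assert_that(length(muscle_labels) == m, "need one label per muscle")
  if (is.null(channel_map)) {
    idx <- seq_len(min(m, 8))
    channel_map <- stats::setNames(muscle_labels[idx],
                                   sprintf("emg_%02d", idx))
  }
  unknown <- setdiff(unname(channel_map), muscle_labels)
  assert_that(length(unknown) == 0,
              "channel_map targets unknown muscle(s): ",
              paste(unknown, collapse = ", "))
  n_ch <- length(channel_map)
  delays <- rep_len(delays, n_ch)
  if (is.null(crosstalk)) crosstalk <- diag(n_ch)
  assert_that(is.matrix(crosstalk) && all(dim(crosstalk) == n_ch),
              "`crosstalk` must be a c x c matrix")
  assert_that(all(crosstalk >= 0), "`crosstalk` must be non-negative")

  duration <- (f - 1) * dt
  t_emg <- seq(0, duration, by = 1 / sample_rate)
  t_frames <- (seq_len(f) - 1) * dt

  sources <- sapply(seq_len(n_ch), function(ci) {
    col <- a[, match(channel_map[ci], muscle_labels)]
    # delayed copy; constant extrapolation at the edges
    stats::approx(t_frames, col, xout = t_emg - delays[ci],
                  rule = 2)$y
  })
  sources <- matrix(sources, nrow = length(t_emg))
  mixed <- sources %*% t(crosstalk)
  signals <- with_seed(seed, {
    if (noise_sd > 0) {
      scale <- apply(mixed, 2, function(x) max(abs(x), 1e-12))
      mixed + matrix(stats::rnorm(length(mixed)), nrow(mixed)) *
        matrix(noise_sd * scale, nrow(mixed), n_ch, byrow = TRUE)
    } else mixed
  })
  structure(list(signals = abs(signals), sample_rate = sample_rate,
                 channel_map = channel_map, delays = delays,
                 noise_sd = noise_sd, crosstalk = crosstalk),
            class = "emg_set")
}

#' @export
print.emg_set <- function(x, ...) {
  cat("<emg_set> ", ncol(x$signals), " channels x ", nrow(x$signals),
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}
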