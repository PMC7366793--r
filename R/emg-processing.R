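#' Zero-phase Butterworth low-pass filter
#'
#' Forward-reverse (zero-phase) low-pass Butterworth filtering of one
#' or more columns. The two passes square the magnitude response, so an
#' order-5 design attenuates like an order-10 filter with no phase
#' distortion — the standard envelope smoother for rectified EMG.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (default 15; must be below the
#'   Nyquist frequency).
#' @param order Filter order per pass (default 5).
#' @return Filtered data with the same shape as `x`.
#' @export
butterworth_lowpass <- function(x, sample_rate, cutoff = 15, order = 5) {
  assert_that(is_number(sample_rate) && sample_rate > 0,
              "`sample_rate` must be > 0")
  assert_that(is_number(cutoff) && cutoff > 0, "`cutoff` must be > 0")
  if (cutoff >= sample_rate / 2)
    stop_invalid("`cutoff` (", cutoff, " Hz) must be below the Nyquist ",
                 "frequency (", sample_rate / 2, " Hz)")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # settle the filter well within the pad: ~3 cutoff periods of samples
  npad <- ceiling(3 * sample_rate / cutoff)
  apply_cols(x, function(col) zero_phase_filter(bf, col, npad))
}

# Forward-reverse filtering with odd-reflection padding and level-shifted
# passes (the filter runs on x - x[1], which starts at zero, so the
# zero-initial-state step transient is eliminated; the level is restored
# through the DC gain). signal::filtfilt alone leaves large edge
# transients because it applies no padding or initial-condition handling.
zero_phase_filter <- function(bf, x, npad) {
  n <- length(x)
  npad <- max(min(npad, n - 1), 1)
  dc <- sum(bf$b) / sum(bf$a)
  one_pass <- function(y) {
    drop(signal::filter(bf, y - y[1])) + y[1] * dc
  }
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  yp <- one_pass(xp)
  yp <- rev(one_pass(rev(yp)))
  yp[(npad + 1):(npad + n)]
}

#' Singular-spectrum-analysis smoother
#'
#' Embeds the signal in a trajectory matrix of the given window length,
#' takes its SVD, keeps the dominant components, and reconstructs by
#' diagonal averaging. An alternative envelope smoother whose effect,
#' at window 250 on 1 kHz EMG, is close to the 15 Hz zero-phase
#' Butterworth. A component is kept while its energy (squared singular
#' value) stays above `rel_energy` times the leading component's:
#' broadband noise spreads its energy over many small components, so a
#' per-component threshold rejects it, whereas a cumulative-energy rule
#' would absorb noise components until the target fraction is reached.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param window Embedding window length in samples (default 250).
#' @param rel_energy Per-component energy floor relative to the leading
#'   component (default 0.01).
#' @return Smoothed data with the same shape as `x`.
#' @export
ssa_smooth <- function(x, window = 250, rel_energy = 0.01) {
  assert_that(is_count(window, min = 2), "`window` must be >= 2")
  assert_that(is_number(rel_energy) && rel_energy > 0 && rel_energy <= 1,
              "`rel_energy` must be in (0, 1]")
  apply_cols(x, function(col) {
    n <- length(col)
    L <- min(window, floor(n / 2))
    if (L < 2) return(col)
    K <- n - L + 1
    traj <- sapply(seq_len(K), function(j) col[j:(j + L - 1)])
    sv <- svd(traj)
    keep <- max(1L, sum(sv$d^2 >= rel_energy * sv$d[1]^2))
    rec <- sv$u[, seq_len(keep), drop = FALSE] %*%
      (sv$d[seq_len(keep)] * t(sv$v[, seq_len(keep), drop = FALSE]))
    # diagonal averaging back to a series
    out <- numeric(n)
    cnt <- numeric(n)
    for (j in seq_len(K)) {
      idx <- j:(j + L - 1)
      out[idx] <- out[idx] + rec[, j]
      cnt[idx] <- cnt[idx] + 1
    }
    out / cnt
  })
}

apply_cols <- function(x, fn) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- fn(x[, j])
    out
  } else fn(x)
}

#' Process raw EMG into normalized envelopes
#'
#' The standard envelope pipeline: rectify (absolute value), smooth
#' with a zero-phase low-pass (forward-reverse Butterworth, or a
#' singular-spectrum-analysis smoother), clip residual negatives to
#' zero, and normalize each channel by its maximum over the record. An
#' all-zero channel is returned as zeros and flagged.
#'
#' @param emg An `emg_set` (from [synthesize_emg()] or [read_emg()]).
#' @param cutoff Low-pass cutoff, Hz (default 15).
#' @param order Butterworth order per pass (default 5).
#' @param method `"butterworth"` (default) or `"ssa"`.
#' @param ssa_window SSA embedding window, samples (default 250).
#' @return A list of class `envelope_set`: `values` (samples x
#'   channels, in `[0, 1]`), `sample_rate`, `channel_map`,
#'   `zero_channels` (logical per channel).
#' @export
process_emg <- function(emg, cutoff = 15, order = 5,
                        method = c("butterworth", "ssa"),
                        ssa_window = 250) {
  assert_that(inherits(emg, "emg_set"), "`emg` must be an emg_set")
  method <- match.arg(method)
  rect <- abs(emg$signals)
  if (cutoff >= emg$sample_rate / 2)
    stop_invalid("`cutoff` (", cutoff, " Hz) must be below the Nyquist ",
                 "frequency (", emg$sample_rate / 2, " Hz)")
  smoothed <- if (method == "butterworth") {
    butterworth_lowpass(rect, emg$sample_rate, cutoff, order)
  } else {
    ssa_smooth(rect, window = ssa_window)
  }
  smoothed <- pmax(smoothed, 0)
  maxima <- apply(smoothed, 2, max)
  zero_channels <- maxima <= 0
  if (any(zero_channels))
    warning(sum(zero_channels), " all-zero channel(s) returned as zeros",
            call. = FALSE)
  maxima[zero_channels] <- 1
  values <- sweep(smoothed, 2, maxima, "/")
  structure(list(values = values, sample_rate = emg$sample_rate,
                 channel_map = emg$channel_map,
                 zero_channels = zero_channels),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat("<envelope_set> ", ncol(x$values), " channels x ", nrow(x$values),
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Resample envelopes onto the motion frame times
#'
#' Linear interpolation of each envelope channel onto the `f` frame
#' times `0, dt, ..., (f-1) dt`. Linear interpolation of values in
#' `[0, 1]` stays in `[0, 1]`.
#'
#' @param env An `envelope_set`.
#' @param f Number of motion frames.
#' @param dt Motion frame period, s.
#' @return Numeric `f x c` matrix of envelope values at frame times.
#' @export
resample_to_frames <- function(env, f, dt) {
  assert_that(inherits(env, "envelope_set"),
              "`env` must be an envelope_set")
  assert_that(is_count(f) && is_number(dt) && dt > 0,
              "`f` must be a count and `dt` > 0")
  n <- nrow(env$values)
  t_env <- (seq_len(n) - 1) / env$sample_rate
  t_frames <- (seq_len(f) - 1) * dt
  if (max(t_frames) > max(t_env) + 1e-9)
    stop_invalid("trial duration (", max(t_frames),
                 " s) exceeds the EMG recording (", max(t_env), " s)")
  out <- sapply(seq_len(ncol(env$values)), function(j) {
    stats::approx(t_env, env$values[, j], xout = t_frames, rule = 2)$y
  })
  matrix(out, nrow = f,
         dimnames = list(NULL, colnames(env$values) %||%
                           names(env$channel_map)))
}

#' Read raw EMG channels from CSV
#'
#' Expects a `time` column (seconds, uniformly sampled) and one column
#' per channel; the sampling rate is inferred from the time column.
#'
#' @param path CSV file path.
#' @param channel_map Named character vector channel -> muscle label.
#' @return An `emg_set`.
#' @export
read_emg <- function(path, channel_map) {
  assert_that(file.exists(path), "EMG file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_that("time" %in% names(df), "EMG CSV must have a `time` column")
  chans <- setdiff(names(df), "time")
  assert_that(all(names(channel_map) %in% chans),
              "channel_map names missing from the CSV columns")
  dtv <- diff(df$time)
  assert_that(all(abs(dtv - dtv[1]) < 1e-9), "`time` must be uniform")
  structure(list(signals = as.matrix(df[names(channel_map)]),
                 sample_rate = 1 / dtv[1], channel_map = channel_map,
                 delays = rep(0, length(channel_map)),
                 noise_sd = NA_real_, crosstalk = diag(length(channel_map))),
            class = "emg_set")
}
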