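#' Variance accounted for (VAF)
#'
#' Moment-tracking score `100 * (1 - sum((ref - est)^2) / sum(ref^2))`
#' — the uncentered definition standard in the muscle-synergy
#' literature, so that a perfect match scores exactly 100% and the zero
#' estimate scores 0%. A mean-centered variant (reference variance in
#' the denominator around its mean) is available behind `centered`.
#'
#' @param q_ref Numeric reference vector (length >= 2, not all zero).
#' @param q_est Numeric estimate vector of equal length.
#' @param centered Use the mean-centered variant (default `FALSE`).
#' @return VAF in percent (<= 100; can be negative for poor fits).
#' @examples
#' vaf(c(2, 0, -2), c(3, 0, -2)) # 87.5
#' @export
vaf <- function(q_ref, q_est, centered = FALSE) {
  assert_that(length(q_ref) == length(q_est) && length(q_ref) >= 2,
              "`q_ref` and `q_est` must be equal-length vectors (>= 2)")
  denom <- if (centered) sum((q_ref - mean(q_ref))^2) else sum(q_ref^2)
  if (denom == 0)
    stop_invalid("VAF undefined: reference signal has no ",
                 if (centered) "variance" else "energy")
  100 * (1 - sum((q_ref - q_est)^2) / denom)
}

#' Per-DOF VAF between two moment matrices
#'
#' @param q_ref,q_est Numeric `f x d` matrices.
#' @param centered Passed to [vaf()].
#' @return Numeric `d`-vector of VAF percentages.
#' @export
vaf_by_dof <- function(q_ref, q_est, centered = FALSE) {
  assert_that(all(dim(q_ref) == dim(q_est)),
              "`q_ref` and `q_est` must have equal dimensions")
  vapply(seq_len(ncol(q_ref)),
         function(k) vaf(q_ref[, k], q_est[, k], centered = centered),
         numeric(1))
}

#' Maximum lagged Pearson correlation
#'
#' Pearson correlation between `x` and `y` computed on the overlapping
#' samples at every integer-sample lag within `max_lag_ms`; returns the
#' maximum signed correlation and the lag at which it occurs. A
#' positive lag means `y` lags `x` by that amount (e.g. an EMG channel
#' delayed relative to the activation it reflects). Ties are broken
#' toward the smallest absolute lag.
#'
#' @param x,y Numeric vectors of equal length sharing the frame period.
#' @param dt Frame period, s.
#' @param max_lag_ms Maximum tested delay, ms (default 100).
#' @return A list with `r` (max signed Pearson r) and `lag_ms`.
#' @export
lagged_pearson <- function(x, y, dt, max_lag_ms = 100) {
  n <- length(x)
  assert_that(length(y) == n && n >= 3,
              "`x` and `y` must be equal-length vectors (>= 3)")
  max_lag <- floor((max_lag_ms / 1000) / dt)
  max_lag <- min(max_lag, n - 3) # keep a meaningful overlap
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)] # smallest |lag| first for ties
  best_r <- -Inf
  best_lag <- NA_integer_
  for (L in lags) {
    xs <- if (L >= 0) x[seq_len(n - L)] else x[(1 - L):n]
    ys <- if (L >= 0) y[(1 + L):n] else y[seq_len(n + L)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    if (r > best_r) {
      best_r <- r
      best_lag <- L
    }
  }
  if (!is.finite(best_r))
    stop_invalid("correlation undefined: a series is constant over ",
                 "every tested overlap")
  list(r = best_r, lag_ms = best_lag * dt * 1000)
}

#' Mean squared correlation between two activation matrices
#'
#' Per-muscle squared Pearson correlation at zero lag between matching
#' columns, averaged over muscles. Columns that are constant in either
#' matrix carry no shape information and are skipped (their count is
#' reported).
#'
#' @param a,a_star Numeric `f x m` activation matrices.
#' @return A list with `mean_r2`, `r2` (per muscle, `NA` when
#'   skipped), and `n_skipped`.
#' @export
activation_similarity_r2 <- function(a, a_star) {
  assert_that(all(dim(a) == dim(a_star)),
              "`a` and `a_star` must have equal dimensions")
  r2 <- vapply(seq_len(ncol(a)), function(i) {
    if (stats::sd(a[, i]) == 0 || stats::sd(a_star[, i]) == 0)
      return(NA_real_)
    stats::cor(a[, i], a_star[, i])^2
  }, numeric(1))
  if (all(is.na(r2)))
    stop_invalid("no non-constant muscle columns to correlate")
  list(mean_r2 = mean(r2, na.rm = TRUE), r2 = r2,
       n_skipped = sum(is.na(r2)))
}

#' Permutation-matched cosine similarity between synergy vector sets
#'
#' Greedy best-permutation matching of rows (synergy vectors) between
#' two sets, scored by cosine similarity; used to compare recovered
#' synergy vectors against ground truth irrespective of synergy order.
#'
#' @param V_est,V_true Numeric `n x m` matrices.
#' @return A list with `mean_cosine`, `cosine` (per matched pair), and
#'   `permutation` (row of `V_true` matched to each row of `V_est`).
#' @export
match_synergy_vectors <- function(V_est, V_true) {
  assert_that(all(dim(V_est) == dim(V_true)),
              "`V_est` and `V_true` must have equal dimensions")
  n <- nrow(V_est)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  S <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) cosine(V_est[i, ], V_true[j, ])))
  S <- matrix(S, n, n)
  # exact search over permutations for small n, greedy otherwise
  if (n <= 7) {
    perms <- permutations_of(n)
    scores <- vapply(perms, function(p) mean(S[cbind(seq_len(n), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(n)
    avail <- seq_len(n)
    for (i in order(apply(S, 1, max), decreasing = TRUE)) {
      j <- avail[which.max(S[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  sims <- S[cbind(seq_len(n), best)]
  list(mean_cosine = mean(sims), cosine = sims, permutation = best)
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

#' Assemble the three-way method comparison report
#'
#' Collects, as tidy tibbles, the study's comparison tables: per-DOF
#' moment-tracking VAF for SO, SynO (per synergy count) and SO-NMF
#' (per synergy count); maximum lagged Pearson correlation between
#' estimated activations and EMG envelopes per channel; and the mean
#' squared correlation between SO and SO-NMF activations per synergy
#' count.
#'
#' @param trial A [trial_data] with `q_id`.
#' @param so_fit An `so_fit` from [solve_so()].
#' @param syno_fits Named list of `syno_fit` objects (names = synergy
#'   counts), possibly empty.
#' @param sonmf_fits Named list of `sonmf_fit` objects, possibly empty.
#' @param emg Optional `envelope_set`; when given, every channel's
#'   envelope is resampled to the frame times and correlated (max
#'   lagged r within `max_lag_ms`) against the mapped muscle's
#'   estimated activation, per method.
#' @param max_lag_ms Correlation lag window, ms (default 100).
#' @return A list of class `evaluation_report` with tibbles
#'   `moment_vaf` (method, n_s, dof, vaf), `emg_correlation` (method,
#'   n_s, channel, muscle, r, lag_ms) and `activation_similarity`
#'   (n, mean_r2).
#' @export
build_comparison_report <- function(trial, so_fit, syno_fits = list(),
                                    sonmf_fits = list(), emg = NULL,
                                    max_lag_ms = 100) {
  assert_that(inherits(so_fit, "so_fit"), "`so_fit` must be an so_fit")
  d <- length(trial$dof_labels)

  vaf_rows <- list(tibble::tibble(method = "SO", n_s = NA_integer_,
                                  dof = trial$dof_labels, vaf = so_fit$vaf))
  for (fit in syno_fits)
    vaf_rows <- c(vaf_rows, list(tibble::tibble(
      method = "SynO", n_s = fit$n_s, dof = trial$dof_labels,
      vaf = fit$vaf)))
  for (fit in sonmf_fits)
    vaf_rows <- c(vaf_rows, list(tibble::tibble(
      method = "SO-NMF", n_s = fit$n, dof = trial$dof_labels,
      vaf = fit$vaf)))
  moment_vaf <- dplyr::bind_rows(vaf_rows)

  emg_correlation <- NULL
  if (!is.null(emg)) {
    unknown <- setdiff(unname(emg$channel_map), trial$muscle_labels)
    assert_that(length(unknown) == 0,
                "EMG channel_map names muscle(s) absent from the trial: ",
                paste(unknown, collapse = ", "))
    env_f <- resample_to_frames(emg, trial$n_frames, trial$dt)
    acts <- list(list(method = "SO", n_s = NA_integer_,
                      a = so_fit$activations))
    for (fit in syno_fits)
      acts <- c(acts, list(list(method = "SynO", n_s = fit$n_s,
                                a = fit$activations)))
    for (fit in sonmf_fits)
      acts <- c(acts, list(list(method = "SO-NMF", n_s = fit$n,
                                a = fit$a_star)))
    rows <- list()
    for (entry in acts) {
      for (ci in seq_along(emg$channel_map)) {
        muscle <- unname(emg$channel_map[ci])
        mi <- match(muscle, trial$muscle_labels)
        lp <- tryCatch(
          lagged_pearson(entry$a[, mi], env_f[, ci], dt = trial$dt,
                         max_lag_ms = max_lag_ms),
          error = function(e) list(r = NA_real_, lag_ms = NA_real_))
        rows <- c(rows, list(tibble::tibble(
          method = entry$method, n_s = entry$n_s,
          channel = names(emg$channel_map)[ci], muscle = muscle,
          r = lp$r, lag_ms = lp$lag_ms)))
      }
    }
    emg_correlation <- dplyr::bind_rows(rows)
  }

  activation_similarity <- if (length(sonmf_fits)) {
    tibble::tibble(
      n = vapply(sonmf_fits, function(x) x$n, integer(1)),
      mean_r2 = vapply(sonmf_fits, function(x) x$r2_activation, numeric(1)))
  } else NULL

  structure(list(moment_vaf = moment_vaf,
                 emg_correlation = emg_correlation,
                 activation_similarity = activation_similarity),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n\nMoment-tracking VAF (%):\n")
  print(x$moment_vaf, n = Inf)
  if (!is.null(x$emg_correlation)) {
    cat("\nEMG lagged correlation:\n")
    print(x$emg_correlation)
  }
  if (!is.null(x$activation_similarity)) {
    cat("\nSO vs SO-NMF activation similarity (mean r2):\n")
    print(x$activation_similarity)
  }
  invisible(x)
}
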