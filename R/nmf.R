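#' Non-negative matrix factorization with sum-to-one synergy vectors
#'
#' Factorizes a non-negative activation matrix `a` (`f x m`) into
#' `n` synergies, `a ~ H W` with `H` (`f x n`) the time-varying synergy
#' activations and `W` (`n x m`) the synergy vectors, minimizing the
#' Frobenius reconstruction error by multiplicative updates. After
#' every iteration each row of `W` is rescaled to sum to one with the
#' compensating scale absorbed into the corresponding column of `H` — a
#' cost-invariant reparameterization that imposes the same sum-to-one
#' constraint the synergy optimization uses. The best of `n_restarts`
#' seeded random initializations is returned.
#'
#' @param a Numeric non-negative `f x m` matrix.
#' @param n Number of synergies (the study sweeps 2 through 6).
#' @param seed Integer seed for the initializations.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 500).
#' @param tol Relative Frobenius-error change declaring convergence
#'   (default 1e-6).
#' @param extra_init Optional `list(W =, H =)` additional
#'   initialization (e.g. a lower-rank solution padded with a small
#'   extra component), tried alongside the random restarts.
#' @return A list of class `nmf_fit`: `W` (`n x m`, rows sum to 1),
#'   `H` (`f x n`), `error` (Frobenius norm of the residual),
#'   `restart_errors`, `iterations`.
#' @export
fit_nmf_l1 <- function(a, n, seed = 1L, n_restarts = 10, max_iter = 500,
                       tol = 1e-6, extra_init = NULL) {
  assert_that(is.matrix(a), "`a` must be a matrix")
  if (any(a < 0)) stop_invalid("`a` must be non-negative for NMF")
  assert_that(is_count(n) && n <= min(dim(a)),
              "`n` must be a positive integer <= min(dim(a))")
  f <- nrow(a); m <- ncol(a)
  eps <- 1e-12
  scale0 <- max(mean(a), eps)

  run_mu <- function(W, H) {
    err_prev <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      H <- H * (a %*% t(W)) / (H %*% W %*% t(W) + eps)
      W <- W * (t(H) %*% a) / (t(H) %*% H %*% W + eps)
      s <- pmax(rowSums(W), eps) # L1-normalize rows, absorb scale into H
      W <- W / s
      H <- H * rep(s, each = f)
      err <- sqrt(sum((a - H %*% W)^2))
      if (it >= max_iter ||
          (is.finite(err_prev) && abs(err_prev - err) <=
             tol * max(err_prev, eps))) break
      err_prev <- err
    }
    list(W = W, H = H, error = err, iterations = it)
  }

  inits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      list(W = matrix(stats::runif(n * m, 0.1, 1), n, m),
           H = matrix(stats::runif(f * n, 0.1, 1), f, n) * scale0)
    })
  })
  if (!is.null(extra_init)) inits <- c(list(extra_init), inits)
  runs <- lapply(inits, function(z) run_mu(z$W, z$H))
  errors <- vapply(runs, function(r) r$error, numeric(1))
  best <- runs[[which.min(errors)]]
  # final exact renormalization (degenerate zero rows fall back to uniform)
  s <- rowSums(best$W)
  dead <- s < eps
  if (any(dead)) {
    best$W[dead, ] <- 1 / m
    best$H[, dead] <- 0
    s[dead] <- 1
  }
  best$H <- best$H * rep(s, each = f)
  best$W <- best$W / s
  structure(list(W = best$W, H = best$H, error = best$error,
                 restart_errors = errors, iterations = best$iterations,
                 n = as.integer(n)), class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> ", x$n, " synergies, Frobenius error ",
      signif(x$error, 5), " after ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Reconstruct activations from a synergy factorization
#'
#' `a* = sum_i H_i W_i = H W`: the rank-`n` synergy reconstruction of
#' the activation matrix.
#'
#' @param W Numeric `n x m` synergy vectors.
#' @param H Numeric `f x n` synergy activations.
#' @return Numeric `f x m` reconstructed activation matrix.
#' @export
reconstruct_activations <- function(W, H) {
  assert_that(is.matrix(W) && is.matrix(H), "`W` and `H` must be matrices")
  assert_that(ncol(H) == nrow(W),
              "shape mismatch: ncol(H) = ", ncol(H),
              " but nrow(W) = ", nrow(W))
  H %*% W
}

#' Forces and moments implied by reconstructed activations
#'
#' Pushes synergy-reconstructed activations back through the
#' rigid-tendon muscle model and the moment-arm Jacobian. Unlike the
#' static optimization they were derived from, the reconstructed
#' moments carry no equality constraint, so they generally deviate from
#' the inverse-dynamics moments.
#'
#' @param a_star Numeric non-negative `f x m` reconstructed activations.
#' @param trial A [trial_data].
#' @param params A [muscle_params] table.
#' @param curves A [hill_curves] object.
#' @return A list with `f_star` (`f x m` forces, N) and `q_star`
#'   (`f x d` moments, N.m).
#' @export
reconstructed_moments <- function(a_star, trial, params,
                                  curves = hill_curves()) {
  if (any(a_star < 0)) stop_invalid("`a_star` must be non-negative")
  f_star <- compute_muscle_forces(a_star, trial$lmt, trial$vmt, params,
                                  curves)
  q_star <- compute_joint_moments(f_star, trial$moment_arms)
  list(f_star = f_star, q_star = q_star)
}

#' SO-NMF: synergy analysis of a static-optimization solution
#'
#' Decomposes static-optimization activations into `n` synergies with
#' sum-to-one synergy vectors ([fit_nmf_l1()]), reconstructs
#' activations, and derives the reconstructed forces and joint moments
#' through the muscle model.
#'
#' @param trial A [trial_data] with `q_id`.
#' @param params A [muscle_params] table.
#' @param so_activations Numeric `f x m` static-optimization
#'   activations.
#' @param n Number of synergies.
#' @param curves A [hill_curves] object.
#' @param ... Passed to [fit_nmf_l1()] (`seed`, `n_restarts`, ...).
#' @return A list of class `sonmf_fit`: `W`, `H`, `a_star`, `f_star`,
#'   `q_star`, `vaf` (per DOF vs `q_id`, %), `vaf_mean`,
#'   `r2_activation` (mean squared correlation between original and
#'   reconstructed activations), `reconstruction_error`, `n`.
#' @export
analyze_sonmf <- function(trial, params, so_activations, n,
                          curves = hill_curves(), ...) {
  assert_that(!is.null(trial$q_id), "`trial` must carry q_id")
  nm <- fit_nmf_l1(so_activations, n, ...)
  a_star <- reconstruct_activations(nm$W, nm$H)
  rec <- reconstructed_moments(a_star, trial, params, curves)
  vaf_dof <- vaf_by_dof(trial$q_id, rec$q_star)
  structure(list(W = nm$W, H = nm$H, a_star = a_star,
                 f_star = rec$f_star, q_star = rec$q_star,
                 vaf = vaf_dof, vaf_mean = mean(vaf_dof),
                 r2_activation =
                   activation_similarity_r2(so_activations, a_star)$mean_r2,
                 reconstruction_error = nm$error,
                 n = as.integer(n),
                 dof_labels = trial$dof_labels,
                 muscle_labels = trial$muscle_labels), class = "sonmf_fit")
}

#' @export
print.sonmf_fit <- function(x, ...) {
  cat("<sonmf_fit> n = ", x$n, ", mean moment VAF = ",
      sprintf("%.2f%%", x$vaf_mean), ", activation r2 = ",
      sprintf("%.3f", x$r2_activation), "\n", sep = "")
  invisible(x)
}
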