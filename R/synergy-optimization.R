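#' Synergy set: time-varying activations and time-invariant vectors
#'
#' A set of `n_s` muscle synergies: the `f x n_s` matrix `C` of
#' time-varying synergy activations and the `n_s x m` matrix `V` of
#' time-invariant synergy vectors. Muscle activations are their
#' product, `a = C V`. Rows of `V` sum to one — the constraint that
#' makes the factorization unique up to permutation.
#'
#' @param C Numeric `f x n_s` matrix, non-negative.
#' @param V Numeric `n_s x m` matrix, non-negative, rows summing to 1
#'   within `tol`.
#' @param tol Row-sum tolerance (default 1e-6).
#' @return A list of class `synergy_set` with `n_s`, `C`, `V`.
#' @export
synergy_set <- function(C, V, tol = 1e-6) {
  assert_that(is.matrix(C) && is.matrix(V), "`C` and `V` must be matrices")
  assert_that(ncol(C) == nrow(V), "`C` columns must match `V` rows")
  assert_that(all(C >= -1e-12) && all(V >= -1e-12),
              "`C` and `V` must be non-negative")
  assert_that(all(abs(rowSums(V) - 1) <= tol),
              "rows of `V` must sum to 1 (tol ", tol, ")")
  structure(list(n_s = ncol(C), C = C, V = V), class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat("<synergy_set> ", x$n_s, " synergies: C ", nrow(x$C), "x", x$n_s,
      ", V ", x$n_s, "x", ncol(x$V), "\n", sep = "")
  invisible(x)
}

#' Muscle activations from a synergy factorization
#'
#' `a = C V`: each muscle's activation is the synergy-vector-weighted
#' sum of the time-varying synergy activations. Non-negative factors
#' give non-negative activations.
#'
#' @param C Numeric `f x n_s` matrix.
#' @param V Numeric `n_s x m` matrix.
#' @return Numeric `f x m` activation matrix.
#' @export
construct_activations <- function(C, V) {
  assert_that(is.matrix(C) && is.matrix(V), "`C` and `V` must be matrices")
  assert_that(ncol(C) == nrow(V),
              "shape mismatch: ncol(C) = ", ncol(C),
              " but nrow(V) = ", nrow(V))
  C %*% V
}

#' Synergy optimization settings
#'
#' @param beta Moment-tracking weight (default 100): scales the
#'   normalized squared moment-tracking error against the activation
#'   effort term.
#' @param lambda_pen Penalty magnitude applied to `(a - 1)^2` wherever
#'   an activation exceeds 1 (default 1e5). Activations are
#'   non-negative by construction, so only the upper bound needs the
#'   penalty.
#' @param n_multistarts Number of optimization starts (default 5).
#' @param seed Integer seed for the random starts.
#' @param degree B-spline degree (default 3; reduced automatically when
#'   the trial is too short for a cubic).
#' @param maxit L-BFGS-B iteration cap per start.
#' @param factr L-BFGS-B convergence factor (smaller = tighter).
#' @param use_nmf_start Include a data-driven start built from the NMF
#'   of the static-optimization solution (default `TRUE`).
#' @return A list of class `syno_config`.
#' @export
syno_config <- function(beta = 100, lambda_pen = 1e5, n_multistarts = 5,
                        seed = 1L, degree = 3, maxit = 2000, factr = 1e5,
                        use_nmf_start = TRUE) {
  assert_that(is_number(beta) && beta > 0, "`beta` must be > 0")
  assert_that(is_number(lambda_pen) && lambda_pen >= 0,
              "`lambda_pen` must be >= 0")
  assert_that(is_count(n_multistarts), "`n_multistarts` must be >= 1")
  structure(list(beta = beta, lambda_pen = lambda_pen,
                 n_multistarts = as.integer(n_multistarts),
                 seed = as.integer(seed), degree = degree,
                 maxit = maxit, factr = factr,
                 use_nmf_start = isTRUE(use_nmf_start)),
            class = "syno_config")
}

#' Per-DOF moment normalizers
#'
#' The tracking error of each DOF is normalized by the peak absolute
#' inverse-dynamics moment of that DOF over the whole trial; a DOF
#' whose moment is identically zero falls back to 1 with a warning.
#' @keywords internal
moment_normalizers <- function(q_id) {
  norms <- apply(abs(q_id), 2, max)
  if (any(norms == 0)) {
    warning("zero inverse-dynamics moment over a whole DOF; ",
            "normalizer fallback to 1", call. = FALSE)
    norms[norms == 0] <- 1
  }
  norms
}

#' Synergy-optimization cost of an activation/moment pair
#'
#' The penalized moment-tracking cost summed over frames:
#' `sum_j ( beta * sum_k [(Q_mt - Q_id)/max|Q_id_k|]^2 +
#'          sum_i (a^2 + lambda_pen (a - 1)^2 1{a > 1 or a < 0}) )`.
#' The per-DOF normalizer is the peak absolute inverse-dynamics moment
#' over the trial.
#'
#' @param a Numeric `f x m` activation matrix.
#' @param q_mt Numeric `f x d` muscle-produced moments.
#' @param q_id Numeric `f x d` inverse-dynamics moments.
#' @param beta Moment-tracking weight (default 100).
#' @param lambda_pen Out-of-bounds penalty magnitude (default 1e5).
#' @return Scalar cost.
#' @examples
#' # perfect moment match, one frame/muscle/DOF, a = 0.5 -> 0.25
#' syno_cost(matrix(0.5), matrix(2), matrix(2))
#' @export
syno_cost <- function(a, q_mt, q_id, beta = 100, lambda_pen = 1e5) {
  assert_that(all(dim(q_mt) == dim(q_id)),
              "`q_mt` and `q_id` must have equal dimensions")
  norms <- moment_normalizers(q_id)
  res <- sweep(q_mt - q_id, 2, norms, "/")
  out_of_bounds <- a > 1 | a < 0 # lambda is zero only inside [0, 1]
  beta * sum(res^2) + sum(a^2) +
    lambda_pen * sum(((a - 1)^2)[out_of_bounds])
}

# Precomputed linear moment map for a trial:
# Q[j,k] = sum_i RG[j,k,i] a[j,i] + Q0[j,k]
moment_map <- function(trial, params, curves) {
  co <- activation_force_coefficients(trial$lmt, trial$vmt, params, curves)
  f <- trial$n_frames
  d <- length(trial$dof_labels)
  m <- length(trial$muscle_labels)
  RG <- array(0, c(f, d, m))
  for (k in seq_len(d)) {
    rk <- trial$moment_arms[, k, , drop = FALSE]
    dim(rk) <- c(f, m)
    RG[, k, ] <- rk * co$gain
  }
  Q0 <- compute_joint_moments(co$offset, trial$moment_arms)
  list(RG = RG, Q0 = Q0, gain = co$gain, offset = co$offset)
}

map_moments <- function(mm, a) {
  f <- nrow(a); d <- dim(mm$RG)[2]; m <- ncol(a)
  q <- mm$Q0
  for (k in seq_len(d)) {
    rg <- mm$RG[, k, , drop = FALSE]
    dim(rg) <- c(f, m)
    q[, k] <- q[, k] + rowSums(rg * a)
  }
  q
}

#' Synergy-optimization objective for a packed design vector
#'
#' Decodes a packed design (B-spline nodes, then unnormalized synergy
#' vector rows), builds activations `a = C V` with `V` rows normalized
#' to sum 1, pushes them through the muscle model, and evaluates
#' [syno_cost()]. This is the function the SynO solver minimizes.
#'
#' @param design Numeric vector of length `n_s * (p + m)`: `p x n_s`
#'   non-negative nodes followed by the `n_s x m` non-negative
#'   unnormalized synergy weights.
#' @param trial A [trial_data] with `q_id`.
#' @param params A [muscle_params] table.
#' @param n_s Number of synergies.
#' @param config A [syno_config].
#' @param curves A [hill_curves] object.
#' @return Scalar cost.
#' @export
syno_objective <- function(design, trial, params, n_s,
                           config = syno_config(),
                           curves = hill_curves()) {
  ctx <- syno_context(trial, params, n_s, config, curves)
  ctx$fn(design)
}

# Shared solver context: precomputations plus objective/gradient closures.
syno_context <- function(trial, params, n_s, config, curves) {
  assert_that(!is.null(trial$q_id), "`trial` must carry q_id")
  assert_that(is_count(n_s), "`n_s` must be a positive integer")
  f <- trial$n_frames
  m <- length(trial$muscle_labels)
  d <- length(trial$dof_labels)
  p <- node_count(f)
  degree <- min(config$degree, p - 1)
  B <- bspline_basis(f, p, degree = degree, dt = trial$dt)
  mm <- moment_map(trial, params, curves)
  q_id <- trial$q_id
  norms <- moment_normalizers(q_id)
  beta <- config$beta
  lam <- config$lambda_pen

  unpack <- function(design) {
    nodes <- matrix(design[seq_len(p * n_s)], p, n_s)
    U <- matrix(design[p * n_s + seq_len(n_s * m)], n_s, m)
    list(nodes = nodes, U = U)
  }
  decode <- function(design) {
    z <- unpack(design)
    V <- z$U / rowSums(z$U)
    C <- B %*% z$nodes
    list(nodes = z$nodes, U = z$U, V = V, C = C, a = C %*% V)
  }

  fn <- function(design) {
    z <- decode(design)
    q_mt <- map_moments(mm, z$a)
    res <- sweep(q_mt - q_id, 2, norms, "/")
    over <- z$a > 1
    beta * sum(res^2) + sum(z$a^2) + lam * sum(((z$a - 1)^2)[over])
  }

  gr <- function(design) {
    z <- decode(design)
    q_mt <- map_moments(mm, z$a)
    res <- sweep(q_mt - q_id, 2, norms, "/")
    dq <- sweep(res, 2, norms, "/") * (2 * beta)
    dJda <- 2 * z$a
    over <- z$a > 1
    if (any(over)) dJda[over] <- dJda[over] + 2 * lam * (z$a[over] - 1)
    for (k in seq_len(d)) {
      rg <- mm$RG[, k, , drop = FALSE]
      dim(rg) <- c(f, m)
      dJda <- dJda + dq[, k] * rg
    }
    g_nodes <- crossprod(B, dJda %*% t(z$V))
    g_V <- crossprod(z$C, dJda) # n_s x m
    su <- rowSums(z$U)
    g_U <- (g_V - rowSums(g_V * z$V)) / su
    c(as.vector(g_nodes), as.vector(g_U))
  }

  list(f = f, m = m, d = d, p = p, n_s = n_s, degree = degree, B = B,
       mm = mm, q_id = q_id, norms = norms,
       unpack = unpack, decode = decode, fn = fn, gr = gr)
}

pack_design <- function(nodes, U) c(as.vector(nodes), as.vector(U))

# least-squares fit of spline nodes to target curves, clipped to >= 0
fit_nodes <- function(B, target) {
  nodes <- tryCatch(qr.solve(B, target), error = function(e) NULL)
  if (is.null(nodes)) nodes <- matrix(stats::runif(ncol(B) * ncol(target)),
                                      ncol(B), ncol(target))
  pmax(matrix(nodes, ncol(B), ncol(target)), 0)
}

#' Solve the synergy optimization problem (SynO)
#'
#' Simultaneously optimizes, over all frames, the B-spline nodes of
#' `n_s` time-varying synergy activations and their `n_s x m` synergy
#' vectors, minimizing the penalized moment-tracking cost
#' ([syno_cost()]). Design variables are non-negative; synergy vector
#' rows are kept on the sum-to-one simplex by optimizing unnormalized
#' weights and normalizing inside the objective, so returned rows sum
#' to one exactly. The solver is L-BFGS-B with the analytic gradient
#' (force is affine in activation under the rigid-tendon model), run
#' from `n_multistarts` seeded feasible starts; by default one start is
#' data-driven (NMF of the static-optimization solution, nodes fitted
#' to its time courses by least squares) and the rest are random
#' (flat-Dirichlet synergy rows, uniform nodes). The lowest-cost
#' solution wins.
#'
#' @param trial A [trial_data] with `q_id`.
#' @param params A [muscle_params] table.
#' @param n_s Number of synergies (the study sweeps 2 through 6).
#' @param config A [syno_config].
#' @param curves A [hill_curves] object.
#' @param so_activations Optional `f x m` matrix of static-optimization
#'   activations to seed the data-driven start (computed internally
#'   when omitted and `use_nmf_start` is set).
#' @param extra_starts Optional list of `list(nodes =, V =)` starts,
#'   e.g. the solution for `n_s - 1` padded with an inactive synergy.
#' @return A list of class `syno_fit`: `synergies` ([synergy_set]),
#'   `activations`, `moments`, `cost`, `vaf` (per DOF, %), `vaf_mean`,
#'   `n_s`, `start_costs`, `convergence`, `config`.
#' @export
solve_syno <- function(trial, params, n_s, config = syno_config(),
                       curves = hill_curves(), so_activations = NULL,
                       extra_starts = NULL) {
  ctx <- syno_context(trial, params, n_s, config, curves)
  p <- ctx$p; m <- ctx$m; f <- ctx$f

  starts <- list()
  if (config$use_nmf_start) {
    if (is.null(so_activations)) {
      so <- tryCatch(
        solve_so(trial, params,
                 config = so_config(seed = config$seed), curves = curves),
        error = function(e) NULL)
      so_activations <- if (is.null(so)) NULL else so$activations
    }
    if (!is.null(so_activations)) {
      nm <- fit_nmf_l1(pmax(so_activations, 0), n_s,
                       seed = config$seed, n_restarts = 3)
      starts <- c(starts, list(list(nodes = fit_nodes(ctx$B, nm$H),
                                    V = nm$W)))
    }
  }
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  n_random <- max(config$n_multistarts - length(starts), 1L)
  rand <- with_seed(config$seed, {
    lapply(seq_len(n_random), function(i) {
      V <- matrix(stats::rexp(n_s * m), n_s, m)
      list(nodes = matrix(stats::runif(p * n_s), p, n_s),
           V = V / rowSums(V))
    })
  })
  starts <- c(starts, rand)

  runs <- lapply(starts, function(s) {
    design0 <- pack_design(pmax(s$nodes, 0), pmax(s$V, 1e-9))
    res <- tryCatch(
      stats::optim(design0, fn = ctx$fn, gr = ctx$gr, method = "L-BFGS-B",
                   lower = c(rep(0, p * n_s), rep(1e-9, n_s * m)),
                   control = list(maxit = config$maxit,
                                  factr = config$factr)),
      error = function(e) NULL)
    if (is.null(res)) list(value = Inf, par = design0, convergence = NA)
    else res
  })
  costs <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(costs)))
    stop_invalid("synergy optimization failed to converge from any start; ",
                 "start costs: ", paste(signif(costs, 4), collapse = ", "))
  best <- runs[[which.min(costs)]]
  z <- ctx$decode(best$par)
  q_mt <- map_moments(ctx$mm, z$a)
  vaf_dof <- vaf_by_dof(trial$q_id, q_mt)

  structure(list(
    synergies = synergy_set(z$C, z$V),
    activations = z$a, moments = q_mt,
    cost = best$value, vaf = vaf_dof, vaf_mean = mean(vaf_dof),
    n_s = as.integer(n_s), nodes = z$nodes, degree = ctx$degree,
    start_costs = costs, convergence = best$convergence,
    dof_labels = trial$dof_labels, muscle_labels = trial$muscle_labels,
    config = config), class = "syno_fit")
}

#' @export
print.syno_fit <- function(x, ...) {
  cat("<syno_fit> n_s = ", x$n_s, ", cost = ", signif(x$cost, 6),
      ", mean moment VAF = ", sprintf("%.2f%%", x$vaf_mean), "\n", sep = "")
  invisible(x)
}

# pad a fit's solution with one inactive synergy for use as a warm start
pad_syno_start <- function(fit, m) {
  nodes <- cbind(fit$nodes, 0)
  V <- rbind(fit$synergies$V, rep(1 / m, m))
  list(nodes = nodes, V = V)
}
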