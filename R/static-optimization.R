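#' Static optimization settings
#'
#' @param n_multistarts Random initial guesses for the first frame
#'   (default 5). The per-frame problem is strictly convex, so the
#'   starts agree to solver tolerance; the multi-start mirrors the
#'   field's standard practice and guards the nonsmooth dual solve.
#' @param tol Constraint tolerance, relative to the peak absolute
#'   inverse-dynamics moment per DOF (default 1e-6).
#' @param max_polish Active-set polish iterations (default 50).
#' @param seed Integer seed for the random initial guesses.
#' @param reserve_weight If not `NULL`, switches on reserve-actuator
#'   mode: instead of hard equality constraints, residual torques are
#'   allowed and penalized quadratically with this weight.
#' @return A list of class `so_config`.
#' @export
so_config <- function(n_multistarts = 5, tol = 1e-6, max_polish = 50,
                      seed = 1L, reserve_weight = NULL) {
  assert_that(is_count(n_multistarts), "`n_multistarts` must be >= 1")
  assert_that(is_number(tol) && tol > 0, "`tol` must be > 0")
  structure(list(n_multistarts = as.integer(n_multistarts), tol = tol,
                 max_polish = as.integer(max_polish),
                 seed = as.integer(seed), reserve_weight = reserve_weight),
            class = "so_config")
}

# Strictly convex per-frame QP:
#   min sum(a^2)  s.t.  M a = c,  0 <= a <= 1
# solved through its smooth concave dual over the d moment multipliers
# (a(lambda) = clip(M' lambda / 2, 0, 1)), followed by an active-set
# KKT polish that drives the equality residual to machine precision.
solve_box_qp <- function(M, c_vec, lambda0 = NULL, tol = 1e-8,
                         max_polish = 50) {
  d <- nrow(M)
  primal <- function(lambda) pmin(pmax(drop(crossprod(M, lambda)) / 2, 0), 1)
  neg_dual <- function(lambda) {
    a <- primal(lambda)
    -(sum(a^2) - sum(lambda * (M %*% a - c_vec)))
  }
  neg_grad <- function(lambda) -(c_vec - drop(M %*% primal(lambda)))

  if (is.null(lambda0)) {
    MMt <- tcrossprod(M)
    lambda0 <- tryCatch(drop(solve(MMt + 1e-12 * diag(d), 2 * c_vec)),
                        error = function(e) rep(0, d))
  }
  opt <- stats::optim(lambda0, neg_dual, neg_grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  lambda <- opt$par
  a <- primal(lambda)

  # active-set polish: resolve the KKT system on the free set exactly
  for (it in seq_len(max_polish)) {
    free <- a > 1e-12 & a < 1 - 1e-12
    resid <- c_vec - drop(M %*% a)
    if (max(abs(resid)) <= tol) break
    if (!any(free)) break
    Mf <- M[, free, drop = FALSE]
    rhs <- c_vec - drop(M[, !free, drop = FALSE] %*% a[!free])
    mu <- tryCatch(drop(solve(tcrossprod(Mf) + 1e-14 * diag(d), 2 * rhs)),
                   error = function(e) NULL)
    if (is.null(mu)) break
    a_new <- pmin(pmax(drop(crossprod(M, mu)) / 2, 0), 1)
    if (max(abs(c_vec - drop(M %*% a_new))) < max(abs(resid))) {
      a <- a_new
      lambda <- mu
    } else break
  }
  list(a = a, lambda = lambda,
       residual = max(abs(c_vec - drop(M %*% a))))
}

#' Solve one frame of static optimization
#'
#' Minimizes the sum of squared activations subject to exact
#' reproduction of the frame's inverse-dynamics moments
#' (`d` equality constraints through the muscle model) and activation
#' bounds `[0, 1]`. Under the rigid-tendon model musculotendon force is
#' affine in activation, so the constraints are linear and the problem
#' is a strictly convex quadratic program, solved by smooth dual ascent
#' with an active-set polish.
#'
#' @param q_id_j Numeric `d`-vector of inverse-dynamics moments, N.m.
#' @param r_j Numeric `d x m` matrix of signed moment arms at the
#'   frame, m.
#' @param lmt_j,vmt_j Numeric `m`-vectors of musculotendon length and
#'   velocity at the frame.
#' @param params A [muscle_params] table.
#' @param a_init Optional initial activation guess in `[0, 1]^m`
#'   (used to warm-start the dual multipliers).
#' @param curves A [hill_curves] object.
#' @param tol Absolute constraint tolerance (default `1e-6 *
#'   max(1, max |q_id_j|)`).
#' @param reserve_weight If not `NULL`, reserve-actuator mode: solve
#'   `min sum(a^2) + w * ||Q(a) - q_id||^2` over the box instead of the
#'   equality-constrained program.
#' @return Numeric `m`-vector of activations, with attributes
#'   `residual` (max absolute moment residual, N.m) and `lambda`
#'   (equality multipliers).
#' @export
solve_so_frame <- function(q_id_j, r_j, lmt_j, vmt_j, params,
                           a_init = NULL, curves = hill_curves(),
                           tol = NULL, reserve_weight = NULL) {
  d <- length(q_id_j)
  m <- nrow(params)
  assert_that(is.matrix(r_j) && all(dim(r_j) == c(d, m)),
              "`r_j` must be a d x m matrix")
  co <- activation_force_coefficients(matrix(lmt_j, 1), matrix(vmt_j, 1),
                                      params, curves)
  M <- r_j * matrix(drop(co$gain), d, m, byrow = TRUE)
  c_vec <- q_id_j - drop(r_j %*% drop(co$offset))
  tol <- tol %||% (1e-6 * max(1, max(abs(q_id_j))))

  if (!is.null(reserve_weight)) {
    fn <- function(a) sum(a^2) + reserve_weight * sum((drop(M %*% a) - c_vec)^2)
    gr <- function(a) 2 * a + 2 * reserve_weight *
      drop(crossprod(M, drop(M %*% a) - c_vec))
    a0 <- if (is.null(a_init)) rep(0.1, m) else pmin(pmax(a_init, 0), 1)
    res <- stats::optim(a0, fn, gr, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(maxit = 1000, factr = 1e4))
    a <- res$par
    attr(a, "residual") <- max(abs(c_vec - drop(M %*% a)))
    attr(a, "lambda") <- NULL
    return(a)
  }

  lambda0 <- NULL
  if (!is.null(a_init)) {
    assert_that(all(a_init >= -1e-9 & a_init <= 1 + 1e-9),
                "`a_init` must lie in [0, 1]")
    lam_attr <- attr(a_init, "lambda")
    if (!is.null(lam_attr)) lambda0 <- lam_attr
  }
  sol <- solve_box_qp(M, c_vec, lambda0 = lambda0, tol = tol)
  if (sol$residual > tol)
    stop_invalid("infeasible frame: best moment residual ",
                 format(sol$residual, digits = 4), " N.m exceeds tolerance ",
                 format(tol, digits = 4),
                 " (demand outside the muscles' moment capacity)")
  a <- sol$a
  attr(a, "residual") <- sol$residual
  attr(a, "lambda") <- sol$lambda
  a
}

#' Solve static optimization over a whole trial
#'
#' Runs [solve_so_frame()] frame by frame. The first frame is solved
#' from the best of `n_multistarts` seeded random initial guesses; each
#' later frame is warm-started from the previous frame's solution
#' (muscle activation is smooth in gait, so the previous optimum is an
#' excellent guess). With equality constraints satisfied at every
#' frame, the muscle-produced moments reproduce the inverse-dynamics
#' moments to constraint tolerance, i.e. moment VAF is 100% up to
#' round-off.
#'
#' @param trial A [trial_data] with `q_id`.
#' @param params A [muscle_params] table.
#' @param config An [so_config].
#' @param curves A [hill_curves] object.
#' @return A list of class `so_fit`: `activations` (`f x m`), `forces`,
#'   `moments` (`f x d`), `vaf` (per DOF, %), `vaf_mean`, `residuals`
#'   (per frame, N.m), `objective` (per frame `sum(a^2)`).
#' @export
solve_so <- function(trial, params, config = so_config(),
                     curves = hill_curves()) {
  assert_that(inherits(trial, "trial_data"), "`trial` must be a trial_data")
  assert_that(!is.null(trial$q_id), "`trial` must carry q_id")
  f <- trial$n_frames
  d <- length(trial$dof_labels)
  m <- length(trial$muscle_labels)
  tol_dof <- config$tol * pmax(1, apply(abs(trial$q_id), 2, max))
  tol_abs <- max(tol_dof)

  a_mat <- matrix(0, f, m, dimnames = list(NULL, trial$muscle_labels))
  residuals <- numeric(f)
  a_prev <- NULL
  inits <- with_seed(config$seed, {
    lapply(seq_len(config$n_multistarts),
           function(i) stats::runif(m))
  })
  for (j in seq_len(f)) {
    r_j <- trial$moment_arms[j, , , drop = FALSE]
    dim(r_j) <- c(d, m)
    solve_j <- function(a0) {
      tryCatch(
        solve_so_frame(trial$q_id[j, ], r_j, trial$lmt[j, ], trial$vmt[j, ],
                       params, a_init = a0, curves = curves, tol = tol_abs,
                       reserve_weight = config$reserve_weight),
        error = function(e) {
          stop_invalid("static optimization failed at frame ", j, ": ",
                       conditionMessage(e))
        })
    }
    if (j == 1L) {
      cands <- lapply(inits, solve_j)
      obj <- vapply(cands, function(a) sum(a^2), numeric(1))
      a_j <- cands[[which.min(obj)]]
    } else {
      a_j <- solve_j(a_prev)
    }
    a_mat[j, ] <- a_j
    residuals[j] <- attr(a_j, "residual")
    a_prev <- a_j
  }
  forces <- compute_muscle_forces(a_mat, trial$lmt, trial$vmt, params, curves)
  q_mt <- compute_joint_moments(forces, trial$moment_arms)
  vaf_dof <- vaf_by_dof(trial$q_id, q_mt)
  structure(list(activations = a_mat, forces = forces, moments = q_mt,
                 vaf = vaf_dof, vaf_mean = mean(vaf_dof),
                 residuals = residuals,
                 objective = rowSums(a_mat^2),
                 dof_labels = trial$dof_labels,
                 muscle_labels = trial$muscle_labels,
                 config = config), class = "so_fit")
}

#' @export
print.so_fit <- function(x, ...) {
  cat("<so_fit> ", nrow(x$activations), " frames x ", ncol(x$activations),
      " muscles, mean moment VAF = ", sprintf("%.4f%%", x$vaf_mean),
      ", max residual = ", format(max(x$residuals), digits = 3), " N.m\n",
      sep = "")
  invisible(x)
}
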