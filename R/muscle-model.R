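#' Rigid-tendon fiber state and activation-to-force coefficients
#'
#' Under the rigid-tendon assumption the tendon stays at its slack
#' length, so the fiber state follows algebraically from musculotendon
#' kinematics: the along-tendon fiber projection is `lmt - lts`, the
#' constant-thickness pennation model keeps `h = l0 * sin(alpha0)`
#' fixed, fiber length is `sqrt((lmt - lts)^2 + h^2)`, and fiber
#' velocity is the projection `vmt * cos(alpha)`. Force is then affine
#' in activation for fixed kinematics:
#' `F = gain * a + offset` with
#' `gain = f_max * fl * fv * cos(alpha)` and
#' `offset = f_max * fpe * cos(alpha)` (zero when passive force is
#' disabled).
#'
#' @param lmt,vmt Numeric `f x m` matrices of musculotendon lengths (m)
#'   and velocities (m/s, lengthening positive).
#' @param params A [muscle_params] table with `m` rows.
#' @param curves A [hill_curves] object.
#' @return A list with `f x m` matrices `gain` and `offset` (N).
#' @keywords internal
#' @export
activation_force_coefficients <- function(lmt, vmt, params,
                                          curves = hill_curves()) {
  assert_that(is.matrix(lmt) && is.matrix(vmt) && all(dim(lmt) == dim(vmt)),
              "`lmt` and `vmt` must be matrices of equal dimension")
  m <- ncol(lmt)
  assert_that(nrow(params) == m,
              "`params` must have one row per muscle (", m, ")")
  f <- nrow(lmt)
  byrow <- function(v) matrix(v, f, m, byrow = TRUE)

  proj <- lmt - byrow(params$lts)
  if (any(proj <= 0)) {
    bad <- which(proj <= 0, arr.ind = TRUE)[1, ]
    stop_invalid("degenerate geometry: musculotendon length <= tendon ",
                 "slack length for muscle '", params$name[bad[2]],
                 "' at frame ", bad[1])
  }
  h <- byrow(params$l0 * sin(params$alpha0)) # constant muscle thickness
  lfib <- sqrt(proj^2 + h^2)
  cos_a <- proj / lfib
  ln <- lfib / byrow(params$l0)
  vn <- (vmt * cos_a) / byrow(params$vmax * params$l0)

  fmax <- byrow(params$f_max)
  gain <- fmax * curves$fl(ln) * curves$fv(vn) * cos_a
  offset <- fmax * curves$fpe(ln) * cos_a *
    byrow(as.numeric(params$passive_enabled))
  list(gain = gain, offset = offset)
}

#' Musculotendon forces from activations
#'
#' Evaluates the rigid-tendon Hill model
#' `F = f_max * (a * fl(ln) * fv(vn) + fpe(ln)) * cos(alpha)`
#' for every frame and muscle.
#'
#' @param a Numeric `f x m` activation matrix (finite).
#' @inheritParams activation_force_coefficients
#' @return Numeric `f x m` force matrix, N.
#' @examples
#' p <- muscle_params("m1", f_max = 1000, l0 = 0.1, lts = 0.2,
#'                    alpha0 = 0, passive_enabled = FALSE)
#' lmt <- matrix(0.3, 1, 1)  # fiber exactly at optimal length
#' vmt <- matrix(0, 1, 1)
#' compute_muscle_forces(matrix(0.5, 1, 1), lmt, vmt, p,
#'                       curves = unit_hill_curves())  # 500 N
#' @export
compute_muscle_forces <- function(a, lmt, vmt, params,
                                  curves = hill_curves()) {
  assert_that(is.matrix(a) && all(dim(a) == dim(lmt)),
              "`a` must be an f x m matrix matching `lmt`")
  assert_that(all(is.finite(a)), "`a` must be finite")
  co <- activation_force_coefficients(lmt, vmt, params, curves)
  co$gain * a + co$offset
}

#' Joint moments from musculotendon forces
#'
#' Contracts the signed moment-arm tensor with the force matrix:
#' `Q[j, k] = sum_i r[j, k, i] * F[j, i]` — the moment-arm Jacobian
#' transposed applied to the forces, frame by frame. Linear in `F` and
#' additive over muscles.
#'
#' @param forces Numeric `f x m` force matrix, N.
#' @param moment_arms Numeric `f x d x m` signed moment-arm array, m.
#' @return Numeric `f x d` moment matrix, N.m.
#' @export
compute_joint_moments <- function(forces, moment_arms) {
  assert_that(is.array(moment_arms) && length(dim(moment_arms)) == 3L,
              "`moment_arms` must be a 3-d array")
  f <- dim(moment_arms)[1]
  d <- dim(moment_arms)[2]
  m <- dim(moment_arms)[3]
  assert_that(is.matrix(forces) && all(dim(forces) == c(f, m)),
              "`forces` must be an f x m matrix matching `moment_arms`")
  if (anyNA(forces) || anyNA(moment_arms))
    stop_invalid("NaN/NA in forces or moment arms")
  q <- matrix(0, f, d)
  for (k in seq_len(d)) {
    rk <- moment_arms[, k, , drop = FALSE]
    dim(rk) <- c(f, m)
    q[, k] <- rowSums(rk * forces)
  }
  q
}
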