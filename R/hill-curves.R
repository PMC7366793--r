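#' Normalized Hill muscle curves
#'
#' The rigid-tendon model takes three pluggable normalized curves: the
#' active force-length curve `fl` (with `fl(1) = 1`), the
#' force-velocity curve `fv` (with `fv(0) = 1`, shortening negative,
#' lengthening positive), and the passive force-length curve `fpe`
#' (non-negative, zero at and below optimal length). Defaults are the
#' standard smooth shapes: Gaussian active force-length, a logistic
#' force-velocity with an eccentric plateau at 1.5 and near-zero force
#' at maximum shortening velocity, and a C1 quadratic passive curve.
#'
#' @param fl,fv,fpe Vectorized functions of normalized fiber length
#'   (`fl`, `fpe`) or normalized fiber velocity (`fv`).
#' @return A list of class `hill_curves` with elements `fl`, `fv`, `fpe`.
#' @examples
#' crv <- hill_curves()
#' crv$fl(1)   # 1 at optimal length
#' crv$fv(0)   # 1 at zero velocity
#' @export
hill_curves <- function(fl = NULL, fv = NULL, fpe = NULL) {
  fl <- fl %||% function(ln) exp(-((ln - 1) / 0.45)^2)
  fv <- fv %||% function(vn) 1.5 / (1 + 0.5 * exp(-4.06 * vn))
  fpe <- fpe %||% function(ln) ifelse(ln > 1, ((ln - 1) / 0.7)^2, 0)
  structure(list(fl = fl, fv = fv, fpe = fpe), class = "hill_curves")
}

#' Constant-one Hill curves
#'
#' Replaces every normalized curve by 1 (and the passive curve by 0),
#' making force exactly `f_max * a * cos(alpha)`. Used for analytic
#' closed-form checks of the optimization layers.
#' @return A `hill_curves` object.
#' @export
unit_hill_curves <- function() {
  hill_curves(fl = function(ln) rep(1, length(ln)),
              fv = function(vn) rep(1, length(vn)),
              fpe = function(ln) rep(0, length(ln)))
}
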