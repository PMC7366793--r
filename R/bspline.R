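#' Number of B-spline nodes for a trial length
#'
#' Each time-varying synergy activation is parameterized by
#' `p = (f - 1)/5 + 1` B-spline nodal points, rounded to the nearest
#' integer (half-up), where `f` is the number of frames — one node per
#' 5% of the gait cycle plus an endpoint.
#'
#' @param f Number of frames (>= 1).
#' @return Integer node count `p`.
#' @examples
#' node_count(101) # 21
#' node_count(6)   # 2
#' @export
node_count <- function(f) {
  assert_that(is_count(f), "`f` must be a positive integer")
  as.integer(floor((f - 1) / 5 + 1 + 0.5)) # half-up rounding
}

#' Clamped uniform B-spline basis over a trial
#'
#' Basis matrix `B` (`f x p`) of a clamped, uniformly-knotted B-spline
#' of the given degree over the trial duration. The basis functions are
#' non-negative and sum to one at every frame (partition of unity), so
#' non-negative nodes give non-negative curves and equal nodes give a
#' constant curve.
#'
#' @param f Number of frames to evaluate at.
#' @param p Number of basis functions / control nodes (p >= degree + 1).
#' @param degree Spline degree (default 3, cubic).
#' @param dt Frame period (the knot span covers `[0, (f-1) dt]`).
#' @return An `f x p` basis matrix.
#' @export
bspline_basis <- function(f, p, degree = 3, dt = 1) {
  assert_that(is_count(f, min = 1) && is_count(p),
              "`f` and `p` must be positive counts")
  assert_that(is_count(degree + 1), "`degree` must be a non-negative integer")
  assert_that(p >= degree + 1,
              "need at least degree + 1 = ", degree + 1, " nodes, got ", p)
  t_end <- max((f - 1) * dt, dt)
  interior <- if (p - degree - 1 > 0)
    seq(0, t_end, length.out = p - degree + 1)[-c(1, p - degree + 1)]
  else numeric(0)
  knots <- c(rep(0, degree + 1), interior, rep(t_end, degree + 1))
  x <- if (f > 1) seq(0, t_end, length.out = f) else 0
  splines::splineDesign(knots, x, ord = degree + 1)
}

#' Evaluate B-spline synergy activations at the trial frames
#'
#' Maps control nodes to time-varying synergy activations:
#' `C[j, s] = sum_k B_k(t_j) nodes[k, s]`. Non-negative nodes yield
#' non-negative activations because the basis is a partition of unity.
#'
#' @param nodes Numeric `p x n_s` matrix of non-negative control values.
#' @param f Number of frames.
#' @param degree Spline degree (default 3).
#' @param dt Frame period, s.
#' @return Numeric `f x n_s` matrix `C`.
#' @export
evaluate_synergy_activations <- function(nodes, f, degree = 3, dt = 1) {
  assert_that(is.matrix(nodes), "`nodes` must be a p x n_s matrix")
  B <- bspline_basis(f, nrow(nodes), degree = degree, dt = dt)
  B %*% nodes
}
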