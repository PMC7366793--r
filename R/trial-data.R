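#' Musculoskeletal trial container
#'
#' Bundles everything the activation-estimation methods need for one
#' recorded (or synthesized) trial: the inverse-dynamics joint moments
#' `q_id` (the tracking target), the signed moment-arm tensor mapping
#' musculotendon forces to joint moments, and the musculotendon
#' lengths/velocities that drive the rigid-tendon muscle model.
#'
#' @param dt Seconds per frame (> 0).
#' @param moment_arms Numeric array `f x d x m` of signed moment arms in
#'   meters; `r > 0` means the muscle produces a positive moment about
#'   that degree of freedom.
#' @param lmt,vmt Numeric matrices `f x m`: musculotendon lengths (m) and
#'   velocities (m/s, lengthening positive).
#' @param q_id Optional numeric matrix `f x d` of inverse-dynamics joint
#'   moments (N.m). A trial without `q_id` describes the plant only.
#' @param dof_labels,muscle_labels Character labels; defaulted from the
#'   array dimensions when omitted.
#'
#' @return An object of class `trial_data`: a list with elements
#'   `n_frames`, `dt`, `dof_labels`, `muscle_labels`, `q_id`,
#'   `moment_arms`, `lmt`, `vmt`.
#' @seealso [generate_plant()], [forward_consistent_trial()],
#'   [write_trial()]
#' @export
trial_data <- function(dt, moment_arms, lmt, vmt, q_id = NULL,
                       dof_labels = NULL, muscle_labels = NULL) {
  assert_that(is_number(dt) && dt > 0, "`dt` must be a positive number")
  assert_that(is.array(moment_arms) && length(dim(moment_arms)) == 3L,
              "`moment_arms` must be a 3-d array (frames x dofs x muscles)")
  f <- dim(moment_arms)[1]
  d <- dim(moment_arms)[2]
  m <- dim(moment_arms)[3]
  assert_that(is.matrix(lmt) && all(dim(lmt) == c(f, m)),
              "`lmt` must be an f x m matrix matching `moment_arms`")
  assert_that(is.matrix(vmt) && all(dim(vmt) == c(f, m)),
              "`vmt` must be an f x m matrix matching `moment_arms`")
  if (!is.null(q_id)) {
    assert_that(is.matrix(q_id) && all(dim(q_id) == c(f, d)),
                "`q_id` must be an f x d matrix matching `moment_arms`")
    assert_that(all(is.finite(q_id)), "`q_id` must be finite")
  }
  assert_that(all(is.finite(moment_arms)), "`moment_arms` must be finite")
  assert_that(all(is.finite(lmt)) && all(lmt > 0),
              "`lmt` must be finite and positive")
  assert_that(all(is.finite(vmt)), "`vmt` must be finite")
  dof_labels <- dof_labels %||% default_dof_labels(d)
  muscle_labels <- muscle_labels %||% default_muscle_labels(m)
  assert_that(length(dof_labels) == d, "need one dof label per DOF")
  assert_that(length(muscle_labels) == m, "need one muscle label per muscle")

  structure(
    list(n_frames = f, dt = dt,
         dof_labels = as.character(dof_labels),
         muscle_labels = as.character(muscle_labels),
         q_id = q_id, moment_arms = moment_arms, lmt = lmt, vmt = vmt),
    class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data> ", x$n_frames, " frames x ", length(x$dof_labels),
      " DOFs x ", length(x$muscle_labels), " muscles, dt = ", x$dt, " s\n",
      sep = "")
  cat("  q_id: ", if (is.null(x$q_id)) "absent (plant only)" else "present",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.trial_data <- function(x) dim(x$moment_arms)

# frame times, 0-based
trial_times <- function(trial) (seq_len(trial$n_frames) - 1) * trial$dt
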