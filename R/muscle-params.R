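#' Hill-type muscle parameter table
#'
#' One row per muscle with the constants of the rigid-tendon Hill model:
#' maximum isometric force, optimal fiber length, tendon slack length,
#' pennation angle at optimal fiber length, and maximum shortening
#' velocity. `passive_enabled` switches the parallel-elastic (passive)
#' force term on or off per muscle.
#'
#' @param name Character muscle labels.
#' @param f_max Maximum isometric force, N (> 0).
#' @param l0 Optimal fiber length, m (> 0).
#' @param lts Tendon slack length, m (>= 0).
#' @param alpha0 Pennation angle at optimal fiber length, rad, in
#'   `[0, pi/2)`.
#' @param vmax Maximum shortening velocity in optimal fiber lengths per
#'   second (> 0).
#' @param passive_enabled Logical, include the passive force term.
#'
#' @return A tibble of class `muscle_params`.
#' @export
muscle_params <- function(name, f_max, l0, lts, alpha0 = 0,
                          vmax = 10, passive_enabled = TRUE) {
  out <- tibble::tibble(name = as.character(name),
                        f_max = as.numeric(f_max),
                        l0 = as.numeric(l0),
                        lts = as.numeric(lts),
                        alpha0 = as.numeric(alpha0),
                        vmax = as.numeric(vmax),
                        passive_enabled = as.logical(passive_enabled))
  assert_that(all(out$f_max > 0), "`f_max` must be > 0")
  assert_that(all(out$l0 > 0), "`l0` must be > 0")
  assert_that(all(out$lts >= 0), "`lts` must be >= 0")
  assert_that(all(out$alpha0 >= 0 & out$alpha0 < pi / 2),
              "`alpha0` must lie in [0, pi/2)")
  assert_that(all(out$vmax > 0), "`vmax` must be > 0")
  class(out) <- c("muscle_params", class(out))
  out
}

#' Read or write muscle parameters as CSV
#'
#' The on-disk format is a plain CSV with header
#' `name,f_max,l0,lts,alpha0,vmax` and an optional `passive_enabled`
#' column (defaulting to `TRUE` when absent).
#'
#' @param path File path.
#' @return `read_muscle_params()` returns a [muscle_params] table;
#'   `write_muscle_params()` returns `path` invisibly.
#' @export
read_muscle_params <- function(path) {
  assert_that(file.exists(path), "muscle parameter file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("name", "f_max", "l0", "lts", "alpha0", "vmax")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0,
              "muscle parameter CSV missing column(s): ",
              paste(missing, collapse = ", "))
  if (!"passive_enabled" %in% names(df)) df$passive_enabled <- TRUE
  muscle_params(df$name, df$f_max, df$l0, df$lts, df$alpha0, df$vmax,
                df$passive_enabled)
}

#' @rdname read_muscle_params
#' @param params A [muscle_params] table.
#' @export
write_muscle_params <- function(params, path) {
  readr::write_csv(tibble::as_tibble(unclass(params)), path)
  invisible(path)
}

#' Synthetic Hill parameters consistent with a generated plant
#'
#' Derives a plausible parameter set from the musculotendon length
#' trajectories of a synthetic plant: the optimal fiber length is sized
#' to the muscle's excursion so normalized fiber length stays near 1,
#' and the tendon slack length places the operating point at the center
#' of the force-length curve. Maximum isometric forces span the range
#' typical of adult lower-limb muscles.
#'
#' @param plant A [trial_data] plant (with or without `q_id`).
#' @param seed Integer seed for the per-muscle draws.
#' @param passive_enabled Include passive force (default `TRUE`).
#' @return A [muscle_params] table with one row per plant muscle.
#' @export
synthetic_muscle_params <- function(plant, seed = 1L, passive_enabled = TRUE) {
  assert_that(inherits(plant, "trial_data"), "`plant` must be a trial_data")
  m <- length(plant$muscle_labels)
  rng <- with_seed(seed, {
    list(f_max = stats::runif(m, 300, 3000),
         alpha0 = stats::runif(m, 0, 0.25),
         l0_scale = stats::runif(m, 2.2, 3.0))
  })
  lmt_min <- apply(plant$lmt, 2, min)
  lmt_max <- apply(plant$lmt, 2, max)
  lmt_mid <- (lmt_min + lmt_max) / 2
  excursion <- pmax(lmt_max - lmt_min, 1e-4)
  # fiber sized so the excursion maps to roughly +/- 0.2 normalized length
  l0 <- pmax(rng$l0_scale * excursion, 0.06 * lmt_mid)
  lts <- pmax(lmt_mid - l0 * cos(rng$alpha0), 0.02 * lmt_mid)
  muscle_params(plant$muscle_labels, rng$f_max, l0, lts, rng$alpha0,
                vmax = 10, passive_enabled = passive_enabled)
}
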