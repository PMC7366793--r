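# internal helpers

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_invalid(...)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
default_muscle_labels <- function(m) sprintf("muscle_%02d", seq_len(m))

#' @keywords internal
default_dof_labels <- function(d) {
  base <- c("hip_abd_add", "hip_flex_ext", "hip_int_ext_rot",
            "knee_flex_ext", "ankle_int_ext_rot", "ankle_plantar_dorsi")
  if (d <= length(base)) base[seq_len(d)] else c(base, sprintf("dof_%02d", seq_len(d - length(base)) + length(base)))
}

# Seeded evaluation that never leaks RNG state into the caller's session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
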