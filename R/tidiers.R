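#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a static-optimization fit
#'
#' @param x An `so_fit`.
#' @param ... Unused.
#' @return A tibble with one row per frame-muscle pair: `frame`,
#'   `muscle`, `activation`, `force`.
#' @export
tidy.so_fit <- function(x, ...) {
  f <- nrow(x$activations)
  tibble::tibble(
    frame = rep(seq_len(f), times = ncol(x$activations)),
    muscle = rep(x$muscle_labels, each = f),
    activation = as.vector(x$activations),
    force = as.vector(x$forces))
}

#' @rdname tidy.so_fit
#' @export
glance.so_fit <- function(x, ...) {
  tibble::tibble(method = "SO", vaf_mean = x$vaf_mean,
                 max_residual = max(x$residuals),
                 mean_objective = mean(x$objective))
}

#' Tidy a synergy-optimization fit
#'
#' @param x A `syno_fit`.
#' @param ... Unused.
#' @return A tibble of synergy vector weights: `synergy`, `muscle`,
#'   `weight`.
#' @export
tidy.syno_fit <- function(x, ...) {
  V <- x$synergies$V
  tibble::tibble(
    synergy = rep(seq_len(nrow(V)), times = ncol(V)),
    muscle = rep(x$muscle_labels, each = nrow(V)),
    weight = as.vector(V))
}

#' @rdname tidy.syno_fit
#' @export
glance.syno_fit <- function(x, ...) {
  tibble::tibble(method = "SynO", n_s = x$n_s, cost = x$cost,
                 vaf_mean = x$vaf_mean,
                 n_starts = length(x$start_costs),
                 convergence = x$convergence)
}

#' Tidy an SO-NMF fit
#'
#' @param x An `sonmf_fit`.
#' @param ... Unused.
#' @return A tibble of synergy vector weights: `synergy`, `muscle`,
#'   `weight`.
#' @export
tidy.sonmf_fit <- function(x, ...) {
  tibble::tibble(
    synergy = rep(seq_len(nrow(x$W)), times = ncol(x$W)),
    muscle = rep(x$muscle_labels, each = nrow(x$W)),
    weight = as.vector(x$W))
}

#' @rdname tidy.sonmf_fit
#' @export
glance.sonmf_fit <- function(x, ...) {
  tibble::tibble(method = "SO-NMF", n = x$n, vaf_mean = x$vaf_mean,
                 r2_activation = x$r2_activation,
                 reconstruction_error = x$reconstruction_error)
}
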