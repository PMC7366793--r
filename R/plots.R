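#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synergy set
#'
#' Time-varying synergy activations as line traces (one facet) and the
#' synergy vector weights as a muscle-by-synergy tile map.
#'
#' @param object A [synergy_set].
#' @param dt Frame period used for the time axis (default 1, i.e.
#'   frames).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_set <- function(object, dt = 1, ...) {
  f <- nrow(object$C)
  dfC <- tibble::tibble(
    time = rep((seq_len(f) - 1) * dt, times = object$n_s),
    synergy = factor(rep(seq_len(object$n_s), each = f)),
    activation = as.vector(object$C))
  ggplot2::ggplot(dfC, ggplot2::aes(.data$time, .data$activation,
                                    colour = .data$synergy)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = if (dt == 1) "frame" else "time (s)",
                  y = "synergy activation",
                  title = sprintf("%d synergy activations", object$n_s)) +
    ggplot2::theme_minimal()
}

#' Plot moment tracking of a fit
#'
#' Inverse-dynamics joint moments against the moments produced by the
#' estimated muscle forces, one facet per DOF.
#'
#' @param trial A [trial_data] with `q_id`.
#' @param fit An `so_fit`, `syno_fit` or `sonmf_fit` (anything with a
#'   `moments` or `q_star` element).
#' @return A ggplot object.
#' @export
plot_moment_tracking <- function(trial, fit) {
  q_est <- fit$moments %||% fit$q_star
  assert_that(!is.null(q_est), "`fit` carries no moment estimate")
  f <- trial$n_frames
  t <- trial_times(trial)
  df <- dplyr::bind_rows(
    tibble::tibble(time = rep(t, length(trial$dof_labels)),
                   dof = rep(trial$dof_labels, each = f),
                   moment = as.vector(trial$q_id),
                   source = "inverse dynamics"),
    tibble::tibble(time = rep(t, length(trial$dof_labels)),
                   dof = rep(trial$dof_labels, each = f),
                   moment = as.vector(q_est),
                   source = "muscle-produced"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$moment,
                                   colour = .data$source)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~dof, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "joint moment (N m)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot an evaluation report
#'
#' Mean moment-tracking VAF against synergy count per method, with the
#' SO reference as a horizontal line.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- object$moment_vaf |>
    dplyr::group_by(.data$method, .data$n_s) |>
    dplyr::summarise(vaf = mean(.data$vaf), .groups = "drop")
  so_level <- df$vaf[df$method == "SO"]
  p <- ggplot2::ggplot(dplyr::filter(df, !is.na(.data$n_s)),
                       ggplot2::aes(.data$n_s, .data$vaf,
                                    colour = .data$method)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "number of synergies", y = "mean moment VAF (%)") +
    ggplot2::theme_minimal()
  if (length(so_level))
    p <- p + ggplot2::geom_hline(yintercept = so_level,
                                 linetype = "dashed", colour = "grey40")
  p
}
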