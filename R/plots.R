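#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a net-charge-vs-pH profile
#'
#' Charge curve with the zero-charge line and, when defined, the pI marked
#' as the grey circle of the in-silico analysis.
#'
#' @param object A `charge_profile` from [charge_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.charge_profile <- function(object, ...) {
  pI <- attr(object, "pI")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$ph, y = .data$net_charge)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "pH", y = "Net charge (e)",
                  title = attr(object, "sequence_id"),
                  subtitle = if (!is.na(pI)) sprintf("pI = %.2f", pI) else
                    "pI undefined") +
    ggplot2::theme_minimal()
  if (!is.na(pI)) {
    p <- p + ggplot2::annotate("point", x = pI, y = 0, shape = 21, size = 3,
                               fill = "grey70")
  }
  p
}

#' Plot screening results
#'
#' Charge at each report pH per construct (dodged bars) with pI on a
#' secondary axis as grey points, STAND designations starred in the x
#' labels.
#'
#' @param records Screening tibble from [screen_constructs()].
#' @return A ggplot.
#' @export
plot_screen <- function(records) {
  long <- tidyr::pivot_longer(records, dplyr::starts_with("charge_"),
                              names_to = "ph", values_to = "net_charge",
                              names_prefix = "charge_")
  long$label <- ifelse(long$is_stand, paste0(long$id, " *"), long$id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$net_charge,
                                     fill = .data$ph)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Net charge (e)", fill = "pH",
                  caption = "* designated STAND") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname fit_hill_langmuir
#' @param object A `binding_fit`.
#' @export
autoplot.binding_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration_nM,
                                    y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[protein] (nM)", y = "Specific binding",
                  title = "Hill-Langmuir saturation binding") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      concentration_nM = exp(seq(log(min(object$data$concentration_nM)),
                                 log(max(object$data$concentration_nM)),
                                 length.out = 200)))
    grid$response <- predict(object, grid$concentration_nM)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("Kd = %.3g nM, Bmax = %.3g",
                                       object$kd, object$bmax))
  }
  p
}

#' @rdname fit_half_life
#' @param object A `half_life_fit`.
#' @export
autoplot.half_life_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_min,
                                    y = .data$fluorescence)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "Fluorescence (a.u.)",
                  title = "Thermal unfolding") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(time_min = seq(min(object$data$time_min),
                                          max(object$data$time_min),
                                          length.out = 200))
    grid$fluorescence <- object$f0 +
      (object$fmax - object$f0) * grid$time_min / (object$t_half + grid$time_min)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$t_half, linetype = "dotted") +
      ggplot2::labs(subtitle = sprintf("t1/2 = %.3g min", object$t_half))
  }
  p
}

#' Plot charge (or pI) against aggregation rate
#'
#' Scatter of the screening panel used for the charge-aggregation
#' correlation, annotated with Pearson r and its t-based p-value.
#'
#' @param records Screening tibble from [screen_constructs()].
#' @param summaries Summary tibble from [aggregation_summary()].
#' @param ph pH of the charge axis, or `"pI"`.
#' @return A ggplot.
#' @export
plot_charge_aggregation <- function(records, summaries, ph = 6.6) {
  axis <- if (identical(ph, "pI")) "pI" else charge_col(ph)
  joined <- dplyr::inner_join(
    dplyr::select(records, "id", value = dplyr::all_of(axis)),
    dplyr::select(summaries, id = "construct_id", "mean_rate", "sem"),
    by = "id")
  res <- correlate_charge_aggregation(records, summaries, ph = ph)
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$value, y = .data$mean_rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                                        ymax = .data$mean_rate + .data$sem),
                           width = 0, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = if (axis == "pI") "pI" else
                    sprintf("Net charge at pH %s (e)", sub("charge_", "", axis)),
                  y = "Aggregation rate (%)",
                  subtitle = sprintf("r = %.4f, P = %.3g (n = %d)",
                                     res$r, res$p_t, res$n)) +
    ggplot2::theme_minimal()
}
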