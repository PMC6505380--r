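#' Plot concentration-time profiles
#'
#' Semilog (or linear) spaghetti plot of every profile in a table, coloured
#' by treatment group.
#'
#' @param profiles A validated profile tibble (see [pk_profiles()]).
#' @param log_y Use a log10 concentration axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, log_y = TRUE) {
  quant <- dplyr::filter(profiles, !.data$blq)
  p <- ggplot2::ggplot(quant,
         ggplot2::aes(x = .data$time_h, y = .data$conc,
                      colour = .data$group,
                      group = interaction(.data$subject_id, .data$analyte))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "Time (h)",
                  y = paste0("Concentration (", quant$conc_unit[1], ")"),
                  colour = "Group") +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn fit_michaelis_menten Plot the data and fitted
#'   Michaelis-Menten curve.
#' @param object An `mm_fit` object.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  s_max <- max(object$assay$conc_um)
  curve <- tibble::tibble(
    conc_um = seq(0, s_max, length.out = 200),
    velocity = object$vmax * seq(0, s_max, length.out = 200) /
      (object$km + seq(0, s_max, length.out = 200))
  )
  ggplot2::ggplot(object$assay,
                  ggplot2::aes(x = .data$conc_um, y = .data$velocity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "[S] (uM)", y = "V",
                  title = sprintf("Km = %.3g uM, Vmax = %.3g",
                                  object$km, object$vmax)) +
    ggplot2::theme_bw()
}
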