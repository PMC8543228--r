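# Figures for effect curves and surfaces (ggplot2, optional).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to draw figures")
}

#' Plot a dose-response reallocation curve
#'
#' Hazard ratio (with Wald ribbon when available) against minutes/day in
#' the focal behaviour; the reference composition is marked.
#'
#' @param curve An `effect_curve` from [dose_response()].
#' @return A ggplot object.
#' @export
plot_effect_curve <- function(curve) {
  .need_ggplot()
  gg <- ggplot2::ggplot(curve,
                        ggplot2::aes(x = .data$focal_min, y = .data$hr))
  if (!all(is.na(curve$lo)))
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.2)
  gg + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point(data = curve[curve$is_ref, , drop = FALSE],
                        size = 2) +
    ggplot2::labs(x = paste0(curve$focal[1], " (min/day)"),
                  y = "hazard ratio") +
    ggplot2::theme_minimal()
}

#' Plot a joint waking-day hazard-ratio heat map
#'
#' MVPA on the x-axis, sedentary time on the y-axis, fill = hazard ratio
#' against the reference; LIPA isotime contour lines overlaid.
#'
#' @param surface An `effect_surface` from [joint_heatmap()].
#' @param isotime_lines LIPA values (min/day) for contour lines.
#' @return A ggplot object.
#' @export
plot_effect_surface <- function(surface,
                                isotime_lines = seq(60, 420, 60)) {
  .need_ggplot()
  d <- surface[surface$feasible, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mvpa, y = .data$sb)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$hr)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$lipa),
                          breaks = isotime_lines, colour = "black",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "HR", option = "B") +
    ggplot2::labs(x = "MVPA (min/day)", y = "SB (min/day)") +
    ggplot2::theme_minimal()
}
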