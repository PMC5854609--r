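# ggplot2 helpers for the main result types.

#' Plot helpers
#'
#' `plot_elispot()` shows per-condition mean spot counts against the
#' positivity threshold; `plot_polyfunctionality()` the cytokine-combination
#' frequencies; `plot_discordance()` the patient-by-neo-epitope compartment
#' landscape; `plot_vj_usage()` a Manhattan-style V-J recombination plot
#' with segments at their chromosomal order.
#'
#' @param calls tibble from [call_elispot()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_elispot <- function(calls, ...) {
  ggplot2::ggplot(filter(calls, .data$role != "viability_control"),
                  ggplot2::aes(x = .data$condition, y = .data$mean_spots,
                               fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::labs(y = "mean spots / well", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_elispot
#' @param summary tibble from [decompose_polyfunctionality()].
#' @export
plot_polyfunctionality <- function(summary, ...) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$combination,
                                                  -.data$frequency),
                               y = .data$frequency,
                               fill = factor(.data$n_cytokines))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of responding cells",
                  fill = "cytokines") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_elispot
#' @param landscape tibble from [discordance_landscape()].
#' @export
plot_discordance <- function(landscape, ...) {
  pal <- c("PBL-only" = "steelblue", "TIL-only" = "firebrick",
           "both" = "orange", "none" = "white")
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$label, y = .data$patient_id,
                               fill = .data$category)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "neo-epitope", y = "patient") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_elispot
#' @param usage tibble from [vj_usage()] (one compartment).
#' @export
plot_vj_usage <- function(usage, ...) {
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$v_order, y = .data$j_order,
                                      size = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(
      breaks = usage$v_order, labels = usage$v_segment) +
    ggplot2::scale_y_continuous(
      breaks = usage$j_order, labels = usage$j_segment) +
    ggplot2::labs(x = "V segment (chromosomal order)",
                  y = "J segment (chromosomal order)",
                  size = "summed frequency") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
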