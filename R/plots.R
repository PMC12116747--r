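# ggplot2 views of the main result types.

#' @method autoplot apa_shift_result
#' @export
autoplot.apa_shift_result <- function(object, ...) {
  samples <- attr(object, "samples") %||% c(a = "control", b = "treatment")
  d <- as_tibble(object) %>%
    mutate(direction = factor(.data$direction,
                              levels = c("lengthened", "shortened", "none")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dist_frac_a, y = .data$dist_frac_b,
                                  colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(lengthened = "#d73027",
                                            shortened = "#1a9850",
                                            none = "grey70"),
                                 drop = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("distal signal fraction (%s)", samples[["a"]]),
                  y = sprintf("distal signal fraction (%s)", samples[["b"]]),
                  colour = "3' UTR call") +
    ggplot2::theme_minimal()
}

#' @method autoplot apa_stratified
#' @export
autoplot.apa_stratified <- function(object, ...) {
  d <- mutate(object$unit_values,
              group = factor(.data$group, levels = c("low", "high")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::scale_fill_manual(values = c(low = "#74add1", high = "#f46d43"),
                               guide = "none") +
    ggplot2::labs(x = sprintf("%s expression group", object$marker),
                  y = sprintf("mean PDUI per %s", object$units),
                  subtitle = sprintf("Mann-Whitney U = %.0f, p = %.2g",
                                     object$statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Per-position signal profile plot for one consensus PAC
#'
#' Displays the two samples' normalised 3'-end signal along the PAC
#' (5' to 3'), the density view used to inspect individual genes' usage
#' shifts.
#'
#' @param profiles Profile table from [pac_signal_profiles()].
#' @param consensus_id The PAC to plot.
#' @return A ggplot.
#' @export
plot_pac_profiles <- function(profiles, consensus_id) {
  samples <- attr(profiles, "samples") %||% c(a = "control", b = "treatment")
  d <- profiles %>%
    filter(.data$consensus_id == !!consensus_id) %>%
    select("rank", "position", "p_a", "p_b") %>%
    tidyr::pivot_longer(c("p_a", "p_b"), names_to = "sample",
                        values_to = "signal") %>%
    mutate(sample = ifelse(.data$sample == "p_a", samples[["a"]],
                           samples[["b"]]))
  if (nrow(d) == 0) abort(sprintf("no profile for '%s'", consensus_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$signal,
                                  fill = .data$sample)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55, width = 1) +
    ggplot2::labs(x = "position within PAC (5' to 3')",
                  y = "normalised 3'-end signal", fill = NULL,
                  title = consensus_id) +
    ggplot2::theme_minimal()
}
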