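#' @export
#' @method autoplot synchrony_matrix
autoplot.synchrony_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  df$r <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = sprintf("Synchrony matrix (bin %g s)",
                                  attr(object, "bin_width_s"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
#' @method autoplot joint_isi
autoplot.joint_isi <- function(object, ...) {
  df <- tidy.joint_isi(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$isi1_s, y = .data$isi2_s,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "ISI k (s)", y = "ISI k+1 (s)", fill = "pairs",
                  title = "Joint inter-spike-interval distribution") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot connectivity_report
autoplot.connectivity_report <- function(object, ...) {
  df <- object$trials %>%
    mutate(trial = factor(.data$trial_id, levels = .data$trial_id)) %>%
    tidyr::pivot_longer(c("n_edges", "mean_synchrony",
                          "similarity_to_prev"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$value,
                                   group = .data$metric,
                                   colour = .data$paradigm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(colour = "grey50", linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Connectivity series metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
#' @method autoplot rhythmic_report
autoplot.rhythmic_report <- function(object, ...) {
  df <- object$gaps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pulses, y = .data$abs_gap)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "pulse repetitions",
                  y = "|40 Hz - 7.8 Hz| metric gap",
                  title = "Adaptive convergence of stimulation effects") +
    ggplot2::theme_minimal()
}
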