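# ggplot2 companions for the main result types.

#' Plot the promoter score distribution with threshold and antimode
#'
#' Density of `log10(crpkm + offset)` per cell state; the activity
#' threshold and (optionally) the estimated antimode are drawn as vertical
#' lines. The bimodal shape with its valley near the threshold is the
#' visual justification of the activity cutoff.
#'
#' @param records Score tibble with `crpkm` and `cell_state`.
#' @param threshold Activity cutoff to mark (default 8).
#' @param antimode Optional antimode estimate to mark.
#' @param offset Log offset (default 0.1).
#' @return A ggplot object.
#' @export
plot_crpkm_density <- function(records, threshold = 8, antimode = NULL,
                               offset = 0.1) {
  df <- mutate(records, lx = log10(.data$crpkm + offset))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lx,
                                        colour = .data$cell_state)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = log10(threshold + offset),
                        linetype = "dashed") +
    ggplot2::labs(
      x = expression(log[10](cRPKM + offset)), y = "density",
      colour = "cell state"
    )
  if (!is.null(antimode) && is.finite(antimode)) {
    p <- p + ggplot2::geom_vline(xintercept = log10(antimode + offset),
                                 linetype = "dotted")
  }
  p
}

#' Plot a binned frequency distribution
#'
#' @param freq Tibble from [frequency_distribution()].
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_frequency_distribution <- function(freq, xlab = "value") {
  ggplot2::ggplot(freq, ggplot2::aes(.data$bin_center, .data$freq)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = xlab, y = "relative frequency")
}

#' Scatter of ongoing transcription vs steady-state mRNA
#'
#' log10 RPKM against log10 FPKM for one cell state; genes well below the
#' diagonal produce much less steady-state mRNA than their transcription
#' predicts, i.e. candidate unstable transcripts.
#'
#' @param omics Wide omics tibble.
#' @param cell_state `"pre_pro_B"` or `"pro_B"`.
#' @return A ggplot object.
#' @export
plot_stability_scatter <- function(omics, cell_state = "pro_B") {
  r <- omics[[paste0("rpkm_", cell_state)]]
  f <- omics[[paste0("fpkm_", cell_state)]]
  keep <- !is.na(r) & !is.na(f) & r > 0 & f > 0
  df <- tibble(rpkm = log10(r[keep]), fpkm = log10(f[keep]))
  ggplot2::ggplot(df, ggplot2::aes(.data$rpkm, .data$fpkm)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(log[10] ~ "RPKM (ongoing transcription)"),
      y = expression(log[10] ~ "FPKM (steady-state mRNA)"),
      title = cell_state
    )
}

#' Autoplot method for pipeline reports
#'
#' Percentage-matrix tile plot of the broad regulatory groups by promoter
#' class, for all genes and for the differential-protein subset.
#'
#' @param object A `regmodes_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.regmodes_report <- function(object, ...) {
  df <- object$table1
  ggplot2::ggplot(df, ggplot2::aes(.data$promoter_class, .data$group,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$percent), "",
                     sprintf("%.1f", .data$percent))
    ), size = 3) +
    ggplot2::facet_wrap(~block) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)
    ) +
    ggplot2::labs(x = "promoter class", y = "regulatory group",
                  fill = "% of column")
}
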