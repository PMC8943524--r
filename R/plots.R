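# Figures mirroring the standard readouts: per-fraction CV histograms with
# mean-CV annotation, and the two-triangle pairwise heatmap.

#' Per-fraction CSM/URP histograms over CV
#'
#' Bar chart of CSM and URP counts per applied CV, faceted by SEC
#' fraction, with the fraction's CSM-weighted mean CV in the facet label.
#'
#' @param csms CSM tibble.
#' @param include_decoys Count decoy CSMs (default FALSE).
#' @return A ggplot object.
#' @export
plot_fraction_summary <- function(csms, include_decoys = FALSE) {
  summary <- summarize_fractions(csms, include_decoys)
  long <- tidyr::pivot_longer(summary, c("n_csms", "n_urps"),
                              names_to = "level", values_to = "count")
  long$level <- ifelse(long$level == "n_csms", "CSMs", "URPs")
  long$panel <- sprintf("fraction %d (mean CV %.1f V)", long$sec_fraction,
                        long$mean_cv)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cv, y = .data$count,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "compensation voltage (V)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Two-CV combination heatmap
#'
#' Upper triangle: percentage URP overlap between the two CVs; lower
#' triangle: union URP count of the combination.
#'
#' @param yields Tibble from [pair_yield_matrix()].
#' @return A ggplot object.
#' @export
plot_pair_heatmap <- function(yields) {
  upper <- tibble::tibble(x = yields$cv_a, y = yields$cv_b,
                          value = yields$overlap_pct, panel = "overlap (%)")
  lower <- tibble::tibble(x = yields$cv_b, y = yields$cv_a,
                          value = as.numeric(yields$urps_union),
                          panel = "union URPs")
  dat <- dplyr::bind_rows(upper, lower)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$x), y = factor(.data$y),
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value)), size = 2.5) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "CV a (V)", y = "CV b (V)", fill = NULL) +
    ggplot2::theme_minimal()
}
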