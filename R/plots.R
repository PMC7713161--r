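#' Violin plot of per-accession [AT] values by group
#'
#' @param profiles Tibble with `accession` and `at_value` (e.g. from
#'   [accession_composition()]).
#' @param panel An [at_panel] object.
#' @return A ggplot object.
#' @export
plot_at_groups <- function(profiles, panel) {
  df <- dplyr::inner_join(
    profiles, tibble::as_tibble(panel),
    by = "accession"
  ) |>
    dplyr::filter(!is.na(.data$at_value))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$group, y = .data$at_value, fill = .data$group)
  ) +
    ggplot2::geom_violin(alpha = 0.6, scale = "width") +
    ggplot2::geom_jitter(width = 0.12, size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "[AT] value across polymorphic sites") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Sliding-window [AT] track plot
#'
#' @param track Tibble from [window_at()].
#' @return A ggplot object.
#' @export
plot_window_track <- function(track) {
  ggplot2::ggplot(
    dplyr::filter(track, !is.na(.data$at_value)),
    ggplot2::aes(
      x = (.data$start + .data$end) / 2e6, y = .data$at_value,
      colour = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "window [AT] value") +
    ggplot2::theme_minimal()
}

#' Motif-spectrum bar plot
#'
#' @param spectrum An `at_spectrum` from [spectrum_frequencies()].
#' @param expected Reference expectation line (1/96 by default).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, expected = 1 / 96) {
  ggplot2::ggplot(
    spectrum$motifs,
    ggplot2::aes(x = .data$motif, y = .data$frequency, fill = .data$type)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = expected, linetype = 2) +
    ggplot2::geom_hline(yintercept = 2 * expected, linetype = 2,
      colour = "red"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "motif frequency") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6
    ))
}

#' Manhattan plot of an LMM scan
#'
#' @param object An `at_lmm_scan` object.
#' @param threshold Horizontal `-log10(p)` guide line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.at_lmm_scan <- function(object, threshold = 6, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$p_value))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$pos / 1e6, y = .data$neg_log10_p, colour = .data$chrom
    )
  ) +
    ggplot2::geom_point(size = 0.7, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
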