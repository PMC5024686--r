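#' Waterfall plot of a drug-response ranking
#'
#' Barcodes ordered by rank against log2 response score, one panel per
#' drug; the horizontal line marks the neutral score of 1.
#'
#' @param object A `bc_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank,
                                       y = log2(.data$score))) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "rank", y = "log2 drug-response score") +
    ggplot2::theme_minimal()
}

#' Fold-change heat map of top-ranked barcodes
#'
#' log2 fold-change tiles for the `top_n` barcodes of a ranking, samples
#' ordered by treatment and time.
#'
#' @param fc A `bc_foldchange`.
#' @param ranking A `bc_ranking` on the same screen.
#' @param top_n Barcodes to show (default 20).
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(fc, ranking, top_n = 20) {
  top <- ranking |>
    dplyr::filter(.data$rank <= top_n) |>
    dplyr::pull(.data$barcode)
  dat <- fc |>
    dplyr::filter(.data$barcode %in% top) |>
    dplyr::mutate(sample = paste0(.data$treatment, " ", .data$time_h, "h"),
                  barcode = factor(.data$barcode, levels = rev(top)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$barcode,
                                    fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Response-group fold-change trajectories
#'
#' Mean log2 fold-change profile per response group over the clustered
#' promoter profiles.
#'
#' @param object A `bc_response_groups`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_response_groups <- function(object, ...) {
  m <- attr(object, "profiles")
  dat <- tibble::as_tibble(m, rownames = "promoter_id") |>
    tidyr::pivot_longer(-"promoter_id", names_to = "sample",
                        values_to = "log2_fc") |>
    dplyr::left_join(tibble::as_tibble(unclass(object)), by = "promoter_id") |>
    dplyr::mutate(sample = factor(.data$sample, levels = colnames(m)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$log2_fc,
                                    group = .data$promoter_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~group, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Enrichment overview plot
#'
#' Enrichment score against -log10 permutation p per motif.
#'
#' @param object A `bc_enrichment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$es,
                                       y = -log10(.data$p_perm))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$motif_id), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = "enrichment score", y = "-log10 permutation p") +
    ggplot2::theme_minimal()
}
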