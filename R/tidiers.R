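#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a drug-response ranking
#'
#' @param x A `bc_ranking`.
#' @param ... Unused.
#' @return Plain tibble, one row per (treatment, barcode).
#' @export
tidy.bc_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.bc_ranking
#' @export
glance.bc_ranking <- function(x, ...) {
  x |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(n_barcodes = dplyr::n(),
                     median_score = stats::median(.data$score),
                     max_score = max(.data$score), .groups = "drop")
}

#' Tidy a motif enrichment result
#'
#' @param x A `bc_enrichment`.
#' @param ... Unused.
#' @return Plain tibble sorted by permutation p-value.
#' @export
tidy.bc_enrichment <- function(x, ...) {
  dplyr::arrange(tibble::as_tibble(unclass(x)), .data$p_perm,
                 dplyr::desc(abs(.data$es)))
}

#' @rdname tidy.bc_enrichment
#' @export
glance.bc_enrichment <- function(x, ...) {
  tibble::tibble(n_motifs = nrow(x),
                 n_fdr_05 = sum(x$fdr < 0.05),
                 min_p_perm = min(x$p_perm))
}

#' Tidy response-group assignments
#'
#' @param x A `bc_response_groups`.
#' @param ... Unused.
#' @return Tibble `promoter_id`, `group`.
#' @export
tidy.bc_response_groups <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.bc_response_groups
#' @export
glance.bc_response_groups <- function(x, ...) {
  tibble::tibble(n_promoters = nrow(x),
                 n_groups = dplyr::n_distinct(x$group))
}
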