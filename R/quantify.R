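#' Median-normalize a count table
#'
#' Divides each barcode count by the median of its sample (column) and
#' rescales by the global median of all counts in the experiment, so that
#' every sample column ends up with the same median while the table keeps
#' count-like magnitudes. Downstream fold changes use the depth ratio
#' (count / column median), from which the global rescaling constant
#' cancels exactly; see the methods vignette.
#'
#' @param counts Long count tibble (`barcode`, `sample_id`, `count`), e.g.
#'   from [count_screen_reads()].
#' @return The tibble with added `depth_ratio` and `norm` columns, class
#'   `bc_norm`; the global median in `attr(, "global_median")`.
#' @export
median_normalize <- function(counts) {
  stopifnot(all(c("barcode", "sample_id", "count") %in% names(counts)))
  med <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(col_median = stats::median(.data$count), .groups = "drop")
  bad <- med$sample_id[med$col_median <= 0]
  if (length(bad) > 0) {
    stop("QC error: zero or negative median in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  global_median <- stats::median(counts$count)
  out <- counts |>
    dplyr::left_join(med, by = "sample_id") |>
    dplyr::mutate(depth_ratio = .data$count / .data$col_median,
                  norm = .data$depth_ratio * global_median) |>
    dplyr::select(-"col_median")
  attr(out, "global_median") <- global_median
  class(out) <- c("bc_norm", setdiff(class(out), "bc_counts"))
  out
}

# Control samples: time-0 points plus every time point of the control
# treatments (vehicle).
control_samples <- function(design, control_treatments = "DMSO") {
  stopifnot(all(c("sample_id", "treatment", "time_h") %in% names(design)))
  design$sample_id[design$time_h == 0 |
                     design$treatment %in% control_treatments]
}

#' Fold changes relative to the control average
#'
#' Per barcode, each sample's normalized value is divided by the mean of
#' the control samples (time-0 plus all vehicle time points by default).
#' With `pseudocount = 0` (the default; the presence-in-all-samples filter
#' guarantees positive counts) fold changes are computed from depth ratios
#' and are exactly invariant to rescaling any sample's counts. A positive
#' pseudocount is applied on the normalized scale and trades that exact
#' invariance for damping of low counts.
#'
#' @param normalized `bc_norm` tibble from [median_normalize()].
#' @param design Sample sheet (`sample_id`, `treatment`, `time_h`).
#' @param control_treatments Treatments counted as vehicle controls.
#' @param controls Optional explicit character vector of control sample ids
#'   (overrides `control_treatments`).
#' @param pseudocount Added before forming the ratio (default 0).
#' @return Tibble `barcode`, (`promoter_id`,) `sample_id`, `treatment`,
#'   `time_h`, `fc`, `log2_fc`, class `bc_foldchange`.
#' @export
fold_changes <- function(normalized, design, control_treatments = "DMSO",
                         controls = NULL, pseudocount = 0) {
  if (is.null(controls)) controls <- control_samples(design, control_treatments)
  controls <- intersect(controls, unique(normalized$sample_id))
  if (length(controls) == 0) {
    stop("design error: no control samples found", call. = FALSE)
  }
  value <- if (pseudocount == 0) normalized$depth_ratio else
    normalized$norm + pseudocount
  out <- normalized |>
    dplyr::mutate(.value = value) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::mutate(fc = .data$.value /
                    mean(.data$.value[.data$sample_id %in% controls])) |>
    dplyr::ungroup() |>
    dplyr::mutate(log2_fc = log2(.data$fc)) |>
    dplyr::select(-".value", -dplyr::any_of(c("depth_ratio", "norm",
                                              "count"))) |>
    dplyr::left_join(design[, c("sample_id", "treatment", "time_h")],
                     by = "sample_id")
  attr(out, "controls") <- controls
  class(out) <- c("bc_foldchange", setdiff(class(out), "bc_norm"))
  out
}

#' Drug-response score and ranking
#'
#' For every barcode and every drug, the score is the mean fold change of
#' the drug-treated samples over the post-treatment time series divided by
#' the mean fold change of the vehicle samples at the same times. Barcodes
#' are ranked per drug by descending score; ties break lexicographically by
#' barcode.
#'
#' @param fc `bc_foldchange` tibble.
#' @param drug_times Time points entering the averages (default 1, 2, 4, 8 h).
#' @param control_treatments Vehicle treatment label(s) (default "DMSO").
#' @param treatments Drugs to score (default: all non-control treatments
#'   with time > 0 samples).
#' @return Tibble `treatment`, `barcode`, (`promoter_id`,) `drug_mean_fc`,
#'   `control_mean_fc`, `score`, `rank` (per treatment), class `bc_ranking`.
#' @export
drug_response_score <- function(fc, drug_times = c(1, 2, 4, 8),
                                control_treatments = "DMSO",
                                treatments = NULL) {
  if (is.null(treatments)) {
    treatments <- setdiff(unique(fc$treatment[fc$time_h > 0]),
                          control_treatments)
  }
  have <- unique(fc[, c("treatment", "time_h")])
  need <- tidyr::expand_grid(treatment = c(treatments, control_treatments),
                             time_h = drug_times)
  missing <- dplyr::anti_join(need, have, by = c("treatment", "time_h"))
  if (nrow(missing) > 0) {
    stop("design error: missing time point(s): ",
         paste(paste0(missing$treatment, "@", missing$time_h, "h"),
               collapse = ", "), call. = FALSE)
  }
  ctrl <- fc |>
    dplyr::filter(.data$treatment %in% control_treatments,
                  .data$time_h %in% drug_times) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(control_mean_fc = mean(.data$fc), .groups = "drop")
  keep_cols <- intersect(c("barcode", "promoter_id"), names(fc))
  out <- fc |>
    dplyr::filter(.data$treatment %in% treatments,
                  .data$time_h %in% drug_times) |>
    dplyr::group_by(.data$treatment, .data$barcode) |>
    dplyr::summarise(drug_mean_fc = mean(.data$fc), .groups = "drop") |>
    dplyr::left_join(ctrl, by = "barcode") |>
    dplyr::mutate(score = .data$drug_mean_fc / .data$control_mean_fc) |>
    dplyr::left_join(dplyr::distinct(fc[, keep_cols]), by = "barcode") |>
    dplyr::arrange(.data$treatment, dplyr::desc(.data$score),
                   .data$barcode) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  class(out) <- c("bc_ranking", setdiff(class(out), "bc_foldchange"))
  out
}

#' Merge replicate top responders and cluster into response groups
#'
#' Takes the union of each replicate's `top_k` strongest promoter responses
#' (per drug), builds each promoter's log2 fold-change profile (averaged
#' over its barcodes and replicates), and clusters the profiles by
#' agglomerative complete-linkage on Euclidean distance, cutting the tree
#' into `k_groups` response groups. Deterministic for a fixed input order.
#'
#' @param rankings A `bc_ranking` or list of them (one per replicate).
#' @param fcs A `bc_foldchange` or list of them, parallel to `rankings`.
#' @param top_k Promoters taken from the top of each ranking (default 20).
#' @param k_groups Number of response groups to cut (default 4).
#' @return Tibble `promoter_id`, `group`, class `bc_response_groups`;
#'   the `hclust` tree in `attr(, "hclust")`, the profile matrix in
#'   `attr(, "profiles")`.
#' @export
merge_replicates_and_cluster <- function(rankings, fcs, top_k = 20,
                                         k_groups = 4) {
  if (inherits(rankings, "bc_ranking")) rankings <- list(rankings)
  if (inherits(fcs, "bc_foldchange")) fcs <- list(fcs)
  stopifnot(length(rankings) == length(fcs))
  top <- unique(unlist(lapply(rankings, function(r) {
    r |>
      dplyr::filter(.data$rank <= top_k) |>
      dplyr::pull(.data$promoter_id)
  })))
  top <- sort(top)
  if (length(top) < k_groups) {
    stop("parameter error: merged set of ", length(top),
         " promoters is smaller than k_groups = ", k_groups, call. = FALSE)
  }
  prof <- purrr::imap_dfr(fcs, function(f, i) {
    f |>
      dplyr::filter(.data$promoter_id %in% top) |>
      dplyr::group_by(.data$promoter_id, .data$treatment, .data$time_h) |>
      dplyr::summarise(log2_fc = mean(.data$log2_fc), .groups = "drop") |>
      dplyr::mutate(replicate = i)
  }) |>
    dplyr::mutate(col = paste0("rep", .data$replicate, "_", .data$treatment,
                               "_", .data$time_h, "h")) |>
    dplyr::select("promoter_id", "col", "log2_fc") |>
    tidyr::pivot_wider(names_from = "col", values_from = "log2_fc")
  m <- as.matrix(prof[, -1])
  rownames(m) <- prof$promoter_id
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  grp <- stats::cutree(hc, k = k_groups)
  out <- tibble::tibble(promoter_id = names(grp), group = unname(grp))
  attr(out, "hclust") <- hc
  attr(out, "profiles") <- m
  class(out) <- c("bc_response_groups", class(out))
  out
}

#' Coefficient-of-variation QC filter
#'
#' Transfection-uniformity gate: replicates (e.g. per-dish luminescence)
#' pass when the coefficient of variation (sample standard deviation over
#' mean) is below `max_cv`, 12% by default.
#'
#' @param values Numeric vector of at least two positive values.
#' @param max_cv Maximum CV to keep (default 0.12).
#' @return One-row tibble: `kept` (logical), `cv`.
#' @export
cv_filter <- function(values, max_cv = 0.12) {
  if (length(values) < 2) {
    stop("cv_filter() needs at least two values", call. = FALSE)
  }
  cv <- stats::sd(values) / mean(values)
  tibble::tibble(kept = cv < max_cv, cv = cv)
}
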