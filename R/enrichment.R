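#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked list: walking down the ranking, the
#' sum rises by the normalized weight at each set member and falls by
#' `1/(N - m)` at each non-member; the enrichment score is the maximum
#' signed deviation (positive: set concentrated at the top; negative: at
#' the bottom). Always in [-1, 1].
#'
#' @param member_pos Integer positions (1-based ranks) of the set members
#'   within the ranked list.
#' @param weights Non-negative weights, parallel to `member_pos` (already
#'   exponentiated).
#' @param n Length of the ranked list.
#' @return The enrichment score.
#' @export
enrichment_score <- function(member_pos, weights, n) {
  m <- length(member_pos)
  stopifnot(m >= 1, m < n, length(weights) == m)
  o <- order(member_pos)
  pos <- member_pos[o]
  w <- weights[o]
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / m else w <- w / tot
  cw <- cumsum(w)
  dec <- 1 / (n - m)
  i <- seq_len(m)
  top <- cw - (pos - i) * dec          # just after each member step
  bot <- c(0, cw[-m]) - (pos - i) * dec  # just before each member step
  max_top <- max(top, 0)
  min_bot <- min(bot, 0)
  if (max_top >= -min_bot) max_top else min_bot
}

#' GSEA-style motif-set enrichment over a drug-response ranking
#'
#' For each motif, the promoters carrying at least one hit form the motif
#' set; the weighted Kolmogorov-Smirnov running sum over the score-ordered
#' promoter list (member weights `|log2 score|^weight_exponent`) gives the
#' enrichment score, and significance comes from a promoter-label
#' permutation null: `p = (n_extreme + 1) / (n_perm + 1)`, extremeness
#' measured on |ES|. FDR across the panel by Benjamini-Hochberg.
#'
#' @param ranking Tibble with `promoter_id` and `score` (one row per
#'   promoter; e.g. [promoter_ranking()]).
#' @param hits Hit table with `promoter_id` and `motif_id` (e.g.
#'   [scan_promoters()]).
#' @param motif_ids Motifs to test (default: all in `hits`).
#' @param n_perm Number of permutations (default 999).
#' @param weight_exponent Weight exponent (default 1; 0 = unweighted KS).
#' @param seed Optional integer seed for the permutation null.
#' @return Tibble `motif_id`, `set_size`, `es`, `p_perm`, `fdr`, class
#'   `bc_enrichment`.
#' @export
motif_set_enrichment <- function(ranking, hits,
                                 motif_ids = unique(hits$motif_id),
                                 n_perm = 999, weight_exponent = 1,
                                 seed = NULL) {
  stopifnot(all(c("promoter_id", "score") %in% names(ranking)))
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$score),
                            .data$promoter_id)
  universe <- ranking$promoter_id
  n <- length(universe)
  wts <- abs(log2(ranking$score))^weight_exponent
  res <- with_seed_if(seed, purrr::map_dfr(motif_ids, function(mid) {
    members <- unique(hits$promoter_id[hits$motif_id == mid])
    pos <- which(universe %in% members)
    m <- length(pos)
    if (m == 0 || m == n) {
      stop("domain error: motif set for ", mid, " is empty or equals the ",
           "whole ranking", call. = FALSE)
    }
    es <- enrichment_score(pos, wts[pos], n)
    perm_es <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n, m)
      enrichment_score(p, wts[p], n)
    }, numeric(1))
    tibble::tibble(motif_id = mid, set_size = m, es = es,
                   p_perm = (sum(abs(perm_es) >= abs(es)) + 1) / (n_perm + 1))
  }))
  res$fdr <- stats::p.adjust(res$p_perm, method = "BH")
  class(res) <- c("bc_enrichment", class(res))
  res
}

#' Collapse a barcode-level ranking to promoter level
#'
#' Multiple barcodes can report on the same promoter; their scores are
#' averaged and promoters re-ranked by descending score.
#'
#' @param ranking A `bc_ranking` tibble (one treatment).
#' @return Tibble `promoter_id`, `score`, `rank`.
#' @export
promoter_ranking <- function(ranking) {
  if ("treatment" %in% names(ranking) &&
      dplyr::n_distinct(ranking$treatment) > 1) {
    stop("promoter_ranking() expects a single treatment; filter first",
         call. = FALSE)
  }
  ranking |>
    dplyr::group_by(.data$promoter_id) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$promoter_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}
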