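#' Screen read layout
#'
#' Fixed architecture of a 100-nt screen read: a 6-nt sample index
#' (positions 1-6), a 20-nt constant spacer (7-26), the 20-nt barcode
#' (27-46) and the XbaI anchor `TCTAGA` from position 47, followed by
#' reporter 3' UTR. All positions 1-based inclusive.
#'
#' @return List of span definitions.
#' @export
read_layout <- function() {
  list(index_span = c(1L, 6L), const_span = c(7L, 26L),
       barcode_span = c(27L, 46L), tail_anchor = restriction_sites()$XbaI,
       min_anchor_pos = 47L, read_length = 100L)
}

#' Clip the reporter tail at the XbaI anchor
#'
#' Truncates each read immediately before the first occurrence of the
#' anchor at or after `min_pos`, isolating the 3' end of the barcode.
#' Earlier anchor-like occurrences (possible inside a degenerate barcode)
#' are ignored by the position guard. Reads without the anchor are flagged
#' (`NA`) and excluded downstream.
#'
#' @param reads Character vector.
#' @param anchor Anchor 6-mer (default XbaI `TCTAGA`).
#' @param min_pos First position (1-based) where the anchor may start.
#' @return Character vector of clipped reads; `NA` where flagged.
#' @export
clip_reporter_tail <- function(reads, anchor = restriction_sites()$XbaI,
                               min_pos = read_layout()$min_anchor_pos) {
  tailseq <- substr(reads, min_pos, nchar(reads))
  hit <- regexpr(anchor, tailseq, fixed = TRUE)
  pos <- ifelse(hit > 0, as.integer(hit) + min_pos - 1L, NA_integer_)
  ifelse(is.na(pos), NA_character_, substr(reads, 1L, pos - 1L))
}

# Exact + 1-substitution lookup table from index sequences to sample ids.
# Mutated keys colliding between two indexes are dropped (ambiguous); with
# a Hamming-3 index set no such collision can occur.
index_lookup <- function(sheet, max_mismatch) {
  keys <- sheet$index
  ids <- sheet$sample_id
  if (max_mismatch >= 1) {
    for (i in seq_along(sheet$index)) {
      x <- sheet$index[i]
      for (p in seq_len(nchar(x))) {
        for (b in setdiff(DNA_BASES, substr(x, p, p))) {
          y <- x
          substr(y, p, p) <- b
          keys <- c(keys, y)
          ids <- c(ids, sheet$sample_id[i])
        }
      }
    }
  }
  dup <- keys %in% keys[duplicated(keys)]
  ambiguous <- unique(keys[dup & !(keys %in% sheet$index)])
  keep <- !(keys %in% ambiguous) | keys %in% sheet$index
  list(keys = keys[keep], ids = ids[keep])
}

#' Demultiplex reads by their 5' sample index
#'
#' Assigns every read to the unique sample whose index matches the read's
#' first six bases within `max_mismatch` substitutions, or to `NA`
#' (unassigned). Because the index set has minimum Hamming distance 3,
#' single-error correction (`max_mismatch = 1`) is always unambiguous.
#'
#' @param reads Character vector.
#' @param sheet Sample sheet tibble with `sample_id` and `index` columns.
#' @param max_mismatch 0 or 1 substitutions tolerated in the index.
#' @return Character vector of sample ids (NA = unassigned), parallel to
#'   `reads`.
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1) {
  stopifnot(all(c("sample_id", "index") %in% names(sheet)),
            max_mismatch %in% c(0, 1))
  if (anyDuplicated(sheet$index)) {
    stop("configuration error: duplicate indexes in the sample sheet",
         call. = FALSE)
  }
  if (nrow(sheet) >= 2 && min_pairwise_hamming(sheet$index) < 2 * max_mismatch + 1) {
    warning("index set does not guarantee unambiguous correction at ",
            "max_mismatch = ", max_mismatch)
  }
  lk <- index_lookup(sheet, max_mismatch)
  idx <- substr(reads, 1L, nchar(sheet$index[1]))
  lk$ids[match(idx, lk$keys)]
}

#' Trim the barcode window
#'
#' Extracts the fixed barcode span (default positions 27-46, 1-based
#' inclusive) from each read. Reads shorter than the span end are returned
#' as `NA` (too short; tallied by the caller's QC).
#'
#' @param reads Character vector.
#' @param span Length-2 integer vector, 1-based inclusive.
#' @return Character vector of 20-nt barcodes (`NA` where too short).
#' @export
trim_barcode_window <- function(reads, span = read_layout()$barcode_span) {
  out <- substr(reads, span[1], span[2])
  ifelse(is.na(reads) | nchar(reads) < span[2], NA_character_, out)
}

#' Count barcodes per sample
#'
#' Exact-sequence counting of trimmed barcodes, the in-memory equivalent of
#' collapsing identical FASTA records. When a whitelist is given,
#' off-whitelist barcodes are tallied separately in the QC attribute.
#'
#' @param barcodes Character vector of 20-nt barcodes.
#' @param sample_id Parallel character vector of sample assignments.
#' @param whitelist Optional character vector of expected barcodes.
#' @return Long tibble `barcode`, `sample_id`, `count`; off-whitelist totals
#'   per sample in `attr(, "off_whitelist")`.
#' @export
count_barcodes <- function(barcodes, sample_id, whitelist = NULL) {
  keep <- !is.na(barcodes) & !is.na(sample_id)
  if (any(nchar(barcodes[keep]) != 20)) {
    stop("pipeline-order error: barcodes must all be 20 nt; run ",
         "trim_barcode_window() first", call. = FALSE)
  }
  df <- tibble::tibble(barcode = barcodes[keep], sample_id = sample_id[keep])
  off <- NULL
  if (!is.null(whitelist)) {
    onwl <- df$barcode %in% whitelist
    off <- df[!onwl, ] |> dplyr::count(.data$sample_id, name = "off_whitelist")
    df <- df[onwl, ]
  }
  out <- df |> dplyr::count(.data$barcode, .data$sample_id, name = "count")
  attr(out, "off_whitelist") <- off
  out
}

#' Assemble and filter the count table
#'
#' Joins per-sample counts into a barcode x sample table, keeping only
#' barcodes observed (count >= `min_count`) in every sample and whose
#' promoter association is known -- the screen's guard against spurious
#' barcode sequences born from sequencing errors.
#'
#' @param counts Long tibble from [count_barcodes()].
#' @param association Association table (`barcode`, `promoter_id`).
#' @param samples Character vector of all expected sample ids (defaults to
#'   those present in `counts`).
#' @param min_count Minimum count per sample to call a barcode present.
#' @return Long count tibble `barcode`, `promoter_id`, `sample_id`, `count`
#'   (complete over retained barcodes x samples), class `bc_counts`;
#'   drop tallies in `attr(, "qc")`.
#' @export
assemble_and_filter <- function(counts, association,
                                samples = unique(counts$sample_id),
                                min_count = 1) {
  stopifnot(length(samples) >= 1)
  empty <- setdiff(samples, unique(counts$sample_id))
  if (length(empty) > 0) {
    stop("QC error: sample(s) with zero parsed reads: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  n_samples <- length(samples)
  present_all <- counts |>
    dplyr::filter(.data$count >= min_count, .data$sample_id %in% samples) |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n == n_samples) |>
    dplyr::pull(.data$barcode)
  associated <- intersect(present_all, association$barcode)
  out <- counts |>
    dplyr::filter(.data$barcode %in% associated) |>
    tidyr::complete(barcode = associated, sample_id = samples,
                    fill = list(count = 0L)) |>
    dplyr::left_join(association[, c("barcode", "promoter_id")],
                     by = "barcode") |>
    dplyr::select("barcode", "promoter_id", "sample_id", "count") |>
    dplyr::arrange(.data$barcode, .data$sample_id)
  attr(out, "qc") <- tibble::tibble(
    n_barcodes_seen = dplyr::n_distinct(counts$barcode),
    n_dropped_not_everywhere = dplyr::n_distinct(counts$barcode) -
      length(present_all),
    n_dropped_unassociated = length(present_all) - length(associated),
    n_retained = length(associated)
  )
  class(out) <- c("bc_counts", class(out))
  out
}

#' Full screen read pipeline: reads to filtered count table
#'
#' Clip at the XbaI anchor, demultiplex on the 5' index, trim the barcode
#' window, count per sample, then keep barcodes present everywhere with a
#' known promoter. Deterministic and independent of read order.
#'
#' @param reads Character vector of screen reads (or a FASTQ path).
#' @param sheet Sample sheet (`sample_id`, `index`).
#' @param association Association table.
#' @param max_mismatch Index mismatches tolerated (default 1).
#' @param whitelist Optional barcode whitelist.
#' @return `bc_counts` tibble; QC funnel in `attr(, "qc_funnel")`.
#' @export
count_screen_reads <- function(reads, sheet, association, max_mismatch = 1,
                               whitelist = NULL) {
  if (length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)$seq
  }
  n_in <- length(reads)
  clipped <- clip_reporter_tail(reads)
  sample_id <- demultiplex(reads, sheet, max_mismatch = max_mismatch)
  barcode <- trim_barcode_window(clipped)
  counts <- count_barcodes(barcode, sample_id, whitelist = whitelist)
  out <- assemble_and_filter(counts, association, samples = sheet$sample_id)
  attr(out, "qc_funnel") <- tibble::tibble(
    reads_in = n_in,
    reads_clipped = sum(!is.na(clipped)),
    reads_assigned = sum(!is.na(sample_id)),
    reads_counted = sum(!is.na(barcode) & !is.na(sample_id) & !is.na(clipped))
  )
  out
}
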