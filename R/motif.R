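#' Construct a motif model from a position frequency matrix
#'
#' Wraps a 4 x W count matrix (rows A, C, G, T) with its log-odds transform
#' under a uniform background. A total pseudocount of `pseudocount` per
#' column, split equally over the four bases, regularises zero counts.
#' Scanning uses the relative score
#' `(score - min_score) / (max_score - min_score)`, with hits at or above
#' `rel_score_threshold`.
#'
#' @param motif_id Motif label.
#' @param counts 4 x W numeric matrix, rows in A, C, G, T order.
#' @param rel_score_threshold Relative score threshold in (0, 1] (default
#'   0.85, the common community convention).
#' @param pseudocount Total pseudocount per column (default 0.8).
#' @return A `motif_model` object.
#' @export
motif_model <- function(motif_id, counts, rel_score_threshold = 0.85,
                        pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("parse error: counts must have 4 base rows",
                              call. = FALSE)
  if (any(counts < 0) || any(is.na(counts))) {
    stop("parse error: negative or missing counts", call. = FALSE)
  }
  if (ncol(counts) < 4) stop("motif width must be >= 4", call. = FALSE)
  if (any(colSums(counts) <= 0)) {
    stop("parse error: column with zero total count", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  prob <- sweep(counts + pseudocount / 4, 2,
                colSums(counts) + pseudocount, "/")
  structure(list(motif_id = motif_id, counts = counts,
                 log_odds = log2(prob / 0.25),
                 rel_score_threshold = rel_score_threshold,
                 width = ncol(counts)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model>", x$motif_id, "width", x$width,
      "threshold", x$rel_score_threshold, "\n")
  invisible(x)
}

#' Parse JASPAR-format position frequency matrices
#'
#' Reads the JASPAR PFM text format: a `>identifier name` header followed
#' by four base rows, either bracketed (`A [ 1 2 3 ]`) or as raw
#' whitespace-separated numbers in A, C, G, T order.
#'
#' @param x Path to a JASPAR file, or its contents as a character vector.
#' @param ... Passed to [motif_model()] (threshold, pseudocount).
#' @return List of `motif_model` objects.
#' @export
parse_jaspar <- function(x, ...) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else
    unlist(strsplit(x, "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("parse error: no JASPAR '>' header", call. = FALSE)
  bounds <- c(hdr, length(lines) + 1)
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    if (length(block) != 4) {
      stop("parse error: expected 4 base rows, got ", length(block),
           call. = FALSE)
    }
    rows <- lapply(block, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals)) stop("parse error: non-numeric count", call. = FALSE)
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("parse error: base rows of unequal width", call. = FALSE)
    }
    id <- sub("^>\\s*", "", lines[bounds[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    out[[k]] <- motif_model(id, do.call(rbind, rows), ...)
  }
  out
}

#' Write motifs in JASPAR PFM format
#'
#' Round-trips exactly through [parse_jaspar()].
#'
#' @param motifs List of `motif_model` objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  txt <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$motif_id, " ", m$motif_id),
      vapply(seq_len(4), function(i) {
        paste0(DNA_BASES[i], " [ ",
               paste(format(m$counts[i, ], trim = TRUE), collapse = " "),
               " ]")
      }, character(1)))
  }))
  writeLines(txt, path)
  invisible(path)
}

#' Scan a sequence with a PWM on one or both strands
#'
#' Scores every window of the motif's width; a hit is any window whose
#' relative score reaches the threshold. Reverse-strand hits are reported
#' in forward 0-based coordinates (offset of the leftmost base of the
#' window on the forward strand).
#'
#' @param seq ACGT sequence (at least motif width long).
#' @param motif A `motif_model`.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param threshold Relative score threshold (defaults to the motif's).
#' @return Tibble `offset` (0-based), `strand` ("+"/"-"), `rel_score`.
#' @export
pwm_scan <- function(seq, motif, both_strands = TRUE, threshold = NULL) {
  stopifnot(inherits(motif, "motif_model"))
  if (nchar(seq) < motif$width) {
    stop("sequence shorter than the motif width", call. = FALSE)
  }
  enc_f <- encode_dna(seq)
  enc_r <- if (both_strands) rev(5L - enc_f) else NULL  # complement is 5 - code
  scan_encoded(enc_f, enc_r, motif, threshold)
}

# Raw window scores of an encoded sequence under a log-odds matrix.
window_scores <- function(enc, lo) {
  W <- ncol(lo)
  n_off <- length(enc) - W + 1
  sc <- numeric(n_off)
  for (p in seq_len(W)) {
    sc <- sc + unname(lo[enc[p:(p + n_off - 1)], p])
  }
  sc
}

# Shared scanning core over pre-encoded forward/reverse strands.
scan_encoded <- function(enc_f, enc_r, motif, threshold = NULL) {
  if (is.null(threshold)) threshold <- motif$rel_score_threshold
  lo <- motif$log_odds
  W <- motif$width
  min_s <- sum(apply(lo, 2, min))
  max_s <- sum(apply(lo, 2, max))
  fwd <- (window_scores(enc_f, lo) - min_s) / (max_s - min_s)
  i_f <- which(fwd >= threshold)
  offset <- i_f - 1L
  strand <- rep("+", length(i_f))
  rel_score <- fwd[i_f]
  if (!is.null(enc_r)) {
    rc <- (window_scores(enc_r, lo) - min_s) / (max_s - min_s)
    i_r <- which(rc >= threshold)
    # forward coordinate of the leftmost base of a reverse-strand window
    offset <- c(offset, length(enc_f) - W - (i_r - 1L))
    strand <- c(strand, rep("-", length(i_r)))
    rel_score <- c(rel_score, rc[i_r])
  }
  o <- order(offset, strand)
  tibble::tibble(offset = offset[o], strand = strand[o],
                 rel_score = rel_score[o])
}

#' Scan a set of promoters with a motif panel
#'
#' Scans the concatenated 68-nt random cores of each promoter (constant
#' flanks are masked out: they are shared across the whole library and
#' would only produce uninformative ubiquitous hits).
#'
#' @param promoters Tibble with `promoter_id` and either `scan_seq` or a
#'   `cores` list-column.
#' @param motifs List of `motif_model` objects.
#' @param both_strands Scan both strands (default TRUE).
#' @return Tibble `promoter_id`, `motif_id`, `offset`, `strand`,
#'   `rel_score` (one row per hit).
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  seqs <- if ("scan_seq" %in% names(promoters)) promoters$scan_seq else
    vapply(promoters$cores, paste0, character(1), collapse = "")
  enc_f <- lapply(seqs, encode_dna)
  enc_r <- if (both_strands) lapply(enc_f, function(e) rev(5L - e)) else
    vector("list", length(enc_f))
  out <- vector("list", length(seqs) * length(motifs))
  k <- 0L
  for (i in seq_along(seqs)) {
    for (m in motifs) {
      h <- scan_encoded(enc_f[[i]], enc_r[[i]], m)
      if (nrow(h) > 0) {
        k <- k + 1L
        h$promoter_id <- promoters$promoter_id[i]
        h$motif_id <- m$motif_id
        out[[k]] <- h
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(promoter_id = character(0), motif_id = character(0),
                          offset = integer(0), strand = character(0),
                          rel_score = numeric(0)))
  }
  dplyr::bind_rows(out[seq_len(k)])[, c("promoter_id", "motif_id", "offset",
                                        "strand", "rel_score")]
}

#' Motifs shared by every promoter of a response group
#'
#' Returns the motifs with at least one hit in every member of the group,
#' ordered by decreasing mean best relative score. Monotone: adding a
#' promoter can only shrink or preserve the shared set.
#'
#' @param group Tibble of promoters (`promoter_id` + `cores`/`scan_seq`),
#'   non-empty.
#' @param motifs List of `motif_model` objects.
#' @param both_strands Scan both strands (default TRUE).
#' @return Tibble `motif_id`, `mean_best_rel_score`, sorted descending.
#' @export
shared_motifs <- function(group, motifs, both_strands = TRUE) {
  if (nrow(group) == 0) stop("empty promoter group", call. = FALSE)
  hits <- scan_promoters(group, motifs, both_strands = both_strands)
  if (nrow(hits) == 0) {
    return(tibble::tibble(motif_id = character(0),
                          mean_best_rel_score = numeric(0)))
  }
  hits |>
    dplyr::group_by(.data$motif_id, .data$promoter_id) |>
    dplyr::summarise(best = max(.data$rel_score), .groups = "drop_last") |>
    dplyr::summarise(n_promoters = dplyr::n(),
                     mean_best_rel_score = mean(.data$best),
                     .groups = "drop") |>
    dplyr::filter(.data$n_promoters == nrow(group)) |>
    dplyr::arrange(dplyr::desc(.data$mean_best_rel_score)) |>
    dplyr::select("motif_id", "mean_best_rel_score")
}

#' Synthetic panel of consensus-derived motifs
#'
#' Builds a panel of position frequency matrices from field-standard
#' binding-site consensus strings (the CArG box CC(A/T)6GG among them).
#' This is a synthetic stand-in panel constructed by the package, not a
#' motif-database export: counts place `major` weight on the consensus
#' bases (split over the bases an IUPAC code admits) and a small residual
#' on the others.
#'
#' @param consensi Named character vector of IUPAC consensus strings
#'   (default: a 20-motif panel).
#' @param major Count mass on consensus bases per column (default 94).
#' @param minor Count per non-consensus base (default 2).
#' @param ... Passed to [motif_model()].
#' @return List of `motif_model` objects.
#' @export
make_motif_panel <- function(consensi = default_consensi(), major = 94,
                             minor = 2, ...) {
  tab <- iupac_table()
  purrr::imap(consensi, function(cons, id) {
    codes <- strsplit(cons, "")[[1]]
    counts <- vapply(codes, function(cc) {
      allowed <- tab[[cc]]
      col <- rep(minor, 4)
      names(col) <- DNA_BASES
      col[allowed] <- col[allowed] + major / length(allowed)
      col
    }, numeric(4))
    motif_model(id, counts, ...)
  })
}

#' @rdname make_motif_panel
#' @export
default_consensi <- function() {
  c(CARG_SRF = "CCWWWWWWGG", AP1 = "TGACTCA", CREB = "TGACGTCA",
    NFKB = "GGGACTTTCC", EBOX = "CACGTG", GATA = "WGATAAG",
    ETS = "CCGGAAGT", IRF = "AAGTGAAA", STAT = "TTCCCGGAA",
    TEAD = "GGAATGCG", MEF2 = "CTAWWWWTAG", TBP = "TATAWAWA",
    SP1 = "GGGGCGGGG", OCT = "ATGCAAAT", SOX = "AACAATGG",
    RUNX = "TGTGGTTT", NRF1 = "GCGCATGCGC", P53 = "GGGCATGCCC",
    HSF = "AGAACGTTCT", KLF = "CCACACCC")
}
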