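#' In-silico restriction digestion
#'
#' Splits a sequence at every occurrence of the given recognition sites on
#' the forward strand (all supported enzymes are 6-bp palindromes, so the
#' forward-strand search is strand-agnostic). Cuts are modelled at the first
#' base of the recognition site; overhang chemistry is abstracted away.
#'
#' @param seq DNA sequence (non-empty).
#' @param sites Named list/vector of 6-mer recognition sequences.
#' @return Tibble of fragments: `seq`, `start` (0-based offset in the
#'   input), `kind` = "linear".
#' @export
insilico_digest <- function(seq, sites) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("cannot digest an empty sequence", call. = FALSE)
  cuts <- sort(unique(unlist(lapply(sites, function(s)
    stringr::str_locate_all(seq, stringr::fixed(s))[[1]][, 1]))))
  bounds <- unique(c(1, cuts, nchar(seq) + 1))
  tibble::tibble(
    seq = substring(seq, bounds[-length(bounds)], bounds[-1] - 1),
    start = bounds[-length(bounds)] - 1,
    kind = "linear"
  )
}

new_fragment <- function(seq, kind = "linear", source_id = NA_character_) {
  tibble::tibble(seq = seq, kind = kind, source_id = source_id)
}

#' Circularize a linear fragment
#'
#' Models intramolecular ligation: the former 3' end abuts the former 5'
#' end, bringing a 3'-terminal barcode into immediate proximity of the
#' 5'-terminal promoter across the junction. Length is conserved; the
#' stored sequence keeps the original phase with the junction between the
#' last and first base.
#'
#' @param fragment One-row fragment tibble (`kind` = "linear").
#' @return The fragment with `kind` = "circular".
#' @export
circularize_fragment <- function(fragment) {
  if (fragment$kind[1] != "linear") {
    stop("state error: fragment is already circular", call. = FALSE)
  }
  fragment$kind <- "circular"
  fragment
}

#' Relinearize a circle with one or more enzymes
#'
#' Each enzyme independently digests an aliquot of the circle at every one
#' of its sites (sites spanning the stored junction are found too); the
#' resulting linear fragments are pooled. Using three enzymes with sites in
#' different backbone positions makes it unlikely that every aliquot cuts
#' inside the barcode-promoter junction region.
#'
#' @param circle One-row fragment tibble with `kind` = "circular".
#' @param enzymes Named list of recognition 6-mers (non-empty).
#' @return Tibble of linear fragments with an `enzyme` column; zero rows
#'   (with a warning) if no enzyme cuts anywhere.
#' @export
linearize_circle <- function(circle, enzymes) {
  if (circle$kind[1] != "circular") {
    stop("state error: linearize_circle() needs a circular fragment",
         call. = FALSE)
  }
  if (length(enzymes) == 0) stop("enzyme list is empty", call. = FALSE)
  s <- circle$seq[1]
  L <- nchar(s)
  wrapped <- paste0(s, substr(s, 1, 5))  # catch sites spanning the junction
  out <- list()
  for (nm in names(enzymes)) {
    pos <- stringr::str_locate_all(wrapped,
                                   stringr::fixed(enzymes[[nm]]))[[1]][, 1]
    pos <- sort(unique((pos - 1) %% L))  # 0-based circular cut positions
    if (length(pos) == 0) next
    rot <- paste0(substr(s, pos[1] + 1, L), substr(s, 1, pos[1]))
    rel <- pos - pos[1]
    bounds <- c(rel + 1, L + 1)
    frag <- substring(rot, bounds[-length(bounds)], bounds[-1] - 1)
    out[[nm]] <- tibble::tibble(seq = frag, kind = "linear", enzyme = nm)
  }
  if (length(out) == 0) {
    warning("no enzyme site found anywhere on the circle; empty pool")
    return(tibble::tibble(seq = character(0), kind = character(0),
                          enzyme = character(0)))
  }
  dplyr::bind_rows(out)
}

# First occurrence of `anchor` in each read allowing <= max_mm substitutions.
# Exact vectorised fast path; per-read sliding window only for the misses.
locate_anchor <- function(reads, anchor, max_mm = 1) {
  w <- nchar(anchor)
  pos <- regexpr(anchor, reads, fixed = TRUE)
  pos <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  if (max_mm > 0 && anyNA(pos)) {
    a <- utf8ToInt(anchor)
    miss <- which(is.na(pos))
    for (i in miss) {
      L <- nchar(reads[i])
      if (L < w) next
      for (o in seq_len(L - w + 1)) {
        if (sum(utf8ToInt(substr(reads[i], o, o + w - 1)) != a) <= max_mm) {
          pos[i] <- o
          break
        }
      }
    }
  }
  pos
}

#' Parse circularization-junction reads
#'
#' A junction read covers the constant barcode flank, the 20-nt barcode,
#' the ligated NheI junction and the first promoter repeat. Anchors
#' (constant flank, NheI site + left repeat flank) are matched with at most
#' one substitution; the barcode itself is taken verbatim and, when a
#' whitelist is supplied, must match it exactly -- the degenerate barcode
#' space offers no guaranteed minimum distance, so no error correction is
#' attempted. Failures are returned as unparsed rows, not errors.
#'
#' @param reads Character vector of read sequences.
#' @param template Construct template ([default_template()]).
#' @param whitelist Optional character vector of known barcodes.
#' @param max_anchor_mismatch Substitutions tolerated in constant anchors.
#' @return Tibble: `barcode`, `core1` (first 68-mer), `status`
#'   ("ok"/"unparsed").
#' @export
parse_junction_read <- function(reads, template = default_template(),
                                whitelist = NULL, max_anchor_mismatch = 1) {
  cf <- template$const_flank
  post_anchor <- paste0(restriction_sites()$NheI, template$flanks$left_flank)
  pos <- locate_anchor(reads, cf, max_anchor_mismatch)
  bc_start <- pos + nchar(cf)
  barcode <- substr(reads, bc_start, bc_start + 19)
  jn <- substr(reads, bc_start + 20, bc_start + 20 + 13)  # NheI + left flank
  core1 <- substr(reads, bc_start + 34, bc_start + 34 + 67)
  a <- utf8ToInt(post_anchor)
  jn_ok <- !is.na(pos) & nchar(jn) == 14 &
    vapply(jn, function(x) nchar(x) == 14 &&
             sum(utf8ToInt(x) != a) <= max_anchor_mismatch, logical(1),
           USE.NAMES = FALSE)
  ok <- jn_ok & nchar(barcode) == 20 & nchar(core1) == 68
  if (!is.null(whitelist)) ok <- ok & barcode %in% whitelist
  tibble::tibble(
    barcode = ifelse(ok, barcode, NA_character_),
    core1 = ifelse(ok, core1, NA_character_),
    status = ifelse(ok, "ok", "unparsed")
  )
}

#' Parse long association reads
#'
#' A long read spans the whole NheI-XbaI fragment: the six repeat cores and
#' the barcode are recovered by anchored splitting on the constant flanks.
#' Reads that fail to parse in forward orientation are retried as reverse
#' complements.
#'
#' @param reads Character vector of full-fragment read sequences.
#' @param template Construct template.
#' @param max_anchor_mismatch Substitutions tolerated per anchor.
#' @return Tibble: `barcode`, `cores` (list of 68-mer vectors), `status`.
#' @export
parse_long_read <- function(reads, template = default_template(),
                            max_anchor_mismatch = 1) {
  one <- function(r, retry = TRUE) {
    n <- template$n_repeats
    lf <- template$flanks$left_flank
    nhei <- restriction_sites()$NheI
    ok <- function(sub, ref) nchar(sub) == nchar(ref) &&
      sum(utf8ToInt(sub) != utf8ToInt(ref)) <= max_anchor_mismatch
    parse_fwd <- function(r) {
      if (nchar(r) < 6 + n * 84 || !ok(substr(r, 1, 6), nhei)) return(NULL)
      starts <- 6 + (seq_len(n) - 1) * 84 + 1
      if (!all(vapply(starts, function(s)
        ok(substr(r, s, s + 7), lf), logical(1)))) return(NULL)
      cores <- substring(r, starts + 8, starts + 75)
      cfp <- locate_anchor(r, template$const_flank, max_anchor_mismatch)
      if (is.na(cfp)) return(NULL)
      bc <- substr(r, cfp + 20, cfp + 39)
      if (nchar(bc) != 20) return(NULL)
      list(barcode = bc, cores = cores)
    }
    res <- parse_fwd(r)
    if (is.null(res) && retry) res <- parse_fwd(reverse_complement(r))
    res
  }
  parsed <- lapply(reads, one)
  ok <- !vapply(parsed, is.null, logical(1))
  tibble::tibble(
    barcode = vapply(parsed, function(p) if (is.null(p)) NA_character_
                     else p$barcode, character(1)),
    cores = lapply(parsed, function(p) if (is.null(p)) character(0)
                   else p$cores),
    status = ifelse(ok, "ok", "unparsed")
  )
}

#' Build the barcode-promoter association table
#'
#' Counts identical (barcode, promoter) pairs, keeps rows with read support
#' strictly greater than `min_reads`, and excludes barcodes for which two
#' different promoters both pass the threshold. Such conflicts indicate
#' chimeric molecules or systematic errors -- with a 3^20 barcode space,
#' true barcode reuse across plasmids is statistically negligible -- so
#' conflicting barcodes are dropped and reported, never resolved by majority.
#'
#' @param pairs Tibble/data frame with columns `barcode`, `promoter_id`.
#' @param min_reads Support threshold; rows with support > `min_reads`
#'   are retained (default 50).
#' @return Tibble `barcode`, `promoter_id`, `read_support` of class
#'   `bc_association`; conflicting barcodes in `attr(, "conflicts")`.
#' @export
build_association_table <- function(pairs, min_reads = 50) {
  stopifnot(all(c("barcode", "promoter_id") %in% names(pairs)))
  tab <- pairs |>
    dplyr::filter(!is.na(.data$barcode), !is.na(.data$promoter_id)) |>
    dplyr::count(.data$barcode, .data$promoter_id, name = "read_support") |>
    dplyr::filter(.data$read_support > min_reads)
  conflicts <- tab |>
    dplyr::add_count(.data$barcode, name = "n_promoters") |>
    dplyr::filter(.data$n_promoters > 1) |>
    dplyr::select(-"n_promoters")
  tab <- tab |>
    dplyr::filter(!.data$barcode %in% conflicts$barcode) |>
    dplyr::arrange(.data$barcode)
  attr(tab, "conflicts") <- conflicts
  class(tab) <- c("bc_association", class(tab))
  tab
}

#' Validate an association table
#'
#' A valid table has no barcode linked to more than one promoter; promoters
#' carrying several barcodes are legitimate and serve as internal QC
#' replicates (their fold-change patterns should agree).
#'
#' @param tab Association table.
#' @return List with `collisions` (barcodes mapping to > 1 promoter; must be
#'   empty) and `multi_barcode_promoters`.
#' @export
validate_association <- function(tab) {
  collisions <- tab |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$barcode)
  multi <- tab |>
    dplyr::count(.data$promoter_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$promoter_id)
  list(collisions = collisions, multi_barcode_promoters = multi)
}

#' Associate parsed junction reads with library promoters
#'
#' Maps each parsed read's first repeat core to the library manifest
#' (exact match; errored cores simply fail to match and are absorbed by the
#' read-support threshold) and builds the association table.
#'
#' @param reads Character vector of junction reads.
#' @param manifest Library manifest with `promoter_id` and `core1` columns
#'   (as produced by [simulate_library()]).
#' @param template Construct template.
#' @param min_reads Support threshold (default 50).
#' @param whitelist Optional barcode whitelist.
#' @return `bc_association` table.
#' @export
associate_junction_reads <- function(reads, manifest,
                                     template = default_template(),
                                     min_reads = 50, whitelist = NULL) {
  parsed <- parse_junction_read(reads, template, whitelist = whitelist)
  idx <- match(parsed$core1, manifest$core1)
  pairs <- tibble::tibble(barcode = parsed$barcode,
                          promoter_id = manifest$promoter_id[idx])
  build_association_table(pairs, min_reads = min_reads)
}
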