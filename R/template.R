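#' Restriction landmarks used by the construct template
#'
#' All six enzymes have palindromic 6-bp recognition sites, so site finding
#' on the forward strand is strand-agnostic. NheI and XbaI bracket the
#' promoter--barcode cassette; ApaI, FspI and HincII sit in the reporter
#' stub and serve to relinearize circularized fragments away from the
#' barcode-promoter junction.
#'
#' @return Named list of 6-mer recognition sequences.
#' @export
restriction_sites <- function() {
  list(NheI = "GCTAGC", HindIII = "AAGCTT", XbaI = "TCTAGA",
       ApaI = "GGGCCC", FspI = "TGCGCA", HincII = "GTTAAC")
}

# Constant 20-mer immediately 5' of the barcode. In screen reads it occupies
# positions 7-26 (after the 6-nt index), putting the barcode at 27-46 with
# the XbaI site from position 47. The assay does not print this spacer; it is
# package configuration and the pipeline treats it as opaque.
CONST_BARCODE_FLANK <- "CGGCAAGATCGCCGTGTAAT"

# Deterministic fixed segment free of all landmark motifs. Internal seeds
# keep the template identical across sessions.
make_fixed_segment <- function(width, seed) {
  forb <- c(unlist(restriction_sites()), CONST_BARCODE_FLANK,
            unlist(default_flanks()))
  withr::with_seed(seed, {
    seg <- random_dna(1, width)
    guard <- 0L
    while (contains_any(seg, forb)) {
      # mutate the first base of each offending occurrence
      for (m in forb) {
        pos <- stringr::str_locate(seg, stringr::fixed(m))[1, 1]
        if (!is.na(pos)) {
          substr(seg, pos, pos) <- sample(setdiff(DNA_BASES,
                                                  substr(seg, pos, pos)), 1)
        }
      }
      guard <- guard + 1L
      if (guard > 200L) stop("template sanitization failed", call. = FALSE)
    }
    seg
  })
}

plant_site <- function(seg, site, at) {   # `at` is 1-based
  substr(seg, at, at + nchar(site) - 1) <- site
  seg
}

.template_cache <- new.env(parent = emptyenv())

#' Default reporter construct template
#'
#' Defines the fixed vector context into which a tandem-repeat promoter and
#' a barcode are assembled:
#' `pad5 | NheI | promoter | TATA stub | HindIII | reporter stub | constant
#' flank | barcode | XbaI | pad3`.
#' The reporter stub carries single ApaI, FspI and HincII sites and is sized
#' so the NheI-XbaI span of an assembled construct is 2275 bp, matching the
#' scale of the assay's gel-purified association fragment. None of these
#' fixed sequences is dictated by the assay; they are package configuration.
#'
#' @param n_repeats Repeat units per promoter the template expects (default 6).
#' @return List of template components and expected landmark counts.
#' @export
default_template <- function(n_repeats = 6) {
  key <- paste0("tmpl_", n_repeats)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  sites <- restriction_sites()
  insert_len <- n_repeats * 84
  # NheI..XbaI span = 6 + insert + 40 + 6 + stub + 20 + 20 = 2275 for 6 repeats
  stub_len <- 2275 - (6 + insert_len + 40 + 6 + 20 + 20)
  if (stub_len < 1400) stub_len <- 1400  # keep room for the three sites
  stub <- make_fixed_segment(stub_len, seed = 990001)
  stub <- plant_site(stub, sites$ApaI, 301)
  stub <- plant_site(stub, sites$FspI, 801)
  stub <- plant_site(stub, sites$HincII, 1301)
  tmpl <- list(
    n_repeats = n_repeats,
    pad5 = make_fixed_segment(30, seed = 990002),
    tata = make_fixed_segment(40, seed = 990003),
    reporter_stub = stub,
    const_flank = CONST_BARCODE_FLANK,
    pad3 = make_fixed_segment(60, seed = 990004),
    flanks = default_flanks(),
    barcode_pattern = BARCODE_PATTERN
  )
  .template_cache[[key]] <- tmpl
  tmpl
}

#' Assemble a barcoded reporter construct
#'
#' Joins a promoter insert and a barcode into the template and records
#' 0-based landmark offsets. Landmark order along the sequence is
#' NheI < promoter < HindIII < reporter stub < barcode < XbaI, so a single
#' NheI + XbaI digest yields one fragment carrying both promoter and barcode.
#'
#' @param promoter List as returned by [generate_promoter_insert()], or a
#'   plain promoter sequence string.
#' @param barcode Barcode string matching the template's degenerate pattern.
#' @param template Template from [default_template()].
#' @return One-row tibble: `sequence`, landmark offsets (`nhei`, `hindiii`,
#'   `apai`, `fspi`, `hincii`, `barcode_start`, `xbai`; 0-based) and
#'   `insert_length`.
#' @export
assemble_construct <- function(promoter, barcode, template = default_template()) {
  promoter_seq <- if (is.list(promoter)) promoter$promoter_seq else promoter
  if (!matches_pattern(barcode, template$barcode_pattern)) {
    stop("validation error: barcode does not match the library pattern ",
         template$barcode_pattern, call. = FALSE)
  }
  sites <- restriction_sites()
  parts <- c(template$pad5, sites$NheI, promoter_seq, template$tata,
             sites$HindIII, template$reporter_stub, template$const_flank,
             barcode, sites$XbaI, template$pad3)
  lens <- nchar(parts)
  off <- cumsum(c(0, lens[-length(lens)]))  # 0-based start of each part
  tibble::tibble(
    sequence = paste0(parts, collapse = ""),
    nhei = off[2], hindiii = off[5],
    apai = off[6] + 300, fspi = off[6] + 800, hincii = off[6] + 1300,
    const_start = off[7], barcode_start = off[8], xbai = off[9],
    insert_length = nchar(promoter_seq)
  )
}

#' Recover barcode and promoter from an assembled construct
#'
#' Inverse of [assemble_construct()] by anchored substring extraction: the
#' promoter sits between the NheI site and the TATA stub, the barcode
#' between its constant flank and the XbaI site.
#'
#' @param sequence Construct sequence.
#' @param template Template used for assembly.
#' @return List with `promoter_seq`, `cores` and `barcode`.
#' @export
extract_construct_parts <- function(sequence, template = default_template()) {
  sites <- restriction_sites()
  nhei <- stringr::str_locate(sequence, stringr::fixed(sites$NheI))[1, 1]
  tata <- stringr::str_locate(sequence, stringr::fixed(template$tata))[1, 1]
  cf <- stringr::str_locate(sequence,
                            stringr::fixed(template$const_flank))[1, ]
  if (anyNA(c(nhei, tata, cf))) {
    stop("sequence does not contain the template anchors", call. = FALSE)
  }
  promoter_seq <- substr(sequence, nhei + 6, tata - 1)
  barcode <- substr(sequence, cf["end"] + 1, cf["end"] + 20)
  list(promoter_seq = promoter_seq,
       cores = split_promoter_cores(promoter_seq, template),
       barcode = barcode)
}

# Split a promoter insert into its 68-mer random cores.
split_promoter_cores <- function(promoter_seq, template = default_template()) {
  n <- nchar(promoter_seq) / 84
  stopifnot(n == floor(n))
  starts <- (seq_len(n) - 1) * 84 + 8 + 1
  substring(promoter_seq, starts, starts + 67)
}
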