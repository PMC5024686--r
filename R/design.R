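#' The canonical degenerate barcode pattern
#'
#' Twenty positions, each restricted to one of the triple-degenerate IUPAC
#' codes H, D, V or B, i.e. exactly three admissible bases per position.
#' The admissible barcode space is therefore 3^20 (about 3.5e9), in vast
#' excess over any realistic plasmid library, which makes barcode collisions
#' between plasmids statistically negligible.
#'
#' @export
BARCODE_PATTERN <- "HHDDDDHHBBVVDDDDHDBV"

validate_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  codes <- strsplit(pattern, "")[[1]]
  unknown <- setdiff(codes, names(iupac_table()))
  if (length(unknown) > 0) {
    stop("invalid degenerate pattern: unknown IUPAC code(s) ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  codes
}

#' Size of a degenerate sequence space
#'
#' Product over pattern positions of the number of bases each IUPAC code
#' admits. Returned as a double since 3^20 exceeds integer range.
#'
#' @param pattern IUPAC degeneracy string, e.g. [BARCODE_PATTERN].
#' @return Number of distinct realisations of the pattern.
#' @examples
#' degenerate_space_size("NN")                  # 16
#' degenerate_space_size(BARCODE_PATTERN)       # 3486784401 ~ 3.5e9
#' @export
degenerate_space_size <- function(pattern) {
  codes <- validate_pattern(pattern)
  tab <- iupac_table()
  prod(vapply(codes, function(cc) length(tab[[cc]]), numeric(1)))
}

#' Sample distinct barcodes conforming to a degenerate pattern
#'
#' Draws each position uniformly from the bases its IUPAC code admits and
#' resamples until all barcodes are distinct (duplicates are vanishingly
#' rare for the canonical 3^20 space).
#'
#' @param pattern IUPAC degeneracy string.
#' @param n Number of barcodes.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n` distinct barcodes.
#' @export
sample_barcodes <- function(pattern, n, seed = NULL) {
  codes <- validate_pattern(pattern)
  stopifnot(n >= 0)
  space <- degenerate_space_size(pattern)
  if (n > space) {
    stop("capacity error: requested ", n, " barcodes but pattern space is ",
         space, call. = FALSE)
  }
  if (n == 0) return(character(0))
  tab <- iupac_table()
  with_seed_if(seed, {
    draw <- function(k) {
      cols <- lapply(codes, function(cc) sample(tab[[cc]], k, replace = TRUE))
      do.call(paste0, cols)
    }
    out <- unique(draw(n))
    guard <- 0L
    while (length(out) < n) {
      out <- unique(c(out, draw(n - length(out))))
      guard <- guard + 1L
      if (guard > 1000L) stop("capacity error: barcode space too small to draw ",
                              n, " distinct barcodes", call. = FALSE)
    }
    out[seq_len(n)]
  })
}

#' Check barcodes against a degenerate pattern
#'
#' Position-by-position IUPAC membership test.
#'
#' @param barcodes Character vector.
#' @param pattern IUPAC degeneracy string.
#' @return Logical vector, TRUE where the barcode conforms.
#' @export
matches_pattern <- function(barcodes, pattern = BARCODE_PATTERN) {
  codes <- validate_pattern(pattern)
  tab <- iupac_table()
  regex <- paste0("^", paste0(vapply(codes, function(cc)
    paste0("[", paste0(tab[[cc]], collapse = ""), "]"), character(1)),
    collapse = ""), "$")
  nchar(barcodes) == length(codes) & grepl(regex, barcodes)
}

#' Design Hamming-separated sample indexes
#'
#' Greedy randomized construction of `n` indexes of the given length whose
#' minimum pairwise Hamming distance is at least `min_dist`. A minimum
#' distance of 3 guarantees that any single sequencing error still maps a
#' read uniquely back to its sample, and that at least three errors are
#' needed to convert one index into another.
#'
#' @param n Number of indexes.
#' @param length Index length in nt (default 6).
#' @param min_dist Required minimum pairwise Hamming distance (default 3).
#' @param seed Optional integer seed.
#' @param max_attempts Candidate draws before declaring the search exhausted.
#' @return Tibble with columns `sample_id` (idx01, idx02, ...) and `index`.
#' @export
design_indexes <- function(n, length = 6, min_dist = 3, seed = NULL,
                           max_attempts = 20000) {
  stopifnot(n >= 1, min_dist <= length)
  # Singleton bound: no q-ary code of this length/distance can exceed this.
  if (n > 4^(length - min_dist + 1)) {
    stop("infeasibility error: ", n, " indexes of length ", length,
         " at distance ", min_dist, " exceed the Singleton bound (",
         4^(length - min_dist + 1), ")", call. = FALSE)
  }
  with_seed_if(seed, {
    accepted <- character(0)
    acc_mat <- NULL
    attempts <- 0L
    while (length(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("infeasibility error: index search exhausted after ",
             max_attempts, " attempts with ", length(accepted), "/", n,
             " indexes placed", call. = FALSE)
      }
      cand <- random_dna(1, length)
      ci <- utf8ToInt(cand)
      ok <- is.null(acc_mat) ||
        min(rowSums(acc_mat != matrix(ci, nrow(acc_mat), length,
                                      byrow = TRUE))) >= min_dist
      if (ok) {
        accepted <- c(accepted, cand)
        acc_mat <- rbind(acc_mat, ci)
      }
    }
    tibble::tibble(
      sample_id = sprintf("idx%02d", seq_len(n)),
      index = accepted
    )
  })
}

#' Default repeat-unit flank design
#'
#' The 8-nt constant flanks on either side of each 68-nt random core are not
#' dictated by the assay; these package defaults avoid all restriction
#' landmarks used elsewhere in the construct.
#'
#' @return List with `left_flank` and `right_flank` (8 nt each).
#' @export
default_flanks <- function() {
  list(left_flank = "ACGGTCTC", right_flank = "GAGACCTT")
}

#' Generate one 84-bp tandem-repeat unit
#'
#' A unit is an 8-nt constant left flank, a 68-nt uniformly random core and
#' an 8-nt constant right flank (8 + 68 + 8 = 84 bp). Cores are
#' rejection-sampled so they never contain a restriction landmark or the
#' constant barcode flank; see the methods vignette for why the generator
#' keeps landmarks unique per construct.
#'
#' @param flanks List with `left_flank`/`right_flank`, as [default_flanks()].
#' @param core_width Random core width (default 68).
#' @param seed Optional integer seed.
#' @return One-row tibble: `seq`, `left_flank`, `random_core`, `right_flank`.
#' @export
generate_repeat_unit <- function(flanks = default_flanks(), core_width = 68,
                                 seed = NULL) {
  stopifnot(nchar(flanks$left_flank) == 8, nchar(flanks$right_flank) == 8)
  core <- with_seed_if(seed, random_core(1, core_width))
  tibble::tibble(
    seq = paste0(flanks$left_flank, core, flanks$right_flank),
    left_flank = flanks$left_flank,
    random_core = core,
    right_flank = flanks$right_flank
  )
}

# Forbidden fixed strings inside random cores (restriction landmarks + the
# constant barcode flank); keeps each landmark unique within a construct.
forbidden_in_cores <- function() {
  c(unlist(restriction_sites()), CONST_BARCODE_FLANK)
}

# n random cores free of forbidden landmarks (rejection sampling). Cores are
# screened in flank context so that no landmark can form across a core-flank
# boundary either.
random_core <- function(n, width = 68, flanks = default_flanks()) {
  pad_l <- substr(flanks$left_flank, 4, 8)
  pad_r <- substr(flanks$right_flank, 1, 5)
  screen <- function(cores) {
    contains_any(paste0(pad_l, cores, pad_r), forbidden_in_cores())
  }
  out <- random_dna(n, width)
  bad <- screen(out)
  guard <- 0L
  while (any(bad)) {
    out[bad] <- random_dna(sum(bad), width)
    bad <- screen(out)
    guard <- guard + 1L
    if (guard > 1000L) stop("core resampling failed to converge", call. = FALSE)
  }
  out
}

#' Generate a tandem-repeat promoter insert
#'
#' Concatenates `n_repeats` units sharing the same flank design, each with an
#' independent random core: the default six units carry 6 x 68 = 408 bp of
#' random sequence per promoter.
#'
#' @param n_repeats Number of repeat units (default 6).
#' @param flanks Flank design, as [default_flanks()].
#' @param seed Optional integer seed.
#' @return List with `promoter_seq` (character) and `cores`
#'   (character vector of the 68-mers, 5' to 3').
#' @export
generate_promoter_insert <- function(n_repeats = 6, flanks = default_flanks(),
                                     seed = NULL) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  cores <- with_seed_if(seed, random_core(n_repeats))
  units <- paste0(flanks$left_flank, cores, flanks$right_flank)
  list(promoter_seq = paste0(units, collapse = ""), cores = cores)
}

#' Expected motif occupancy of a random-sequence library
#'
#' Closed-form estimate of how often a motif of a given width is expected to
#' occur by chance in a pool of random DNA, the premise that makes random
#' tandem-repeat promoters informative: most transcription-factor binding
#' sites are short enough to occur spontaneously. `expected` counts motif
#' placements (`strands * n_variants * (L - w + 1) / 4^w`) and
#' `p_at_least_one` applies a Poisson approximation.
#'
#' @param motif_width Motif width in nt.
#' @param n_degenerate_variants Number of distinct sequences matching the
#'   motif (e.g. 2^6 = 64 for the CArG box CC(A/T)6GG).
#' @param total_random_bp Total random base pairs screened.
#' @param strands 1 or 2.
#' @return Tibble with `expected_hits` and `p_at_least_one`.
#' @export
motif_occupancy_estimate <- function(motif_width, n_degenerate_variants = 1,
                                     total_random_bp, strands = 2) {
  stopifnot(motif_width >= 1, total_random_bp >= motif_width,
            strands %in% c(1, 2))
  expected <- strands * n_degenerate_variants *
    (total_random_bp - motif_width + 1) / 4^motif_width
  tibble::tibble(expected_hits = expected,
                 p_at_least_one = 1 - exp(-expected))
}

#' Total random base pairs interrogated by a screen
#'
#' Screened random sequence: retained barcodes x random bp per repeat x
#' strands scanned. With the study-scale 3065 retained barcodes, 68 random
#' bp and both strands this exceeds 400,000 bp.
#'
#' @param n_barcodes Retained barcodes.
#' @param random_bp_per_repeat Random bp per repeat unit (default 68).
#' @param strands Strands scanned (default 2).
#' @return Total random bp (double).
#' @export
screened_random_bp <- function(n_barcodes, random_bp_per_repeat = 68,
                               strands = 2) {
  n_barcodes * random_bp_per_repeat * strands
}
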