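#' IUPAC nucleotide expansion table
#'
#' Maps each IUPAC degeneracy code to the set of bases it stands for. The
#' four triple-degenerate codes (H, D, V, B) are the building blocks of the
#' barcode synthesis scheme: allowing exactly three bases per position avoids
#' long homopolymers and makes single-base sequencing errors detectable.
#'
#' @return Named list of character vectors, one per IUPAC code.
#' @export
iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming_distance("AAAAAA", "AAATTT")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance() requires equal-length sequences (",
         nchar(a), " vs ", nchar(b), ")", call. = FALSE)
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' All-pairs minimum Hamming distance of a sequence set
#'
#' Brute-force verification over every pair; used to validate index designs.
#'
#' @param seqs Character vector of equal-length sequences (length >= 2).
#' @return Integer, the minimum pairwise Hamming distance.
#' @export
min_pairwise_hamming <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  m <- do.call(rbind, lapply(seqs, utf8ToInt))
  best <- nchar(seqs[[1]])
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(m[(i + 1):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of ACGT (IUPAC allowed) sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random DNA strings; vectorised over n sequences of common width.
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Does `x` contain any of the motifs (fixed strings)?
contains_any <- function(x, motifs) {
  hit <- rep(FALSE, length(x))
  for (m in motifs) hit <- hit | stringr::str_detect(x, stringr::fixed(m))
  hit
}

# Encode an ACGT string as integers 1..4; stops on anything else.
encode_dna <- function(seq) {
  code <- utf8ToInt(seq)
  out <- match(code, utf8ToInt("ACGT"))
  if (anyNA(out)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  out
}

# Scoped seed helper: runs expr with a temporary RNG state when seed is given.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
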