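# Small in-code fixtures shared across test files.

# A tiny simulated screen: library + design + expected expression + counts.
tiny_screen <- function(n_plasmids = 120, depth = 2e4, error_rate = 0,
                        seed = 7, planted = default_planted(), ...) {
  cfg <- sim_config(n_plasmids = n_plasmids, depth = depth,
                    error_rate = error_rate, planted = planted,
                    seed = seed, ...)
  sim <- simulate_library(cfg)
  design <- sample_design(cfg)
  expr <- simulate_expression(sim$truth, cfg, design)
  counts <- simulate_screen_counts(expr, depth, seed = seed + 41L)
  list(cfg = cfg, library = sim$library, truth = sim$truth, design = design,
       expression = expr, counts = counts)
}

# Ground-truth association table (support set above any threshold).
truth_association <- function(truth, support = 60) {
  pairs <- dplyr::distinct(truth[, c("barcode", "promoter_id")])
  build_association_table(pairs[rep(seq_len(nrow(pairs)), support), ],
                          min_reads = 50)
}

# Independent occurrence counter: exact overlapping matches of a fixed word
# in an encoded integer sequence.
count_word_occurrences <- function(enc, word_enc) {
  w <- length(word_enc)
  n_off <- length(enc) - w + 1
  if (n_off < 1) return(0L)
  hit <- rep(TRUE, n_off)
  for (p in seq_len(w)) {
    hit <- hit & (enc[p:(p + n_off - 1)] == word_enc[p])
  }
  sum(hit)
}

encode_bases <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
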