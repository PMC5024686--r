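#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic screen generator. The
#' defaults emulate the study conditions: a >3000-plasmid library of six
#' 84-bp repeats (68 random bp each), a wide log-normal baseline-expression
#' spread, two planted responder archetypes (an immediate-early pulse
#' peaking at 1 h carrying the CArG box, and a delayed pulse peaking at
#' 3 h), a drug + vehicle design sampled at 0, 1, 2, 4 and 8 h, and
#' substitution-only sequencing errors.
#'
#' @param n_plasmids Number of barcoded constructs (default 3000).
#' @param n_repeats Repeat units per promoter (default 6).
#' @param barcode_pattern Degenerate barcode pattern.
#' @param baseline_log10_mean,baseline_log10_sd Log10-normal baseline
#'   abundance parameters (defaults 2 and 0.8).
#' @param planted Tibble of planted responder groups: `group`, `consensus`
#'   (IUPAC), `fraction` of plasmids, `amplitude`, `tau_h` (peak time),
#'   `treatment` (the drug the group responds to).
#' @param treatments Drug labels (default "JASP").
#' @param control_treatment Vehicle label (default "DMSO").
#' @param times Sampling times in hours (default 0, 1, 2, 4, 8).
#' @param depth Reads per sample (default 1e6).
#' @param error_rate Per-base substitution rate (default 0.001).
#' @param duplicate_promoter_fraction Fraction of constructs that reuse an
#'   existing promoter under a new barcode (default 0.02), emulating
#'   multi-barcode promoters.
#' @param seed Master seed; all stages derive their streams from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_plasmids = 3000, n_repeats = 6,
                       barcode_pattern = BARCODE_PATTERN,
                       baseline_log10_mean = 2, baseline_log10_sd = 0.8,
                       planted = default_planted(),
                       treatments = "JASP", control_treatment = "DMSO",
                       times = c(0, 1, 2, 4, 8), depth = 1e6,
                       error_rate = 0.001,
                       duplicate_promoter_fraction = 0.02, seed = 1) {
  stopifnot(n_plasmids >= 1, n_repeats >= 1, depth >= 1, error_rate >= 0,
            error_rate < 1, duplicate_promoter_fraction >= 0,
            duplicate_promoter_fraction < 1)
  validate_pattern(barcode_pattern)
  if (nrow(planted) > 0) {
    stopifnot(all(c("group", "consensus", "fraction", "amplitude", "tau_h",
                    "treatment") %in% names(planted)))
    if (sum(planted$fraction) > 1) {
      stop("config error: planted fractions sum to more than 1", call. = FALSE)
    }
    if (any(planted$tau_h <= 0)) {
      stop("config error: tau_h must be positive", call. = FALSE)
    }
    if (!all(planted$treatment %in% treatments)) {
      stop("config error: planted treatment not in design", call. = FALSE)
    }
  }
  structure(list(
    n_plasmids = n_plasmids, n_repeats = n_repeats,
    barcode_pattern = barcode_pattern,
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    planted = planted, treatments = treatments,
    control_treatment = control_treatment, times = times, depth = depth,
    error_rate = error_rate,
    duplicate_promoter_fraction = duplicate_promoter_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted <- function() {
  tibble::tibble(
    group = c("immediate_early", "delayed"),
    consensus = c("CCWWWWWWGG", "GGGACTTTCC"),
    fraction = c(0.005, 0.005),
    amplitude = c(9, 9),
    tau_h = c(1, 3),
    treatment = "JASP"
  )
}

#' Sample design (sample sheet) for a simulated screen
#'
#' One sample per treatment x time, with Hamming-3 sample indexes.
#'
#' @param cfg A `sim_config`.
#' @return Tibble `sample_id`, `treatment`, `time_h`, `index`.
#' @export
sample_design <- function(cfg) {
  design <- tidyr::expand_grid(
    treatment = c(cfg$treatments, cfg$control_treatment),
    time_h = cfg$times
  ) |>
    dplyr::mutate(sample_id = paste0(.data$treatment, "_", .data$time_h, "h"),
                  .before = 1)
  idx <- design_indexes(nrow(design), length = 6, min_dist = 3,
                        seed = cfg$seed + 11L)
  design$index <- idx$index
  design
}

# Distinct pattern-conforming barcodes whose assembled context
# (constant flank | barcode | XbaI) contains the single terminal XbaI site
# and no other restriction landmark: the degenerate pattern alone does not
# forbid e.g. an internal TCTAGA, which would cleave the barcode off the
# association fragment. Rejection sampling keeps the barcode cassette clean.
draw_clean_barcodes <- function(pattern, n, template = default_template()) {
  sites <- restriction_sites()
  clean <- function(bc) {
    ctx <- paste0(template$const_flank, bc, sites$XbaI)
    n_xbai <- stringr::str_count(ctx, stringr::fixed(sites$XbaI))
    ok <- n_xbai == 1
    for (s in sites[setdiff(names(sites), "XbaI")]) {
      ok <- ok & !stringr::str_detect(ctx, stringr::fixed(s))
    }
    ok
  }
  out <- sample_barcodes(pattern, n)
  bad <- !clean(out)
  guard <- 0L
  while (any(bad)) {
    cand <- sample_barcodes(pattern, 2L * sum(bad))
    cand <- setdiff(cand[clean(cand)], out)
    take <- min(length(cand), sum(bad))
    if (take > 0) {
      out[which(bad)[seq_len(take)]] <- cand[seq_len(take)]
      bad <- !clean(out)
    }
    guard <- guard + 1L
    if (guard > 1000L) stop("barcode resampling failed to converge",
                            call. = FALSE)
  }
  out
}

# Resolve an IUPAC consensus into one concrete sequence (random choice per
# degenerate position).
resolve_consensus <- function(consensus) {
  tab <- iupac_table()
  paste0(vapply(strsplit(consensus, "")[[1]],
                function(cc) sample(tab[[cc]], 1), character(1)),
         collapse = "")
}

#' Simulate a barcoded tandem-repeat promoter library
#'
#' Draws distinct pattern-conforming barcodes and random six-repeat
#' promoters, plants the configured responder motifs into randomly chosen
#' repeat cores at random offsets, duplicates a fraction of promoters under
#' fresh barcodes, and assembles full construct sequences. Amplitudes given
#' as a length-2 `c(min, max)` range in `planted` draw per-plasmid
#' amplitudes uniformly from that range.
#'
#' @param cfg A `sim_config`.
#' @return List with `library` (manifest tibble: `library_id`,
#'   `promoter_id`, `barcode`, `sequence`, `core1`, `cores`) and `truth`
#'   (per-construct ground truth incl. `group`, `amplitude`, `tau_h`,
#'   `responsive_treatment`, `baseline`).
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 21L, {
    n_dup <- round(cfg$n_plasmids * cfg$duplicate_promoter_fraction)
    n_prom <- cfg$n_plasmids - n_dup
    barcodes <- draw_clean_barcodes(cfg$barcode_pattern, cfg$n_plasmids,
                                    default_template(cfg$n_repeats))
    cores <- matrix(random_core(n_prom * cfg$n_repeats), nrow = n_prom)
    prom_group <- rep("none", n_prom)
    prom_motif <- rep(NA_character_, n_prom)
    prom_site <- rep(NA_character_, n_prom)
    prom_repeat <- rep(NA_integer_, n_prom)
    prom_offset <- rep(NA_integer_, n_prom)
    prom_amp <- rep(0, n_prom)
    prom_tau <- rep(NA_real_, n_prom)
    prom_treat <- rep(NA_character_, n_prom)
    if (nrow(cfg$planted) > 0) {
      free <- seq_len(n_prom)
      for (g in seq_len(nrow(cfg$planted))) {
        row <- cfg$planted[g, ]
        n_g <- round(row$fraction * n_prom)
        if (n_g == 0) next
        chosen <- sample(free, n_g)
        free <- setdiff(free, chosen)
        w <- nchar(row$consensus)
        amp <- row$amplitude[[1]]
        amps <- if (length(amp) == 2) stats::runif(n_g, amp[1], amp[2]) else
          rep(amp, n_g)
        for (j in seq_along(chosen)) {
          i <- chosen[j]
          repeat {
            rp <- sample.int(cfg$n_repeats, 1)
            off <- sample.int(68 - w + 1, 1)
            site <- resolve_consensus(row$consensus)
            core <- cores[i, rp]
            substr(core, off, off + w - 1) <- site
            padded <- paste0(substr(default_flanks()$left_flank, 4, 8), core,
                             substr(default_flanks()$right_flank, 1, 5))
            if (!contains_any(padded, forbidden_in_cores())) {
              cores[i, rp] <- core
              break
            }
          }
          prom_group[i] <- row$group
          prom_motif[i] <- row$consensus
          prom_site[i] <- site
          prom_repeat[i] <- rp
          prom_offset[i] <- off
          prom_amp[i] <- amps[j]
          prom_tau[i] <- row$tau_h
          prom_treat[i] <- row$treatment
        }
      }
    }
    # constructs: each promoter once, plus duplicates under new barcodes
    prom_of_construct <- c(seq_len(n_prom),
                           if (n_dup > 0) sample.int(n_prom, n_dup,
                                                     replace = TRUE))
    flanks <- default_flanks()
    unit_seqs <- matrix(paste0(flanks$left_flank, cores, flanks$right_flank),
                        nrow = n_prom)
    promoter_seqs <- do.call(paste0, as.data.frame(unit_seqs,
                                                   stringsAsFactors = FALSE))
    tmpl <- default_template(cfg$n_repeats)
    sites <- restriction_sites()
    sequence <- paste0(tmpl$pad5, sites$NheI, promoter_seqs[prom_of_construct],
                       tmpl$tata, sites$HindIII, tmpl$reporter_stub,
                       tmpl$const_flank, barcodes, sites$XbaI, tmpl$pad3)
    promoter_id <- sprintf("P%04d", prom_of_construct)
    baseline <- 10^stats::rnorm(cfg$n_plasmids, cfg$baseline_log10_mean,
                                cfg$baseline_log10_sd)
    lib <- tibble::tibble(
      library_id = sprintf("L%04d", seq_len(cfg$n_plasmids)),
      promoter_id = promoter_id,
      barcode = barcodes,
      sequence = sequence,
      core1 = cores[prom_of_construct, 1],
      cores = lapply(prom_of_construct, function(i) cores[i, ])
    )
    truth <- tibble::tibble(
      library_id = lib$library_id,
      barcode = barcodes,
      promoter_id = promoter_id,
      group = prom_group[prom_of_construct],
      planted_motif = prom_motif[prom_of_construct],
      planted_site = prom_site[prom_of_construct],
      planted_repeat = prom_repeat[prom_of_construct],
      planted_offset = prom_offset[prom_of_construct],
      amplitude = prom_amp[prom_of_construct],
      tau_h = prom_tau[prom_of_construct],
      responsive_treatment = prom_treat[prom_of_construct],
      baseline = baseline
    )
    list(library = lib, truth = truth)
  })
}

#' Induction pulse
#'
#' Gamma-like pulse `1 + A (t/tau) exp(1 - t/tau)`: zero induction at
#' t = 0, peak fold change `1 + A` exactly at `t = tau`, and a gradual
#' decay thereafter -- an idealisation of immediate-early (tau ~ 1-2 h)
#' versus delayed (tau ~ 3-4 h) induction kinetics.
#'
#' @param t Time (hours), vectorised.
#' @param amplitude Pulse amplitude A.
#' @param tau Peak time (hours, > 0).
#' @return Multiplicative induction factor.
#' @export
induction_pulse <- function(t, amplitude, tau) {
  if (any(tau <= 0, na.rm = TRUE)) stop("config error: tau must be > 0",
                                        call. = FALSE)
  1 + amplitude * (t / tau) * exp(1 - t / tau)
}

#' Expected abundance matrix of a simulated screen
#'
#' Each barcode's expected abundance is its baseline times the induction
#' pulse in samples of its responsive drug, and exactly the baseline in
#' vehicle and time-0 samples.
#'
#' @param truth Truth table from [simulate_library()].
#' @param cfg A `sim_config`.
#' @param design Sample design (defaults to [sample_design()]).
#' @return Long tibble `barcode`, `sample_id`, `abundance`, plus the
#'   expected fold-change trajectory column `expected_fc`.
#' @export
simulate_expression <- function(truth, cfg, design = sample_design(cfg)) {
  stopifnot(all(cfg$times %in% design$time_h))
  out <- tidyr::expand_grid(truth[, c("barcode", "group", "amplitude",
                                      "tau_h", "responsive_treatment",
                                      "baseline")],
                            design[, c("sample_id", "treatment", "time_h")])
  responsive <- !is.na(out$responsive_treatment) &
    out$treatment == out$responsive_treatment & out$time_h > 0
  fc <- rep(1, nrow(out))
  fc[responsive] <- induction_pulse(out$time_h[responsive],
                                    out$amplitude[responsive],
                                    out$tau_h[responsive])
  out$expected_fc <- fc
  out$abundance <- out$baseline * fc
  out[, c("barcode", "sample_id", "treatment", "time_h", "expected_fc",
          "abundance")]
}

#' Multinomial read counts per sample
#'
#' Draws each sample's barcode counts as one multinomial of size `depth`
#' over the normalized expected abundances -- the minimal sampling model
#' for pooled amplicon sequencing at fixed depth.
#'
#' @param expression Expected abundance tibble from [simulate_expression()].
#' @param depth Reads per sample.
#' @param seed Optional integer seed.
#' @return Long tibble `barcode`, `sample_id`, `count`.
#' @export
simulate_screen_counts <- function(expression, depth, seed = NULL) {
  with_seed_if(seed, {
    expression |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(count = as.integer(
        stats::rmultinom(1, depth, .data$abundance / sum(.data$abundance))
      )) |>
      dplyr::ungroup() |>
      dplyr::select("barcode", "sample_id", "count")
  })
}

# Inject i.i.d. substitution errors; loops only over affected reads.
apply_sequencing_errors <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0) return(reads)
  widths <- nchar(reads)
  n_err <- stats::rbinom(length(reads), widths, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES,
                                               substr(reads[i], p, p)), 1)
    }
  }
  reads
}

#' Simulate multiplexed screen reads
#'
#' Expands per-sample counts into 100-nt reads laid out as
#' `index (6) | constant spacer (20) | barcode (20) | XbaI | 3' UTR filler`,
#' applies substitution errors, and optionally writes a multiplexed FASTQ
#' (constant placeholder qualities: the counting pipeline ignores quality).
#'
#' @param counts Long tibble `barcode`, `sample_id`, `count`.
#' @param design Sample design with `sample_id` and `index`.
#' @param cfg A `sim_config` (supplies the error rate and template).
#' @param fastq Optional output FASTQ path.
#' @return Character vector of reads (names = sample ids); written to
#'   `fastq` as a side effect when requested.
#' @export
simulate_screen_reads <- function(counts, design, cfg, fastq = NULL) {
  tmpl <- default_template(cfg$n_repeats)
  layout <- read_layout()
  filler <- substr(paste0(tmpl$pad3, tmpl$pad3), 1,
                   layout$read_length - 52)
  withr::with_seed(cfg$seed + 31L, {
    idx <- design$index[match(counts$sample_id, design$sample_id)]
    reads <- rep(paste0(idx, tmpl$const_flank, counts$barcode,
                        restriction_sites()$XbaI, filler),
                 counts$count)
    names(reads) <- rep(counts$sample_id, counts$count)
    reads <- apply_sequencing_errors(reads, cfg$error_rate)
    if (!is.null(fastq)) {
      write_fastq(tibble::tibble(
        id = paste0("read", seq_along(reads)), seq = unname(reads)
      ), fastq)
    }
    reads
  })
}

#' Simulate association reads (junction or long mode)
#'
#' Junction mode runs the association protocol in silico for every
#' construct -- NheI + XbaI digestion, selection of the promoter-barcode
#' fragment, circularization, independent relinearization with ApaI, FspI
#' and HincII -- and emits 150-nt reads across the ligation junction from
#' every aliquot whose junction stayed intact. Long mode emits the full
#' NheI-XbaI fragment per construct, half of them reverse-complemented.
#' Unligated (linear) molecules are never emitted, mirroring their
#' exonuclease removal.
#'
#' @param library Library manifest from [simulate_library()].
#' @param mode "junction" or "long".
#' @param coverage Reads per construct (default 60).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Optional integer seed.
#' @param read_length Junction read length (default 150).
#' @return Character vector of reads.
#' @export
simulate_association_reads <- function(library, mode = c("junction", "long"),
                                       coverage = 60, error_rate = 0,
                                       seed = NULL, read_length = 150) {
  mode <- match.arg(mode)
  stopifnot(coverage >= 1)
  sites <- restriction_sites()
  lin_enzymes <- sites[c("ApaI", "FspI", "HincII")]
  with_seed_if(seed, {
    reads <- lapply(seq_len(nrow(library)), function(i) {
      frags <- insilico_digest(library$sequence[i],
                               sites[c("NheI", "XbaI")])
      frag <- frags$seq[startsWith(frags$seq, sites$NheI)][1]
      if (is.na(frag)) return(character(0))
      if (mode == "long") {
        r <- rep(frag, coverage)
        flip <- sample(c(TRUE, FALSE), coverage, replace = TRUE)
        r[flip] <- reverse_complement(r[flip])
        return(r)
      }
      circle <- circularize_fragment(new_fragment(frag))
      pool <- suppressWarnings(linearize_circle(circle, lin_enzymes))
      upstream <- read_length - 104  # bases 5' of the junction in the read
      window <- paste0(substr(frag, nchar(frag) - upstream + 1, nchar(frag)),
                       substr(frag, 1, 104))
      valid <- pool$seq[vapply(pool$seq, function(s)
        grepl(window, s, fixed = TRUE), logical(1))]
      if (length(valid) == 0) return(character(0))
      rep(window, coverage)
    })
    apply_sequencing_errors(unlist(reads), error_rate)
  })
}

#' One-call simulated screen
#'
#' Runs the generator end to end: library + truth, sample design, expected
#' expression, multinomial counts and (optionally) screen reads.
#'
#' @param cfg A `sim_config`.
#' @param reads Also simulate read sequences (default TRUE).
#' @return List: `library`, `truth`, `design`, `expression`, `counts`,
#'   and `reads` (when requested).
#' @export
simulate_screen <- function(cfg, reads = TRUE) {
  sim <- simulate_library(cfg)
  design <- sample_design(cfg)
  expr <- simulate_expression(sim$truth, cfg, design)
  counts <- simulate_screen_counts(expr, cfg$depth, seed = cfg$seed + 41L)
  out <- list(library = sim$library, truth = sim$truth, design = design,
              expression = expr, counts = counts)
  if (reads) {
    out$reads <- simulate_screen_reads(counts, design, cfg)
  }
  out
}
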