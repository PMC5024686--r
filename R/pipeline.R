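run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulated screen pipeline
#'
#' One-command end-to-end driver: simulate the library, establish the
#' barcode-promoter association from junction reads, simulate and count the
#' multiplexed screen reads, normalize, compute fold changes and the
#' drug-response ranking, cluster the top responders, and run motif-set
#' enrichment against the synthetic consensus panel. Every stage writes a
#' TSV artifact with a metadata header (tool version, config hash, seed)
#' plus a JSON QC summary; any stage failure aborts with the stage named.
#'
#' @param config A `pipeline_config` (see [load_config()]), a path to a
#'   YAML config, or a named list of overrides.
#' @return Invisibly, a named list of artifact paths (plus the in-memory
#'   results in `attr(, "results")`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    load_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only; output location is not content
  hash_cfg <- unclass(cfg)
  hash_cfg$out_dir <- NULL
  meta <- list(config_hash = rlang::hash(hash_cfg), seed = cfg$seed)
  paths <- list()
  scfg <- sim_config(
    n_plasmids = cfg$n_plasmids, n_repeats = cfg$n_repeats,
    depth = cfg$depth, error_rate = cfg$error_rate,
    duplicate_promoter_fraction = cfg$duplicate_promoter_fraction,
    treatments = cfg$treatments, control_treatment = cfg$control_treatment,
    times = cfg$times, seed = cfg$seed
  )

  sim <- run_stage("simulate", simulate_library(scfg))
  design <- run_stage("simulate", sample_design(scfg))
  paths$library_manifest <- file.path(out_dir, "library_manifest.tsv")
  write_tsv_artifact(sim$library, paths$library_manifest, meta)
  paths$truth <- file.path(out_dir, "truth.tsv")
  write_tsv_artifact(sim$truth, paths$truth, meta)
  paths$sample_sheet <- file.path(out_dir, "sample_sheet.tsv")
  write_tsv_artifact(design, paths$sample_sheet, meta)

  assoc <- run_stage("associate", {
    jr <- simulate_association_reads(sim$library, "junction",
                                     coverage = cfg$coverage,
                                     error_rate = cfg$association_error_rate,
                                     seed = cfg$seed + 51L)
    associate_junction_reads(jr, sim$library, min_reads = cfg$min_reads)
  })
  paths$association <- file.path(out_dir, "association.tsv")
  write_tsv_artifact(assoc, paths$association, meta)

  counts <- run_stage("count", {
    expr <- simulate_expression(sim$truth, scfg, design)
    cts <- simulate_screen_counts(expr, scfg$depth, seed = cfg$seed + 41L)
    reads <- simulate_screen_reads(cts, design, scfg)
    count_screen_reads(reads, design, assoc, max_mismatch = cfg$max_mismatch)
  })
  paths$counts <- file.path(out_dir, "counts.tsv")
  write_tsv_artifact(counts, paths$counts, meta)

  quant <- run_stage("quantify", {
    norm <- median_normalize(counts)
    fc <- fold_changes(norm, design,
                       control_treatments = cfg$control_treatment,
                       pseudocount = cfg$pseudocount)
    ranking <- drug_response_score(fc,
                                   control_treatments = cfg$control_treatment)
    list(norm = norm, fc = fc, ranking = ranking)
  })
  paths$normalized <- file.path(out_dir, "normalized.tsv")
  write_tsv_artifact(quant$norm, paths$normalized, meta)
  paths$fold_changes <- file.path(out_dir, "fold_changes.tsv")
  write_tsv_artifact(quant$fc, paths$fold_changes, meta)
  paths$ranking <- file.path(out_dir, "ranking.tsv")
  write_tsv_artifact(quant$ranking, paths$ranking, meta)

  groups <- run_stage("cluster",
    merge_replicates_and_cluster(quant$ranking, quant$fc,
                                 top_k = cfg$top_k, k_groups = cfg$k_groups))
  paths$clusters <- file.path(out_dir, "clusters.tsv")
  write_tsv_artifact(groups, paths$clusters, meta)

  enrich <- run_stage("enrich", {
    motifs <- make_motif_panel()
    promoters <- sim$library |>
      dplyr::distinct(.data$promoter_id, .keep_all = TRUE) |>
      dplyr::select("promoter_id", "cores")
    first_drug <- setdiff(unique(quant$ranking$treatment),
                          cfg$control_treatment)[1]
    rk <- promoter_ranking(dplyr::filter(quant$ranking,
                                         .data$treatment == first_drug))
    hits <- scan_promoters(promoters |>
                             dplyr::filter(.data$promoter_id %in%
                                             rk$promoter_id), motifs)
    testable <- hits |>
      dplyr::distinct(.data$motif_id, .data$promoter_id) |>
      dplyr::count(.data$motif_id) |>
      dplyr::filter(.data$n > 0, .data$n < nrow(rk)) |>
      dplyr::pull(.data$motif_id)
    motif_set_enrichment(rk, hits, motif_ids = testable,
                         n_perm = cfg$n_perm,
                         weight_exponent = cfg$weight_exponent,
                         seed = cfg$seed + 61L)
  })
  paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  write_tsv_artifact(enrich, paths$enrichment, meta)

  qc <- list(
    config_hash = meta$config_hash, seed = cfg$seed,
    n_constructs = nrow(sim$library),
    n_associations = nrow(assoc),
    association_conflicts = nrow(attr(assoc, "conflicts")),
    count_qc = as.list(attr(counts, "qc")),
    qc_funnel = as.list(attr(counts, "qc_funnel")),
    n_retained_barcodes = dplyr::n_distinct(counts$barcode),
    n_response_groups = dplyr::n_distinct(groups$group)
  )
  paths$qc <- file.path(out_dir, "qc.json")
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  res <- list(library = sim$library, truth = sim$truth, design = design,
              association = assoc, counts = counts, norm = quant$norm,
              fc = quant$fc, ranking = quant$ranking, groups = groups,
              enrichment = enrich)
  out <- paths
  attr(out, "results") <- res
  invisible(out)
}
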