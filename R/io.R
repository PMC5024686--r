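#' Read a FASTQ file
#'
#' Lossless id/sequence/quality import (plain or gzip) via Biostrings.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return Tibble `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- tibble::tibble(
      id = names(x),
      seq = unname(as.character(x)),
      qual = unname(as.character(S4Vectors::mcols(x)$qualities))
    )
    out
  }, error = function(e) {
    stop("FASTQ parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write a FASTQ file
#'
#' @param records Tibble with `id`, `seq` and optionally `qual` (constant
#'   placeholder quality "I" is used when absent).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  qual <- if ("qual" %in% names(records)) records$qual else
    strrep("I", nchar(records$seq))
  writeXStringSet_fastq(x, qual, path)
  invisible(path)
}

writeXStringSet_fastq <- function(x, qual, path) {
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(qual)
  )
}

#' Write a TSV artifact with '#' metadata header
#'
#' Every pipeline artifact carries tool version, a config hash and the seed
#' in comment lines, so runs can be audited and reproduced.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_artifact <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("bcstarprom ",
                               as.character(utils::packageVersion("bcstarprom")))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = " "),
                        character(1)))
  writeLines(hdr, path)
  # drop list-columns; they are not representable in TSV
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV artifact (skipping '#' metadata)
#'
#' @param path Artifact path.
#' @return Tibble.
#' @export
read_tsv_artifact <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

pipeline_defaults <- function() {
  list(
    n_plasmids = 3000, n_repeats = 6, depth = 1e6, error_rate = 0.001,
    duplicate_promoter_fraction = 0.02, treatments = "JASP",
    control_treatment = "DMSO", times = c(0, 1, 2, 4, 8),
    min_reads = 50, max_mismatch = 1, pseudocount = 0, coverage = 60,
    association_error_rate = 0, top_k = 20, k_groups = 4, n_perm = 999,
    weight_exponent = 1, max_cv = 0.12, seed = 1, out_dir = "bcstarprom_out"
  )
}

#' Load and validate a pipeline configuration
#'
#' YAML config with defaults filled in; unknown keys are rejected and
#' out-of-range values named explicitly.
#'
#' @param path YAML file path, or a named list of overrides.
#' @return Validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  check_pos <- c("n_plasmids", "n_repeats", "depth", "coverage", "n_perm",
                 "top_k", "k_groups")
  for (k in check_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1) {
      stop("config error: key '", k, "' must be a positive number",
           call. = FALSE)
    }
  }
  for (k in c("error_rate", "association_error_rate", "max_cv",
              "pseudocount", "duplicate_promoter_fraction")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop("config error: key '", k, "' must be non-negative", call. = FALSE)
    }
  }
  if (!cfg$max_mismatch %in% c(0, 1)) {
    stop("config error: key 'max_mismatch' must be 0 or 1", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips through [load_config()].
#'
#' @param cfg `pipeline_config` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
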