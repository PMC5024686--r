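two_sample_counts <- function(a = c(1, 2, 3), b = c(2, 4, 6)) {
  tibble::tibble(
    barcode = rep(c("b1", "b2", "b3"), 2),
    sample_id = rep(c("A", "B"), each = 3),
    count = c(a, b)
  )
}

test_that("median normalization matches the hand-computed example", {
  n <- median_normalize(two_sample_counts())
  expect_equal(attr(n, "global_median"), 2.5)
  expect_equal(n$norm[n$sample_id == "A"], c(1.25, 2.5, 3.75))
  expect_equal(n$norm[n$sample_id == "B"], c(1.25, 2.5, 3.75))
  # fixed point: columns already sharing the global median are unchanged
  ct <- two_sample_counts(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(median_normalize(ct)$norm, ct$count)
  # zero-median column is a QC error naming the sample
  bad <- two_sample_counts(b = c(0, 0, 5))
  expect_error(median_normalize(bad), "QC error.*B")
})

test_that("every sample column has the same median after normalization", {
  sim <- tiny_screen(n_plasmids = 60, depth = 4000, seed = 37)
  counts <- sim$counts |> dplyr::filter(count > 0)
  n <- median_normalize(counts)
  meds <- n |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(m = stats::median(norm))
  expect_equal(meds$m, rep(meds$m[1], nrow(meds)))
})

test_that("fold changes are neutral on controls by construction", {
  sim <- tiny_screen(n_plasmids = 60, depth = 20000, seed = 41)
  assoc <- truth_association(sim$truth)
  counts <- assemble_and_filter(sim$counts, assoc,
                                samples = sim$design$sample_id)
  fc <- fold_changes(median_normalize(counts), sim$design)
  ctrl <- attr(fc, "controls")
  # mean FC over control columns is 1 per barcode, by construction
  per_bc <- fc |>
    dplyr::filter(sample_id %in% ctrl) |>
    dplyr::group_by(barcode) |>
    dplyr::summarise(m = mean(fc))
  expect_equal(per_bc$m, rep(1, nrow(per_bc)))
  # a barcode with identical depth ratios everywhere has FC 1 everywhere
  flat <- tibble::tibble(barcode = rep(c("x", "y"), each = 2),
                         sample_id = rep(c("A", "B"), 2),
                         count = c(5, 5, 10, 10))
  design <- tibble::tibble(sample_id = c("A", "B"),
                           treatment = c("DMSO", "JASP"), time_h = c(0, 2))
  fc_flat <- fold_changes(median_normalize(flat), design)
  expect_equal(fc_flat$fc, rep(1, 4))
  expect_error(fold_changes(median_normalize(flat),
                            dplyr::mutate(design, time_h = c(2, 2),
                                          treatment = "JASP")),
               "no control samples")
})

test_that("simulated 10x induction lands near FC 10 at the pulse peak", {
  planted <- tibble::tibble(group = "ie", consensus = "CCWWWWWWGG",
                            fraction = 0.05, amplitude = 9, tau_h = 1,
                            treatment = "JASP")
  sim <- tiny_screen(n_plasmids = 300, depth = 1e6, seed = 43,
                     planted = planted, baseline_log10_sd = 0.3)
  assoc <- truth_association(sim$truth)
  counts <- assemble_and_filter(sim$counts, assoc,
                                samples = sim$design$sample_id)
  fc <- fold_changes(median_normalize(counts), sim$design)
  induced <- sim$truth$barcode[sim$truth$group == "ie"]
  peak <- fc |>
    dplyr::filter(barcode %in% induced, treatment == "JASP", time_h == 1)
  expect_true(all(peak$fc > 8 & peak$fc < 12))
})

test_that("drug-response scores reproduce hand arithmetic and rank sensibly", {
  # barcode with drug FC (4,8,8,4) and control FC (1,1,1,1) scores 6
  design <- tibble::tibble(
    sample_id = c(paste0("J", c(1, 2, 4, 8)), paste0("D", c(1, 2, 4, 8))),
    treatment = rep(c("JASP", "DMSO"), each = 4),
    time_h = rep(c(1, 2, 4, 8), 2)
  )
  fc <- tibble::tibble(
    barcode = "b1",
    sample_id = design$sample_id,
    treatment = design$treatment,
    time_h = design$time_h,
    fc = c(4, 8, 8, 4, 1, 1, 1, 1)
  )
  class(fc) <- c("bc_foldchange", class(fc))
  rk <- drug_response_score(fc)
  expect_equal(rk$score, 6)
  expect_equal(rk$rank, 1L)
  expect_error(drug_response_score(fc, drug_times = c(1, 2, 4, 8, 16)),
               "missing time point")
  # uninduced barcodes score near 1; planted near-top ranks
  sim <- tiny_screen(n_plasmids = 200, depth = 5e5, seed = 47)
  assoc <- truth_association(sim$truth)
  counts <- assemble_and_filter(sim$counts, assoc,
                                samples = sim$design$sample_id)
  rk2 <- drug_response_score(fold_changes(median_normalize(counts),
                                          sim$design))
  null_bc <- sim$truth$barcode[sim$truth$group == "none"]
  null_scores <- rk2$score[rk2$barcode %in% null_bc]
  expect_lt(abs(stats::median(null_scores) - 1), 0.05)
  induced <- sim$truth$barcode[sim$truth$group != "none"]
  expect_true(all(rk2$rank[rk2$barcode %in% induced] <=
                    length(induced) + 2))
})

test_that("replicate merge + complete-linkage clustering separates archetypes", {
  planted <- tibble::tibble(
    group = c("immediate_early", "delayed"),
    consensus = c("CCWWWWWWGG", "GGGACTTTCC"),
    fraction = c(0.04, 0.04), amplitude = c(9, 9), tau_h = c(1, 4),
    treatment = "JASP"
  )
  # two biological replicates: one shared library, independent screens
  cfg <- sim_config(n_plasmids = 250, depth = 4e5, error_rate = 0,
                    planted = planted, baseline_log10_sd = 0.4, seed = 53)
  sim <- simulate_library(cfg)
  design <- sample_design(cfg)
  expr <- simulate_expression(sim$truth, cfg, design)
  assoc <- truth_association(sim$truth)
  run_rep <- function(seed) {
    counts <- assemble_and_filter(
      simulate_screen_counts(expr, cfg$depth, seed = seed), assoc,
      samples = design$sample_id)
    fc <- fold_changes(median_normalize(counts), design)
    list(truth = sim$truth, fc = fc, rk = drug_response_score(fc))
  }
  r1 <- run_rep(53)
  r2 <- run_rep(59)
  groups <- merge_replicates_and_cluster(list(r1$rk, r2$rk),
                                         list(r1$fc, r2$fc),
                                         top_k = 20, k_groups = 2)
  g <- tidy(groups)
  truth_grp <- r1$truth$group[match(g$promoter_id, r1$truth$promoter_id)]
  # within-archetype agreement: each cluster is dominated by one archetype
  tab <- table(truth_grp, g$group)
  expect_true(all(apply(tab[c("immediate_early", "delayed"), ], 1,
                        function(x) max(x) / sum(x)) == 1))
  expect_false(which.max(tab["immediate_early", ]) ==
                 which.max(tab["delayed", ]))
  # identical FC vectors cluster together
  expect_error(merge_replicates_and_cluster(r1$rk, r1$fc, top_k = 3,
                                            k_groups = 10),
               "parameter error")
})

test_that("identical profiles always share a cluster", {
  fc <- tidyr::expand_grid(
    barcode = c("a", "b", "c", "d"),
    sample_id = c("J1", "J2", "D1", "D2")
  ) |>
    dplyr::mutate(promoter_id = toupper(barcode),
                  treatment = ifelse(startsWith(sample_id, "J"), "JASP",
                                     "DMSO"),
                  time_h = as.numeric(substr(sample_id, 2, 2)),
                  fc = ifelse(barcode %in% c("a", "b") &
                                treatment == "JASP", 8, 1),
                  log2_fc = log2(fc))
  class(fc) <- c("bc_foldchange", class(fc))
  rk <- drug_response_score(fc, drug_times = c(1, 2))
  groups <- merge_replicates_and_cluster(rk, fc, top_k = 4, k_groups = 2)
  g <- tidy(groups)
  expect_equal(g$group[g$promoter_id == "A"], g$group[g$promoter_id == "B"])
  expect_equal(g$group[g$promoter_id == "C"], g$group[g$promoter_id == "D"])
})

test_that("cv filter reproduces hand-computed coefficients", {
  out <- cv_filter(c(100, 110, 105, 90))
  expect_equal(out$cv, stats::sd(c(100, 110, 105, 90)) / 101.25)
  expect_equal(round(out$cv, 3), 0.084)
  expect_true(out$kept)
  expect_equal(cv_filter(rep(7, 5))$cv, 0)
  expect_true(cv_filter(rep(7, 5))$kept)
  rej <- cv_filter(c(100, 200))
  expect_equal(round(rej$cv, 2), 0.47)
  expect_false(rej$kept)
  expect_error(cv_filter(5), "at least two")
})
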