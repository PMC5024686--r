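test_that("configuration validation catches inconsistent settings", {
  expect_s3_class(sim_config(), "sim_config")
  bad_frac <- default_planted()
  bad_frac$fraction <- c(0.7, 0.4)
  expect_error(sim_config(planted = bad_frac), "fractions sum")
  bad_tau <- default_planted()
  bad_tau$tau_h <- c(0, 1)
  expect_error(sim_config(planted = bad_tau), "tau_h")
  expect_error(sim_config(depth = 0), NULL)
})

test_that("simulated libraries have the configured cardinalities and truth rows", {
  cfg <- sim_config(n_plasmids = 150, seed = 97,
                    duplicate_promoter_fraction = 0.1)
  sim <- simulate_library(cfg)
  expect_equal(nrow(sim$library), 150)
  expect_equal(nrow(sim$truth), 150)
  expect_equal(dplyr::n_distinct(sim$library$barcode), 150)
  expect_true(all(matches_pattern(sim$library$barcode)))
  expect_lt(dplyr::n_distinct(sim$library$promoter_id), 150)
  # determinism: same config + seed gives byte-identical output
  sim2 <- simulate_library(cfg)
  expect_identical(sim$library, sim2$library)
  expect_identical(sim$truth, sim2$truth)
})

test_that("planted consensus sites appear at the recorded offsets", {
  planted <- tibble::tibble(group = "carg", consensus = "CCWWWWWWGG",
                            fraction = 0.1, amplitude = 9, tau_h = 1,
                            treatment = "JASP")
  cfg <- sim_config(n_plasmids = 200, seed = 101, planted = planted,
                    duplicate_promoter_fraction = 0)
  sim <- simulate_library(cfg)
  carg <- sim$truth[sim$truth$group == "carg", ]
  expect_equal(nrow(carg), 20)  # fraction 0.1 of 200 promoters
  # regex count oracle on the whole library
  regex <- "CC[AT][AT][AT][AT][AT][AT]GG"
  n_regex <- sum(vapply(sim$library$cores, function(cs)
    any(grepl(regex, cs)), logical(1)))
  expect_gte(n_regex, 20)
  for (k in seq_len(nrow(carg))) {
    i <- match(carg$library_id[k], sim$library$library_id)
    core <- sim$library$cores[[i]][carg$planted_repeat[k]]
    expect_identical(substr(core, carg$planted_offset[k],
                            carg$planted_offset[k] + 9),
                     carg$planted_site[k])
  }
})

test_that("the induction pulse is neutral at t = 0 and peaks at tau", {
  expect_equal(induction_pulse(0, 9, 1), 1)
  expect_equal(induction_pulse(1, 9, 1), 10)  # FC = 1 + A at the peak
  ts <- seq(0, 10, by = 0.01)
  expect_equal(ts[which.max(induction_pulse(ts, 5, 3))], 3)
  expect_error(induction_pulse(1, 9, 0), "tau")
})

test_that("expected expression follows baselines and planted kinetics", {
  planted <- tibble::tibble(group = c("ie", "del"),
                            consensus = c("CCWWWWWWGG", "GGGACTTTCC"),
                            fraction = c(0.05, 0.05),
                            amplitude = c(9, 9), tau_h = c(1, 3),
                            treatment = "JASP")
  cfg <- sim_config(n_plasmids = 100, seed = 103, planted = planted)
  sim <- simulate_library(cfg)
  expr <- simulate_expression(sim$truth, cfg)
  # non-planted barcodes: identical abundance in every sample
  flat <- expr |>
    dplyr::semi_join(sim$truth[sim$truth$group == "none", "barcode"],
                     by = "barcode") |>
    dplyr::group_by(barcode) |>
    dplyr::summarise(n_vals = dplyr::n_distinct(abundance))
  expect_true(all(flat$n_vals == 1))
  # control columns equal baseline exactly
  ctrl <- expr |> dplyr::filter(treatment == "DMSO" | time_h == 0)
  base <- sim$truth$baseline[match(ctrl$barcode, sim$truth$barcode)]
  expect_equal(ctrl$abundance, base)
  # immediate-early vs delayed: sampled-time argmax follows the pulse whose
  # continuous maximum sits exactly at tau
  times <- c(0, 1, 2, 4, 8)
  for (g in c("ie", "del")) {
    bcs <- sim$truth$barcode[sim$truth$group == g]
    tau <- unique(stats::na.omit(sim$truth$tau_h[sim$truth$group == g]))
    traj <- expr |>
      dplyr::filter(barcode == bcs[1], treatment == "JASP")
    expect_equal(traj$time_h[which.max(traj$expected_fc)],
                 times[which.max(induction_pulse(times, 9, tau))])
  }
  expect_equal(times[which.max(induction_pulse(times, 9, 1))], 1)
})

test_that("multinomial counts conserve depth and track expectations", {
  sim <- tiny_screen(n_plasmids = 100, depth = 1e5, seed = 107)
  per_sample <- sim$counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(n = sum(count))
  expect_true(all(per_sample$n == 1e5))
  # per-barcode deviations within 4 SE for almost all barcodes
  expect_freq <- sim$expression |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(p = abundance / sum(abundance)) |>
    dplyr::ungroup()
  joined <- dplyr::inner_join(sim$counts, expect_freq,
                              by = c("barcode", "sample_id"))
  se <- sqrt(1e5 * joined$p * (1 - joined$p))
  frac_ok <- mean(abs(joined$count - 1e5 * joined$p) <= 4 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("screen reads follow the fixed layout and zero-error identity", {
  sim <- tiny_screen(n_plasmids = 40, depth = 3000, error_rate = 0,
                     seed = 109)
  reads <- simulate_screen_reads(sim$counts, sim$design, sim$cfg)
  expect_equal(sum(sim$counts$count), length(reads))
  expect_true(all(nchar(reads) == 100))
  # layout: index, constant spacer, barcode, XbaI anchor
  r1 <- unname(reads[1])
  s1 <- names(reads)[1]
  expect_identical(substr(r1, 1, 6),
                   sim$design$index[sim$design$sample_id == s1])
  expect_identical(substr(r1, 47, 52), "TCTAGA")
  expect_true(substr(r1, 27, 46) %in% sim$library$barcode)
  # determinism
  reads2 <- simulate_screen_reads(sim$counts, sim$design, sim$cfg)
  expect_identical(reads, reads2)
})

test_that("sequencing errors hit roughly the configured fraction of reads", {
  sim <- tiny_screen(n_plasmids = 40, depth = 4000, error_rate = 0,
                     seed = 113)
  cfg_err <- sim$cfg
  cfg_err$error_rate <- 0.01
  clean <- simulate_screen_reads(sim$counts, sim$design, sim$cfg)
  noisy <- simulate_screen_reads(sim$counts, sim$design, cfg_err)
  frac_changed <- mean(clean != noisy)
  # P(read has >= 1 substitution) = 1 - 0.99^100 ~ 0.634
  expect_gt(frac_changed, 0.55)
  expect_lt(frac_changed, 0.72)
  # binomial survival of the critical positions: a read is assigned and
  # whitelisted iff the XbaI anchor (6 nt) and barcode (20 nt) are clean and
  # the index (6 nt) has at most one substitution
  reads <- unname(noisy)
  sample_id <- demultiplex(reads, sim$design, max_mismatch = 1)
  bc <- trim_barcode_window(clip_reporter_tail(reads))
  counted <- count_barcodes(bc, sample_id, whitelist = sim$truth$barcode)
  frac_whitelisted <- sum(counted$count) / length(reads)
  e <- 0.01
  analytic <- (1 - e)^26 * ((1 - e)^6 + 6 * e * (1 - e)^5)
  expect_lt(abs(frac_whitelisted - analytic), 0.03)
  # at the default error rate 0.001 survival exceeds 95%
  cfg_lo <- sim$cfg
  cfg_lo$error_rate <- 0.001
  lo <- unname(simulate_screen_reads(sim$counts, sim$design, cfg_lo))
  bc_lo <- trim_barcode_window(clip_reporter_tail(lo))
  counted_lo <- count_barcodes(bc_lo, demultiplex(lo, sim$design, 1),
                               whitelist = sim$truth$barcode)
  expect_gte(sum(counted_lo$count) / length(lo), 0.95)
})

test_that("association reads have template-determined lengths", {
  cfg <- sim_config(n_plasmids = 10, seed = 127, error_rate = 0)
  sim <- simulate_library(cfg)
  jr <- simulate_association_reads(sim$library, "junction", coverage = 3,
                                   seed = 1)
  expect_true(all(nchar(jr) == 150))
  lr <- simulate_association_reads(sim$library, "long", coverage = 1,
                                   seed = 2)
  expect_true(all(nchar(lr) == 2275))  # NheI-XbaI fragment length
  expect_error(simulate_association_reads(sim$library, "weird"), "arg")
})
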