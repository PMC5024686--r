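make_construct <- function(seed = 1) {
  p <- generate_promoter_insert(6, seed = seed)
  bc <- bcstarprom:::draw_clean_barcodes(BARCODE_PATTERN, 1)
  list(promoter = p, barcode = bc, construct = assemble_construct(p, bc))
}

test_that("in-silico digestion cuts at every site and keeps coordinates", {
  x <- make_construct(1)
  sites <- restriction_sites()
  frags <- insilico_digest(x$construct$sequence, sites[c("NheI", "XbaI")])
  expect_equal(nrow(frags), 3)  # 2 cut points
  mid <- frags$seq[startsWith(frags$seq, sites$NheI)]
  expect_length(mid, 1)
  expect_true(grepl(x$promoter$promoter_seq, mid, fixed = TRUE))
  expect_true(endsWith(mid, x$barcode))
  # substring-position oracle
  expect_equal(frags$start[2],
               regexpr(sites$NheI, x$construct$sequence, fixed = TRUE)[1] - 1)
  # content conservation
  expect_identical(paste0(frags$seq, collapse = ""), x$construct$sequence)
  none <- insilico_digest("ACGTACGT", list(XbaI = "TCTAGA"))
  expect_equal(nrow(none), 1)
  expect_identical(none$seq, "ACGTACGT")
  # palindromic site present on either strand is found on the forward scan
  s <- paste0("AAAA", "GCTAGC", "AAAA")
  expect_equal(nrow(insilico_digest(s, list(NheI = "GCTAGC"))), 2)
  expect_equal(nrow(insilico_digest(bcstarprom::reverse_complement(s),
                                    list(NheI = "GCTAGC"))), 2)
  expect_error(insilico_digest("", list(NheI = "GCTAGC")), "empty")
})

test_that("circularization preserves length and forbids double circularization", {
  f <- bcstarprom:::new_fragment("ACGTACGTAA")
  circ <- circularize_fragment(f)
  expect_equal(nchar(circ$seq), nchar(f$seq))
  expect_identical(circ$kind, "circular")
  expect_error(circularize_fragment(circ), "state error")
  # junction window = suffix + prefix of the linear input (rotation oracle)
  win <- paste0(substr(f$seq, 7, 10), substr(f$seq, 1, 4))
  doubled <- paste0(circ$seq, circ$seq)
  expect_true(grepl(win, doubled, fixed = TRUE))
})

test_that("relinearization opens circles at enzyme sites and pools aliquots", {
  x <- make_construct(2)
  sites <- restriction_sites()
  frag <- insilico_digest(x$construct$sequence, sites[c("NheI", "XbaI")])
  frag <- frag$seq[startsWith(frag$seq, sites$NheI)]
  circ <- circularize_fragment(bcstarprom:::new_fragment(frag))
  pool <- linearize_circle(circ, sites[c("ApaI", "FspI", "HincII")])
  expect_equal(sort(unique(pool$enzyme)), c("ApaI", "FspI", "HincII"))
  expect_true(all(nchar(pool$seq) > 0))
  # conservation per aliquot: each enzyme's fragments tile the whole circle
  for (e in unique(pool$enzyme)) {
    expect_equal(sum(nchar(pool$seq[pool$enzyme == e])), nchar(frag))
  }
  # every aliquot here has one site, so each keeps the junction intact
  junction <- paste0(substr(frag, nchar(frag) - 45, nchar(frag)),
                     substr(frag, 1, 104))
  expect_true(all(vapply(pool$seq, grepl, logical(1), pattern = junction,
                         fixed = TRUE, USE.NAMES = FALSE)))
  expect_error(linearize_circle(circ, list()), "empty")
  expect_warning(no_cut <- linearize_circle(
    circularize_fragment(bcstarprom:::new_fragment("ACGTACGT")),
    list(ApaI = "GGGCCC")), "no enzyme site")
  expect_equal(nrow(no_cut), 0)
})

test_that("junction reads parse to the true barcode and first core", {
  sim <- simulate_library(sim_config(n_plasmids = 20, seed = 3,
                                     error_rate = 0))
  reads <- simulate_association_reads(sim$library, "junction", coverage = 2,
                                      error_rate = 0, seed = 4)
  parsed <- parse_junction_read(reads)
  expect_true(all(parsed$status == "ok"))
  idx <- match(parsed$barcode, sim$library$barcode)
  expect_false(anyNA(idx))
  expect_identical(parsed$core1, sim$library$core1[idx])
  # random DNA does not parse
  set.seed(5)
  junk <- vapply(1:5, function(i)
    paste0(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
    character(1))
  expect_true(all(parse_junction_read(junk)$status == "unparsed"))
  # one substitution inside the barcode + whitelist: off-whitelist, unparsed
  r <- reads[1]
  bc_pos <- 27  # barcode occupies read positions 27-46 in junction reads
  substr(r, bc_pos, bc_pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(r, bc_pos, bc_pos))[1]
  out <- parse_junction_read(r, whitelist = sim$library$barcode)
  expect_identical(out$status, "unparsed")
})

test_that("long reads parse all cores and retry the reverse strand", {
  sim <- simulate_library(sim_config(n_plasmids = 8, seed = 6,
                                     error_rate = 0))
  reads <- simulate_association_reads(sim$library, "long", coverage = 1,
                                      error_rate = 0, seed = 7)
  parsed <- parse_long_read(reads)
  expect_true(all(parsed$status == "ok"))
  idx <- match(parsed$barcode, sim$library$barcode)
  for (k in seq_along(reads)) {
    expect_identical(parsed$cores[[k]], sim$library$cores[[idx[k]]])
  }
  # strand-retry property: parse(rc(r)) parses iff parse(r) parses
  rc <- bcstarprom::reverse_complement(reads[1:3])
  expect_true(all(parse_long_read(rc)$status == "ok"))
  expect_identical(parse_long_read("ACGT")$status, "unparsed")
  # a read missing the barcode region is unparsed
  trunc <- substr(reads[1], 1, 6 + 6 * 84)
  expect_identical(parse_long_read(trunc)$status, "unparsed")
})

test_that("association table applies the support threshold and uniqueness policy", {
  pairs <- tibble::tibble(
    barcode = c(rep("X", 60), rep("Y", 10)),
    promoter_id = c(rep("P1", 60), rep("P2", 10))
  )
  tab <- build_association_table(pairs, min_reads = 50)
  expect_equal(nrow(tab), 1)
  expect_identical(tab$barcode, "X")
  expect_equal(tab$read_support, 60)
  # exactly-at-threshold support is NOT retained (strict > 50)
  at50 <- tibble::tibble(barcode = rep("Z", 50), promoter_id = "P1")
  expect_equal(nrow(build_association_table(at50, min_reads = 50)), 0)
  empty <- build_association_table(tibble::tibble(barcode = character(0),
                                                  promoter_id = character(0)))
  expect_equal(nrow(empty), 0)
  # conflicting barcode above threshold for two promoters: dropped + reported
  conf <- tibble::tibble(
    barcode = rep("Z", 115),
    promoter_id = c(rep("P1", 60), rep("P2", 55))
  )
  tab2 <- build_association_table(conf, min_reads = 50)
  expect_equal(nrow(tab2), 0)
  expect_equal(sort(unique(attr(tab2, "conflicts")$promoter_id)),
               c("P1", "P2"))
})

test_that("validation reports collisions and multi-barcode promoters", {
  tab <- tibble::tibble(barcode = c("A", "B", "C"),
                        promoter_id = c("P1", "P1", "P1"),
                        read_support = c(60, 70, 80))
  v <- validate_association(tab)
  expect_length(v$collisions, 0)
  expect_identical(v$multi_barcode_promoters, "P1")
  bad <- tibble::tibble(barcode = c("A", "A"), promoter_id = c("P1", "P2"),
                        read_support = c(60, 60))
  expect_identical(validate_association(bad)$collisions, "A")
  v0 <- validate_association(tab[0, ])
  expect_length(v0$collisions, 0)
  expect_length(v0$multi_barcode_promoters, 0)
})

test_that("zero-error junction sequencing recovers the truth table exactly", {
  cfg <- sim_config(n_plasmids = 100, seed = 8, error_rate = 0,
                    duplicate_promoter_fraction = 0.05)
  sim <- simulate_library(cfg)
  reads <- simulate_association_reads(sim$library, "junction", coverage = 60,
                                      error_rate = 0, seed = 9)
  assoc <- associate_junction_reads(reads, sim$library, min_reads = 50)
  truth <- dplyr::distinct(sim$truth[, c("barcode", "promoter_id")]) |>
    dplyr::arrange(barcode)
  expect_identical(tibble::tibble(barcode = assoc$barcode,
                                  promoter_id = assoc$promoter_id), truth)
  v <- validate_association(assoc)
  expect_length(v$collisions, 0)
  expect_gt(length(v$multi_barcode_promoters), 0)  # duplicated promoters
})
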