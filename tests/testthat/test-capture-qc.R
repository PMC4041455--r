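toy_probes <- function() {
  tibble::tibble(
    probe_id = c("pA", "pB", "pC"),
    chrom = "chr1",
    anchor_start = c(1000L, 3000L, 5000L),
    anchor_end = c(1040L, 3040L, 5040L),
    strand = c("+", "-", "+"),
    target_seq_40 = c(
      random_genome_chr(40, 101), random_genome_chr(40, 102),
      random_genome_chr(40, 103)
    )
  )
}

test_that("demultiplexing conserves pairs and respects the mismatch budget", {
  tbl <- tibble::tibble(
    sample_id = c("s1", "s2"), tag = c("ACGTACG", "TTTTTTT")
  )
  pairs <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    tag = c("ACGTACG", "ACGTACT", "GGGGGGG", NA)
  )
  d0 <- demultiplex(pairs, tbl, max_mismatch = 0)
  expect_equal(d0$sample, c("s1", "unassigned", "unassigned", "unassigned"))
  d1 <- demultiplex(pairs, tbl, max_mismatch = 1)
  expect_equal(d1$sample, c("s1", "s1", "unassigned", "unassigned"))
  expect_equal(nrow(d1), nrow(pairs)) # conservation

  expect_error(
    demultiplex(pairs, tibble::tibble(
      sample_id = c("a", "b"), tag = c("ACGTACG", "ACGTACT")
    ), max_mismatch = 1),
    "ambiguous"
  )
  expect_error(
    demultiplex(pairs, tibble::tibble(sample_id = "a", tag = "ACGT")),
    "7 bases"
  )
})

test_that("probe assignment matches the Read 2 prefix within tolerance", {
  probes <- toy_probes()
  exact <- paste0(probes$target_seq_40[2], "ACGTACGT")
  one_mm <- probes$target_seq_40[1]
  substr(one_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(one_mm, 5, 5))[1]
  nothing <- strrep("A", 40)
  got <- assign_probe(c(exact, one_mm, nothing), probes)
  expect_equal(got, c("pB", "pA", NA))
  # zero tolerance rejects the mismatched prefix
  expect_equal(
    assign_probe(one_mm, probes, max_mismatch = 0), NA_character_
  )
  # a tie between two probes is unassigned
  twins <- dplyr::mutate(probes, target_seq_40 = target_seq_40[1])
  expect_true(is.na(assign_probe(probes$target_seq_40[1], twins)))
  expect_error(assign_probe("ACGT", probes), "shorter")
  expect_error(assign_probe(exact, probes[0, ]), "empty")
})

test_that("on/off-target classification applies the distance rules", {
  probes <- toy_probes() # pA: + strand, anchor 1000-1040
  aln <- function(start, end, strand = "-", chrom = "chr1", probe = "pA") {
    tibble::tibble(
      read_id = "r", probe_id = probe, chrom = chrom,
      start = start, end = end, strand = strand
    )
  }
  # 60 bases downstream of the anchor: on target
  r <- classify_on_target(aln(1100L, 1180L), probes)
  expect_equal(r$status, "ON_TARGET")
  expect_equal(r$distance, 60L)
  # 1660 bases: beyond even the insert rule
  r <- classify_on_target(aln(2700L, 2780L), probes)
  expect_equal(r$status, "OFF_TARGET")
  expect_equal(r$reason, "DISTANCE_EXCEEDED")
  expect_false(r$gray)
  # 1200 bases: gray zone, still off target under the 1 kb convention
  r <- classify_on_target(aln(2240L, 2320L), probes)
  expect_equal(r$reason, "DISTANCE_EXCEEDED")
  expect_true(r$gray)
  # other chromosome
  r <- classify_on_target(aln(1100L, 1180L, chrom = "chr2"), probes)
  expect_equal(r$reason, "WRONG_CHROM")
  # unexpected strand
  r <- classify_on_target(aln(1100L, 1180L, strand = "+"), probes)
  expect_equal(r$reason, "WRONG_ORIENTATION")
  # read on the anti-extension side of the probe
  r <- classify_on_target(aln(700L, 780L), probes)
  expect_equal(r$reason, "WRONG_ORIENTATION")
  # minus-strand probe pB measures distance on the other side
  r <- classify_on_target(aln(2900L, 2960L, strand = "+", probe = "pB"), probes)
  expect_equal(r$status, "ON_TARGET")
  expect_equal(r$distance, 40L)
  expect_error(
    classify_on_target(aln(1L, 10L, probe = NA_character_), probes),
    "probe-assigned"
  )
})

test_that("per-probe yield, capture rate and uniformity follow definitions", {
  probes <- toy_probes()
  cl <- tibble::tibble(
    probe_id = c(rep("pA", 5), rep("pC", 2), "pC"),
    status = c(rep("ON_TARGET", 7), "OFF_TARGET"),
    gray = FALSE
  )
  y <- per_probe_yield(cl, probes)
  expect_equal(y$n_on[match(c("pA", "pB", "pC"), y$probe_id)], c(5L, 0L, 2L))
  expect_equal(attr(y, "capture_rate"), 2 / 3)
  g <- glance(y)
  expect_equal(g$capture_rate, 2 / 3)
  expect_equal(g$n_on, 7L)

  # empty classification: all-zero table
  y0 <- per_probe_yield(cl[0, ], probes)
  expect_true(all(y0$n_on == 0L))
  expect_equal(attr(y0, "capture_rate"), 0)

  expect_equal(uniformity_1log(c(rep(100, 9), 1)), 0.9)
  expect_equal(uniformity_1log(c(1, 100, 10000)), 1 / 3)
  expect_equal(uniformity_1log(rep(7, 12)), 1)
  expect_error(uniformity_1log(numeric()), "at least one")
})

test_that("uniformity is invariant under rescaling yields", {
  set.seed(99)
  for (i in 1:100) {
    y <- rpois(50, lambda = sample(c(2, 20, 200), 1))
    s <- runif(1, 0.01, 100)
    expect_equal(uniformity_1log(y), uniformity_1log(y * s))
  }
})

test_that("ROI coverage equals a naive pileup and excludes probe overlap", {
  probes <- toy_probes()[1, ] # single + probe at 1000-1040
  # ten 60 b reads tiling the ROI
  alns <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    probe_id = "pA",
    chrom = "chr1",
    start = seq(1040L, 1139L, by = 11L),
    end = seq(1040L, 1139L, by = 11L) + 60L,
    strand = "-"
  )
  rc <- roi_coverage(alns, probes, flank = 50L)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$start, 950L)
  expect_equal(rc$end, 1090L)
  depth <- oracle_pileup(alns, "chr1", 950L, 1090L)
  expect_equal(rc$mean_cov, mean(depth))
  expect_equal(rc$frac_ge_1, mean(depth >= 1))
  expect_equal(rc$frac_ge_10, mean(depth >= 10))

  # a read overlapping its own probe footprint contributes nothing
  overlap <- tibble::tibble(
    read_id = "ov", probe_id = "pA", chrom = "chr1",
    start = 1030L, end = 1090L, strand = "-"
  )
  rc_ov <- roi_coverage(overlap, probes, flank = 50L)
  expect_equal(rc_ov$mean_cov, 0)

  # no reads at all
  rc0 <- roi_coverage(alns[0, ], probes, flank = 50L)
  expect_equal(rc0$mean_cov, 0)
  expect_equal(rc0$frac_ge_1, 0)
})

test_that("the fixed-threshold caller applies depth, frequency and quality", {
  sites <- tibble::tibble(
    depth = c(100L, 8L, 100L, 100L, 40L),
    alt_count = c(20L, 4L, 10L, 20L, 8L),
    mean_qual = c(30, 30, 30, 20, 30)
  )
  calls <- naive_af_call(sites)
  expect_equal(calls$af, c(0.20, 0.50, 0.10, 0.20, 0.20))
  # depth 8 fails min-coverage; AF 0.10 fails min-var-freq; qual 20 fails
  expect_equal(calls$called, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # lowering min_var_freq admits the 10% site
  calls2 <- naive_af_call(sites, min_var_freq = 0.05)
  expect_true(calls2$called[3])
  expect_error(
    naive_af_call(tibble::tibble(depth = 5L, alt_count = 9L, mean_qual = 30)),
    "alt_count"
  )
})

test_that("simulated capture flows through the QC chain conservatively", {
  g <- simulate_genome(8000, seed = 31)$genome
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  d <- design_targets(
    tibble::tibble(
      chrom = "chr1", start = c(2000L, 5000L), end = c(2500L, 5500L),
      target_class = "LOCUS", label = c("tA", "tB")
    ),
    g, track
  )
  cfg <- sim_config(seed = 7, n_fragments = 20000, efficiency = 0.2)
  reads <- simulate_capture(
    list(list(name = "ref", genome = g, weight = 1)), d$probes, cfg,
    tag = "ACGTACG"
  )
  expect_gt(nrow(reads), 200)

  dm <- demultiplex(reads, tibble::tibble(sample_id = "s1", tag = "ACGTACG"))
  expect_true(all(dm$sample == "s1"))

  pid <- assign_probe(reads$read2_seq, d$probes)
  # error rate 1e-3 on a 20 b prefix: nearly all reads assigned correctly
  expect_gt(mean(pid == reads$probe_id, na.rm = TRUE), 0.999)
  aln <- reads_to_alignments(reads)
  aln$probe_id <- pid
  aln <- aln[!is.na(aln$probe_id), ]
  cl <- classify_on_target(aln, d$probes)
  # conservation: every assigned read is classified exactly once
  expect_equal(nrow(cl), nrow(aln))
  expect_true(all(cl$status %in% c("ON_TARGET", "OFF_TARGET")))
  expect_gt(mean(cl$status == "ON_TARGET"), 0.95)
  y <- per_probe_yield(cl, d$probes)
  expect_equal(attr(y, "n_assigned"), nrow(aln))
  expect_equal(sum(y$n_on), sum(cl$status == "ON_TARGET"))
})
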