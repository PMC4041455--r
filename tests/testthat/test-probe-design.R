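make_design_fixture <- function(seed = 1, len = 5000) {
  g <- simulate_genome(len, seed = seed)$genome
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  list(genome = g, track = track)
}

test_that("gc_content is (#G + #C) / length and rejects bad input", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  forty <- paste0(strrep("G", 11), strrep("A", 29))
  expect_equal(gc_content(forty), 0.275)
  p <- design_params()
  expect_true(gc_content(forty) < p$gc_min) # fails the 30-65% gate
  expect_error(gc_content("ACGN"), "ACGT")
  expect_error(gc_content(""), "ACGT")
})

test_that("oligo assembly yields a 101-mer with the 40-mer up front", {
  seg <- universal_segments()
  expect_equal(nchar(seg$universal_mid), 37L)
  expect_equal(nchar(seg$p7_complement), 24L)
  oligo <- assemble_oligo(strrep("T", 40))
  expect_equal(nchar(oligo), 101L)
  expect_equal(substr(oligo, 1, 40), strrep("T", 40))
  expect_error(assemble_oligo(strrep("T", 39)), "40 bases")
  expect_error(assemble_oligo(strrep("T", 40), "ACGT", "ACGT"), "61 bases")
})

test_that("candidate filters report every violated rule", {
  fx <- make_design_fixture(3)
  g <- fx$genome

  clean <- tibble::tibble(chrom = "chr1", anchor_start = 1000L, strand = "+")
  dec <- candidate_passes_filters(clean, g, fx$track)
  expect_true(dec$pass)
  expect_length(dec$failures[[1]], 0L)
  expect_equal(dec$target_seq_40, unname(substr(g, 1001, 1040)))

  # SNP 3 bases from the extension end violates the terminal-10 rule
  snp_plus <- tibble::tibble(chrom = "chr1", pos = 1037L)
  dec <- candidate_passes_filters(clean, g, fx$track, snps = snp_plus)
  expect_false(dec$pass)
  expect_true("SNP_IN_TERMINAL_10" %in% dec$failures[[1]])
  # same offset on the other side only matters for a minus-strand probe
  minus <- mutate(clean, strand = "-")
  dec_m <- candidate_passes_filters(minus, g, fx$track, snps = snp_plus)
  expect_false("SNP_IN_TERMINAL_10" %in% dec_m$failures[[1]])
  snp_minus <- tibble::tibble(chrom = "chr1", pos = 1003L)
  dec_m2 <- candidate_passes_filters(minus, g, fx$track, snps = snp_minus)
  expect_true("SNP_IN_TERMINAL_10" %in% dec_m2$failures[[1]])

  # minus-strand 40-mer is the reverse complement of the anchor
  expect_equal(dec_m$target_seq_40, revcomp(substr(g, 1001, 1040)))

  # repetitive terminal k-mer
  rep_g <- c(chr1 = paste0(substr(g, 1, 2000), strrep("AT", 150), substr(g, 2001, 5000)))
  rep_track <- classify_positions(rep_g, k = 20, margin_mismatches = 1)
  in_rep <- tibble::tibble(chrom = "chr1", anchor_start = 2100L, strand = "+")
  dec_r <- candidate_passes_filters(in_rep, rep_g, rep_track)
  expect_true("KMER_NOT_UNIQUE" %in% dec_r$failures[[1]])
  # clean anchor whose extension side touches the repeat tract
  adj <- tibble::tibble(chrom = "chr1", anchor_start = 1955L, strand = "+")
  dec_a <- candidate_passes_filters(adj, rep_g, rep_track)
  expect_true("REPEAT_ADJACENT" %in% dec_a$failures[[1]])

  # N in the anchor
  n_g <- g
  substr(n_g, 1020, 1020) <- "N"
  n_track <- classify_positions(n_g, k = 20, margin_mismatches = 1)
  dec_n <- candidate_passes_filters(clean, n_g, n_track)
  expect_true("CONTAINS_N" %in% dec_n$failures[[1]])

  expect_error(
    candidate_passes_filters(
      tibble::tibble(chrom = "chr1", anchor_start = 4990L, strand = "+"),
      g, fx$track
    ),
    "outside"
  )
})

test_that("interval design emits passing probes on both strands", {
  fx <- make_design_fixture(5)
  target <- tibble::tibble(
    chrom = "chr1", start = 2000L, end = 2400L, label = "t1"
  )
  d <- design_for_interval(target, fx$genome, fx$track)
  expect_gte(sum(d$probes$strand == "+"), 2L)
  expect_gte(sum(d$probes$strand == "-"), 2L)
  expect_equal(nrow(d$gaps), 0L)
  # soundness: every emitted probe re-passes the filters
  dec <- candidate_passes_filters(
    d$probes |> select(chrom, anchor_start, strand),
    fx$genome, fx$track
  )
  expect_true(all(dec$pass))
  # strand balance
  expect_lte(abs(sum(d$probes$strand == "+") - sum(d$probes$strand == "-")), 1L)
  # anchors are 40 wide, oligos 101, and flanks sit 100-200 b out
  expect_true(all(d$probes$anchor_end - d$probes$anchor_start == 40L))
  expect_true(all(nchar(d$probes$oligo_101) == 101L))
  up <- d$probes[d$probes$slot == "flank_up", ]
  expect_true(2000 - up$anchor_end >= 100 && 2000 - up$anchor_end <= 200)
  dn <- d$probes[d$probes$slot == "flank_dn", ]
  expect_true(dn$anchor_start - 2400 >= 100 && dn$anchor_start - 2400 <= 200)
})

test_that("tiling keeps per-strand spacing near the nominal 200 bases", {
  g <- simulate_genome(3000, seed = 8)$genome
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  target <- tibble::tibble(
    chrom = "chr1", start = 900L, end = 1900L, label = "big"
  )
  d <- design_for_interval(target, g, track)
  tiles <- d$probes[grepl("tile", d$probes$slot), ]
  for (s in c("+", "-")) {
    a <- sort(tiles$anchor_start[tiles$strand == s])
    gaps <- diff(a)
    expect_true(all(gaps >= 140 & gaps <= 260), info = paste("strand", s))
  }
})

test_that("design records gaps instead of failing when windows are blocked", {
  # upstream flank window fully homopolymer: no passing candidate there
  g <- c(chr1 = paste0(
    strrep("A", 300), random_genome_chr(2700, 21)
  ))
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  target <- tibble::tibble(
    chrom = "chr1", start = 360L, end = 460L, label = "edge"
  )
  d <- design_for_interval(target, g, track)
  gap_up <- d$gaps[d$gaps$slot == "flank_up", ]
  expect_equal(nrow(gap_up), 1L)
  expect_equal(gap_up$reason, "NO_PASSING_CANDIDATE")
  # brute force confirms: no anchor in the window passes
  slots <- placement_slots(
    mutate(target, target_class = "LOCUS"), nchar(g), design_params()
  )
  w <- slots[slots$slot == "flank_up", ]
  cand <- tibble::tibble(
    chrom = "chr1", anchor_start = seq.int(w$lo, w$hi), strand = "+"
  )
  expect_false(any(candidate_passes_filters(cand, g, track)$pass))
})

test_that("SNP design places an opposing pair reading across the site", {
  fx <- make_design_fixture(9)
  d <- design_for_snp(2500L, "chr1", fx$genome, fx$track)
  expect_equal(nrow(d$probes), 2L)
  expect_setequal(d$probes$strand, c("+", "-"))
  up <- d$probes[d$probes$strand == "+", ]
  dn <- d$probes[d$probes$strand == "-", ]
  expect_true(2500 - up$anchor_end >= 100 && 2500 - up$anchor_end <= 200)
  expect_true(dn$anchor_start - 2501 >= 100 && dn$anchor_start - 2501 <= 200)
  # anchors never cover the SNP, so it cannot sit in any terminal bases
  expect_true(all(up$anchor_end <= 2500, dn$anchor_start >= 2501))

  # a SNP 30 bases from the contig end loses its downstream probe
  near_end <- nchar(fx$genome) - 30L
  d2 <- design_for_snp(near_end, "chr1", fx$genome, fx$track)
  expect_equal(nrow(d2$probes), 1L)
  expect_equal(nrow(d2$gaps), 1L)
  expect_equal(d2$gaps$reason, "OUTSIDE_GENOME")

  # a SNP deep inside a repeat tract gets no probes at all
  g <- c(chr1 = paste0(
    random_genome_chr(1000, 31), strrep("AT", 400), random_genome_chr(1000, 32)
  ))
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  d3 <- design_for_snp(1400L, "chr1", g, track)
  expect_equal(nrow(d3$probes), 0L)
  expect_equal(nrow(d3$gaps), 2L)
})

test_that("breakpoint design flanks the junction on opposing strands", {
  fx <- make_design_fixture(12, len = 4000)
  sv <- tibble::tibble(
    chrom1 = "chr1", pos1 = 1500L, chrom2 = "chr1", pos2 = 3000L,
    label = "sv1"
  )
  d <- design_for_breakpoint(sv, fx$genome, fx$track)
  expect_equal(nrow(d$probes), 8L) # 4 per breakpoint
  expect_true(all(d$probes$locus == "sv1"))
  for (bp_pos in c(1500, 3000)) {
    bp_label <- if (bp_pos == 1500) "bp1" else "bp2"
    probes <- d$probes[grepl(bp_label, d$probes$probe_id), ]
    expect_setequal(unique(probes$strand), c("+", "-"))
    dist <- ifelse(probes$strand == "+",
      bp_pos - probes$anchor_end, probes$anchor_start - bp_pos
    )
    expect_true(all(dist >= 150 & dist <= 300))
  }

  # a junction 100 b from the contig end cannot host its left-side probes
  sv_edge <- tibble::tibble(
    chrom1 = "chr1", pos1 = 100L, chrom2 = "chr1", pos2 = 2000L,
    label = "sv_edge"
  )
  d2 <- design_for_breakpoint(sv_edge, fx$genome, fx$track)
  bp1 <- d2$probes[grepl("bp1", d2$probes$probe_id), ]
  expect_true(all(bp1$strand == "-"))
  expect_gte(nrow(d2$gaps), 2L)

  # repeats on one side suppress that side's probes
  g <- c(chr1 = paste0(
    random_genome_chr(1200, 41), strrep("TA", 300), random_genome_chr(1200, 42)
  ))
  track <- classify_positions(g, k = 20, margin_mismatches = 1)
  sv_rep <- tibble::tibble(
    chrom1 = "chr1", pos1 = 1800L, chrom2 = "chr1", pos2 = 2200L,
    label = "sv_rep"
  )
  d3 <- design_for_breakpoint(sv_rep, g, track)
  bp1 <- d3$probes[grepl("bp1", d3$probes$probe_id), ]
  # left flank of pos1 = 1800 is the repeat tract: plus-strand slots gap out
  expect_false(any(bp1$strand == "+"))
})

test_that("probe density is probes per kilobase of target", {
  probes <- tibble::tibble(probe_id = sprintf("p%d", 1:10))
  targets <- tibble::tibble(start = 0L, end = 1000L)
  expect_equal(probe_density(probes, targets), 10)
  expect_equal(probe_density(probes[0, ], targets), 0)
  expect_error(probe_density(probes, targets[0, ]), "non-empty")
})

test_that("design is deterministic and catalogs round-trip through TSV", {
  fx <- make_design_fixture(15)
  target <- tibble::tibble(
    chrom = "chr1", start = 1500L, end = 2600L, label = "t"
  )
  d1 <- design_for_interval(target, fx$genome, fx$track)
  d2 <- design_for_interval(target, fx$genome, fx$track)
  expect_identical(d1$probes, d2$probes)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_catalog(d1, path)
  back <- read_probe_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(d1$probes))

  expect_equal(nrow(tidy(d1)), nrow(d1$probes))
  g <- glance(d1)
  expect_equal(g$n_probes, nrow(d1$probes))
})
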