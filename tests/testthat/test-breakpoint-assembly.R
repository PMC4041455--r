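test_that("SV candidate filters reproduce the support and plausibility rules", {
  cand <- tibble::tibble(
    chrom1 = c("chr2", "chr2", "chr2", "chrY", "chr3"),
    pos1 = c(1e4, 2e4, 3e4, 4e4, 5e4),
    chrom2 = c("chr2", "chr2", "chr2", "chrY", "chr3"),
    pos2 = c(1.5e4, 2.5e4, 3.5e4, 4.5e4, 5.5e4),
    type = "DEL",
    support_tumor1 = c(25L, 12L, 12L, 30L, 40L),
    support_tumor2 = c(0L, 0L, 12L, 30L, 40L),
    in_normal = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    label = c("keep25", "drop12", "keep_shared", "dropY", "drop_germ")
  )
  kept <- filter_sv_candidates(cand, sex = "female")
  expect_setequal(kept$label, c("keep25", "keep_shared"))
  ann <- filter_sv_candidates(cand, sex = "female", annotate = TRUE)
  expect_equal(
    ann$drop_reason[match(
      c("drop12", "dropY", "drop_germ"), ann$label
    )],
    c("INSUFFICIENT_SUPPORT", "SEX_IMPLAUSIBLE", "GERMLINE")
  )
  # a male subject may carry Y events
  kept_m <- filter_sv_candidates(cand, sex = "male")
  expect_true("dropY" %in% kept_m$label)
  # repeat-masked anchors are excluded
  mask <- tibble::tibble(chrom = "chr2", start = 9990L, end = 10050L)
  kept_rm <- filter_sv_candidates(cand, sex = "female", repeat_mask = mask)
  expect_false("keep25" %in% kept_rm$label)
  # short anchors are excluded
  cand$anchor1_len <- c(10L, rep(25L, 4))
  expect_false("keep25" %in% filter_sv_candidates(cand, sex = "female")$label)
})

test_that("locus grouping partitions reads and conserves counts", {
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    probe_id = c("p1", "p1", "p2", "p3", NA, "p9"),
    read1_seq = strrep("A", 30)
  )
  map <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), locus_id = c("L1", "L1", "L2")
  )
  g <- build_locus_groups(reads, map)
  expect_equal(nrow(g), 4L) # NA probe and unmapped probe dropped
  expect_equal(sum(g$locus_id == "L1"), 3L)
  expect_equal(sum(g$locus_id == "L2"), 1L)
  # probes-with-locus-column form also accepted
  probes <- tibble::tibble(probe_id = c("p1", "p2", "p3"), locus = c("a", "a", "b"))
  g2 <- build_locus_groups(reads, probes)
  expect_equal(sum(g2$locus_id == "a"), 3L)
})

test_that("assembly read filtering applies quality, primer and reference gates", {
  ref <- c(chr1 = random_genome_chr(3000, 51))
  q35 <- function(n) strrep(rawToChar(as.raw(35 + 33)), n)
  q20 <- function(n) strrep(rawToChar(as.raw(20 + 33)), n)
  ref_read <- substr(ref, 501, 580)
  err_read <- ref_read
  substr(err_read, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(err_read, 40, 40))[1]
  novel <- paste0(substr(ref, 501, 540), substr(ref, 2001, 2040))
  primer_read <- paste0(substr(ref, 501, 532), "AGATCGGAAGAGCGGT", substr(ref, 533, 564))
  primer_rc_read <- paste0(substr(ref, 501, 532), "ACCGCTCTTCCGATCT", substr(ref, 533, 564))
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    read1_seq = c(ref_read, err_read, novel, novel, primer_read, primer_rc_read),
    read1_qual = c(q35(80), q35(80), q35(80), q20(80), q35(80), q35(80))
  )
  kept <- filter_reads_for_assembly(reads, reference = ref)
  # exact reference read and 1-error reference read both eliminated (tolerant
  # matching); low-quality junction read eliminated; primer-2 reads eliminated;
  # the high-quality breakpoint-spanning read survives
  expect_equal(kept$read_id, "r3")

  # reverse-complement reads also match the reference
  rc_reads <- tibble::tibble(
    read_id = "rc", read1_seq = revcomp(ref_read), read1_qual = q35(80)
  )
  expect_equal(nrow(filter_reads_for_assembly(rc_reads, reference = ref)), 0L)

  # alignment-flag route
  al <- tibble::tibble(read_id = c("r3", "r4"), fully_aligned = c(TRUE, FALSE))
  kept2 <- filter_reads_for_assembly(reads[3:4, ], alignments = al)
  expect_equal(nrow(kept2), 0L) # r3 flagged aligned, r4 fails quality
  expect_error(filter_reads_for_assembly(reads), "reference")
})

test_that("reference_matches finds tolerant hits on both strands", {
  ref <- c(chr1 = random_genome_chr(2000, 61))
  hit <- substr(ref, 301, 380)
  hit3 <- hit
  for (p in c(10, 30, 60)) {
    substr(hit3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(hit3, p, p))[1]
  }
  hit4 <- hit3
  substr(hit4, 70, 70) <- setdiff(c("A", "C", "G", "T"), substr(hit4, 70, 70))[1]
  rnd <- random_genome_chr(80, 62)
  out <- reference_matches(
    c(hit, hit3, hit4, revcomp(hit), rnd), ref,
    max_mismatch = 3
  )
  expect_equal(out, c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("the assembler reconstructs source sequences through gates", {
  src <- random_genome_chr(70, 71)
  windows30 <- substring(src, 1:41, 30:70)
  reads4 <- rep(windows30, 4)
  ct <- assemble_locus(reads4, k = 19, min_contig_len = 50, min_coverage = 4,
    kmer_min_count = 1
  )
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$contig, min(src, revcomp(src)))
  # sparse single-copy windows reconstruct the path but fail the coverage
  # gate (mean k-mer coverage < 4)
  sparse <- substring(src, seq(1, 41, by = 10), seq(30, 70, by = 10))
  ct2 <- assemble_locus(sparse,
    k = 19, min_contig_len = 50,
    min_coverage = 4, kmer_min_count = 1
  )
  expect_equal(nrow(ct2), 0L)
  # the same reads pass once the gate is relaxed
  ct2b <- assemble_locus(sparse,
    k = 19, min_contig_len = 50,
    min_coverage = 1, kmer_min_count = 1
  )
  expect_equal(ct2b$contig, min(src, revcomp(src)))
  # two disjoint sources yield two contigs
  src2 <- random_genome_chr(70, 72)
  both <- c(reads4, rep(substring(src2, 1:41, 30:70), 4))
  ct3 <- assemble_locus(both, k = 19, min_contig_len = 50, min_coverage = 4,
    kmer_min_count = 1
  )
  expect_equal(nrow(ct3), 2L)
  expect_setequal(
    ct3$contig, c(min(src, revcomp(src)), min(src2, revcomp(src2)))
  )
  # no reads
  expect_equal(nrow(assemble_locus(character())), 0L)
})

test_that("assembly equals the brute-force overlap walk on simple paths", {
  for (i in 1:50) {
    src <- random_genome_chr(sample(80:150, 1), 1000 + i)
    starts <- seq(1, nchar(src) - 29, by = sample(3:7, 1))
    reads <- substring(src, starts, starts + 29)
    # flip a random subset onto the other strand
    set.seed(2000 + i)
    flip <- runif(length(reads)) < 0.5
    reads[flip] <- revcomp(reads[flip])
    got <- assemble_locus(reads,
      k = 19, min_contig_len = 19, min_coverage = 0,
      kmer_min_count = 1
    )
    expect_equal(nrow(got), 1L, info = paste("case", i))
    expect_equal(got$contig, oracle_overlap_walk(reads, 19),
      info = paste("case", i)
    )
  }
})

test_that("branch noise far below the dominant path is pruned", {
  src <- random_genome_chr(100, 81)
  reads <- rep(substring(src, 1:71, 30:100), 6)
  # two reads sharing the same mid-sequence error
  bad <- substr(src, 31, 60)
  substr(bad, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(bad, 15, 15))[1]
  ct <- assemble_locus(c(reads, bad, bad),
    k = 19, min_contig_len = 50,
    min_coverage = 4, kmer_min_count = 2
  )
  expect_equal(ct$contig, min(src, revcomp(src)))
})

test_that("contig validation resolves split alignments and rejections", {
  ref <- c(chr1 = random_genome_chr(8000, 91), chr2 = random_genome_chr(3000, 92))
  # deletion-like: prefix [100,160) + suffix [5000,5060)
  contig <- paste0(substr(ref[[1]], 101, 160), substr(ref[[1]], 5001, 5060))
  v <- validate_contig(contig, ref)
  expect_equal(v$status, "ACCEPT")
  expect_equal(v$pos1, 160L)
  expect_equal(v$pos2, 5000L)
  expect_equal(v$sv_type, "DEL")
  expect_true(v$somatic)

  # fully reference
  v2 <- validate_contig(substr(ref[[1]], 501, 620), ref)
  expect_equal(v2$reason, "FULLY_REFERENCE")
  v2rc <- validate_contig(revcomp(substr(ref[[1]], 501, 620)), ref)
  expect_equal(v2rc$reason, "FULLY_REFERENCE")

  # germline: same junction in the matched normal
  v3 <- validate_contig(contig, ref, normal_contigs = contig)
  expect_equal(v3$reason, "GERMLINE")
  expect_false(v3$somatic)
  expect_equal(v3$pos1, 160L) # coordinates still reported

  # wrong chromosome
  tra <- paste0(substr(ref[[1]], 101, 160), substr(ref[[2]], 1001, 1060))
  v4 <- validate_contig(tra, ref, expected_chrom = "chr1")
  expect_equal(v4$reason, "WRONG_CHROM")
  v4b <- validate_contig(tra, ref)
  expect_equal(v4b$status, "ACCEPT")
  expect_equal(v4b$sv_type, "TRA")

  # random garbage has no split
  v5 <- validate_contig(random_genome_chr(120, 93), ref)
  expect_equal(v5$reason, "NO_SPLIT")

  # inversion-like junction: forward then reverse-complement segment
  inv_contig <- paste0(
    substr(ref[[1]], 2001, 2060), revcomp(substr(ref[[1]], 6001, 6060))
  )
  v6 <- validate_contig(inv_contig, ref)
  expect_equal(v6$status, "ACCEPT")
  expect_equal(v6$sv_type, "INV")
})

test_that("junction canonicalization agrees with sequence equivalence", {
  set.seed(7)
  ref <- c(chr1 = random_genome_chr(4000, 95))
  # force microhomology: copy a short tract across a deletion junction
  r <- ref[[1]]
  substr(r, 2001, 2006) <- substr(r, 1001, 1006)
  ref <- c(chr1 = r)
  j <- tibble::tibble(
    chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
    chrom2 = "chr1", pos2 = 2000L, strand2 = "+"
  )
  shifted <- tibble::tibble(
    chrom1 = "chr1", pos1 = 1004L, strand1 = "+",
    chrom2 = "chr1", pos2 = 2004L, strand2 = "+"
  )
  # the two representations realize the same fused sequence
  expect_true(junctions_equivalent(ref, j, shifted))
  c1 <- canonicalize_junction(ref, j)
  c2 <- canonicalize_junction(ref, shifted)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  # canonical form is left-most: pos1 at most the original
  expect_lte(c1$pos1, 1000L)

  # flip equivalence: reading the junction from the other side
  flipped <- tibble::tibble(
    chrom1 = "chr1", pos1 = 2000L, strand1 = "-",
    chrom2 = "chr1", pos2 = 1000L, strand2 = "-"
  )
  c3 <- canonicalize_junction(ref, flipped)
  expect_equal(as.data.frame(c3), as.data.frame(c1))

  # property over random junctions incl. strand mixes: canonicalization is
  # idempotent and preserves the fused local sequence up to orientation
  for (i in 1:25) {
    set.seed(3000 + i)
    g <- c(chr1 = random_genome_chr(3000, 4000 + i))
    jj <- list(
      chrom1 = "chr1", pos1 = sample(500:1000, 1), strand1 = sample(c("+", "-"), 1),
      chrom2 = "chr1", pos2 = sample(1500:2500, 1), strand2 = sample(c("+", "-"), 1)
    )
    cc <- canonicalize_junction(g, jj)
    cc2 <- canonicalize_junction(g, cc)
    expect_equal(as.data.frame(cc), as.data.frame(cc2), info = paste("case", i))
    expect_true(junctions_equivalent(g, jj, cc), info = paste("case", i))
  }
})
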