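#' Write the canonical synthetic fixture bundle
#'
#' Generates the small on-disk fixtures the test-suite scenarios are built
#' from, entirely from seeds: a clean design genome with interval/SNP
#' targets, a repeat-rich genome, a two-genome mixture captured at 5/10/20%
#' spike fractions, and a tumor/normal structural-variant pair at 40% tumor
#' cellularity. Every file is listed in a YAML manifest with its MD5 digest,
#' and repeated invocation with the same seed reproduces the files byte for
#' byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-fixture seeds derive from it.
#' @return Invisibly, the manifest as a tibble (`file`, `md5`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  add <- function(p) paths[[length(paths) + 1L]] <<- p

  # clean design fixture: genome + targets + SNPs
  g <- simulate_genome(6000L, seed = seed)
  p_genome <- file.path(out_dir, "design_genome.fa")
  write_genome_fasta(g$genome, p_genome)
  add(p_genome)
  targets <- tibble(
    chrom = "chr1", start = c(2000L, 4200L), end = c(2400L, 4201L),
    label = c("locusA", "snpB"), target_class = c("LOCUS", "SNP")
  )
  p_targets <- file.path(out_dir, "design_targets.bed")
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%s", targets$chrom, targets$start, targets$end,
    targets$label, targets$target_class
  ), p_targets)
  add(p_targets)
  set.seed(seed + 1L)
  snp_pos <- sort(sample.int(5900L, 12L))
  p_snps <- file.path(out_dir, "known_snps.bed")
  writeLines(sprintf("chr1\t%d\t%d\tsnp%d", snp_pos, snp_pos + 1L,
    seq_along(snp_pos)
  ), p_snps)
  add(p_snps)

  # repeat fixture
  rg <- simulate_genome(4000L,
    seed = seed + 2L, repeat_fraction = 0.1,
    repeat_unit = "AT", repeat_tract_len = 200L
  )
  p_rep <- file.path(out_dir, "repeat_genome.fa")
  write_genome_fasta(rg$genome, p_rep)
  add(p_rep)
  p_rep_bed <- file.path(out_dir, "repeat_tracts.bed")
  writeLines(sprintf(
    "%s\t%d\t%d\trepeat", rg$repeats$chrom, rg$repeats$start, rg$repeats$end
  ), p_rep_bed)
  add(p_rep_bed)

  # mixture fixture at 5/10/20% spike fractions
  mix <- mixture_fixture(seed = seed + 3L, spikes = c(0.05, 0.10, 0.20))
  p_mix_ref <- file.path(out_dir, "mixture_reference.fa")
  write_genome_fasta(mix$reference, p_mix_ref)
  add(p_mix_ref)
  readr::write_tsv(mix$sites, file.path(out_dir, "mixture_truth_sites.tsv"))
  add(file.path(out_dir, "mixture_truth_sites.tsv"))
  for (s in names(mix$reads)) {
    r1 <- file.path(out_dir, sprintf("mixture_%s_R1.fq", s))
    r2 <- file.path(out_dir, sprintf("mixture_%s_R2.fq", s))
    write_fastq_pairs(mix$reads[[s]], r1, r2)
    add(r1)
    add(r2)
  }

  # tumor/normal SV fixture at 40% cellularity (scaled down)
  sv <- sv_fixture(
    seed = seed + 4L, genome_length = 30000L,
    n_del = 1L, n_inv = 1L, n_germline = 1L, n_fragments = 120000L
  )
  p_sv_ref <- file.path(out_dir, "sv_reference.fa")
  write_genome_fasta(sv$reference, p_sv_ref)
  add(p_sv_ref)
  readr::write_tsv(sv$truth, file.path(out_dir, "sv_truth_junctions.tsv"))
  add(file.path(out_dir, "sv_truth_junctions.tsv"))
  write_probe_catalog(sv$probes, file.path(out_dir, "sv_probes.tsv"))
  add(file.path(out_dir, "sv_probes.tsv"))
  for (s in c("tumor", "normal")) {
    r1 <- file.path(out_dir, sprintf("sv_%s_R1.fq", s))
    r2 <- file.path(out_dir, sprintf("sv_%s_R2.fq", s))
    write_fastq_pairs(sv$reads[[s]], r1, r2)
    add(r1)
    add(r2)
    sam <- file.path(out_dir, sprintf("sv_%s_truth.sam", s))
    write_truth_sam(sv$reads[[s]],
      if (s == "tumor") sv$tumor_genome else sv$normal_genome, sam
    )
    add(sam)
  }

  paths <- unlist(paths)
  manifest <- tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  yaml::write_yaml(
    list(
      seed = seed,
      files = stats::setNames(as.list(manifest$md5), manifest$file)
    ),
    file.path(out_dir, "manifest.yaml")
  )
  invisible(manifest)
}

#' Build a two-genome mixture scenario
#'
#' A spike genome carrying unique heterozygous and homozygous SNVs is mixed
#' into a background genome at the given spike weight fractions; probes are
#' designed over each variant site and capture is simulated deep enough that
#' sites reach the depth-100 reporting convention. Expected allele fraction
#' is `s/2` at heterozygous and `s` at homozygous spike-unique sites.
#'
#' @param seed Integer seed.
#' @param spikes Spike mass fractions (e.g. `c(0.05, 0.10, 0.20)`).
#' @param genome_length Background genome length.
#' @param n_het,n_hom Spike-unique heterozygous / homozygous SNV counts.
#' @param n_fragments Library fragments per capture.
#' @return List: `reference`, `probes`, `sites` (truth with `zygosity` and
#'   `expected_af` per spike), `reads` (named by spike, e.g. `"spike10"`).
#' @export
mixture_fixture <- function(seed, spikes = c(0.05, 0.10, 0.20),
                            genome_length = 6000L, n_het = 6L, n_hom = 2L,
                            n_fragments = 150000L) {
  g <- simulate_genome(genome_length, seed = seed)
  reference <- g$genome
  set.seed(seed + 10L)
  n_sites <- n_het + n_hom
  # sites spread out so distinct probes cover them
  pos <- as.integer(seq(600L, genome_length - 600L, length.out = n_sites))
  ref_base <- vapply(pos, function(p) char_at(reference[[1]], p), character(1))
  alt_base <- vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  zyg <- sample(c(rep("het", n_het), rep("hom", n_hom)))
  sites <- tibble(
    chrom = names(reference)[1], pos = pos, ref = ref_base, alt = alt_base,
    zygosity = zyg
  )
  variants <- tibble(
    chrom = sites$chrom, type = "SNV", start = sites$pos,
    end = sites$pos + 1L, alt = sites$alt,
    label = paste0("mix_", sites$pos)
  )
  hap_var <- implant_variants(reference, variants)$genome # all variants
  hap_hom <- implant_variants(
    reference, variants[sites$zygosity == "hom", ]
  )$genome # homozygous only
  track <- classify_positions(reference, k = 20L, margin_mismatches = 1L)
  design <- design_targets(
    sites |>
      mutate(
        start = .data$pos, end = .data$pos + 1L, target_class = "SNP",
        label = paste0("site_", .data$pos)
      ) |>
      select("chrom", "start", "end", "target_class", "label"),
    reference, track
  )
  cfg <- sim_config(
    seed = seed + 20L, n_fragments = n_fragments, efficiency = 0.049
  )
  reads <- list()
  for (s in spikes) {
    genomes <- list(
      list(name = "background", genome = reference, weight = 1 - s),
      list(name = "spike_hap1", genome = hap_var, weight = s / 2),
      list(name = "spike_hap2", genome = hap_hom, weight = s / 2)
    )
    cfg_s <- cfg
    cfg_s$seed <- cfg$seed + as.integer(round(1000 * s))
    reads[[sprintf("spike%02d", round(100 * s))]] <-
      simulate_capture(genomes, design$probes, cfg_s)
  }
  sites_per_spike <- bind_rows(lapply(spikes, function(s) {
    mutate(sites,
      spike = s,
      expected_af = ifelse(.data$zygosity == "het", s / 2, s)
    )
  }))
  list(
    reference = reference, probes = design$probes,
    sites = sites_per_spike, reads = reads
  )
}

#' Build a tumor/normal structural-variant scenario
#'
#' Implants somatic deletions and inversions (and shared germline deletions)
#' into a synthetic reference, designs four flanking probes per breakpoint,
#' and simulates capture of a tumor sample (tumor genome at the given
#' cellularity mixed with normal genome) and a matched normal sample.
#'
#' @param seed Integer seed.
#' @param genome_length Reference length (bases).
#' @param n_del,n_inv Somatic deletion / inversion counts.
#' @param n_germline Germline control deletions (implanted in both genomes).
#' @param cellularity Tumor cell fraction of the tumor sample (default 0.4).
#' @param sv_size Structural variant span (bases).
#' @param n_fragments Library fragments per sample.
#' @param read1_len,read2_len Read lengths.
#' @return List: `reference`, `tumor_genome`, `normal_genome`, `probes`
#'   (with `locus` column), `truth` (junction table, `somatic` flag),
#'   `candidates` (SV-candidate records), `reads` (`$tumor`, `$normal`).
#' @export
sv_fixture <- function(seed, genome_length = 100000L, n_del = 5L, n_inv = 2L,
                       n_germline = 2L, cellularity = 0.4, sv_size = 2000L,
                       n_fragments = 600000L, read1_len = 80L,
                       read2_len = 40L) {
  g <- simulate_genome(genome_length, seed = seed)
  reference <- g$genome
  ch <- names(reference)[1]
  n_sv <- n_del + n_inv + n_germline
  # evenly spaced, non-overlapping events with room for probes
  centers <- as.integer(seq(
    4000L, genome_length - 4000L, length.out = n_sv
  ))
  starts <- centers - sv_size %/% 2L
  types <- c(rep("DEL", n_del), rep("INV", n_inv), rep("DEL", n_germline))
  somatic <- c(rep(TRUE, n_del + n_inv), rep(FALSE, n_germline))
  labels <- sprintf(
    "%s_%s", ifelse(somatic, "som", "germ"),
    sprintf("%s%02d", tolower(types), seq_len(n_sv))
  )
  variants <- tibble(
    chrom = ch, type = types, start = starts, end = starts + sv_size,
    alt = NA_character_, label = labels
  )
  tumor <- implant_variants(reference, variants)
  normal <- implant_variants(reference, variants[!somatic, ])
  truth <- tumor$truth |>
    filter(.data$type != "SNV") |>
    left_join(tibble(label = labels, somatic = somatic), by = "label")

  track <- classify_positions(reference, k = 20L, margin_mismatches = 1L)
  designs <- lapply(seq_len(n_sv), function(i) {
    design_for_breakpoint(
      tibble(
        chrom1 = ch, pos1 = variants$start[i],
        chrom2 = ch, pos2 = variants$end[i], label = labels[i]
      ),
      reference, track
    )
  })
  probes <- bind_rows(lapply(designs, function(d) d$probes))
  gaps <- bind_rows(lapply(designs, function(d) d$gaps))

  cfg <- sim_config(
    seed = seed + 30L, n_fragments = n_fragments,
    efficiency = 0.049, read1_len = read1_len, read2_len = read2_len
  )
  tumor_sample <- simulate_capture(
    list(
      list(
        name = "tumor", genome = tumor$genome, weight = cellularity,
        lift = tumor$lift
      ),
      list(
        name = "normal_in_tumor", genome = normal$genome,
        weight = 1 - cellularity, lift = normal$lift
      )
    ),
    probes, cfg
  )
  cfg_n <- cfg
  cfg_n$seed <- cfg$seed + 1L
  normal_sample <- simulate_capture(
    list(list(
      name = "normal", genome = normal$genome, weight = 1,
      lift = normal$lift
    )),
    probes, cfg_n
  )
  candidates <- tibble(
    chrom1 = ch, pos1 = variants$start, chrom2 = ch, pos2 = variants$end,
    type = types, label = labels,
    support_tumor1 = ifelse(somatic, 25L, 30L),
    support_tumor2 = ifelse(somatic, 15L, 30L),
    in_normal = !somatic
  )
  list(
    reference = reference, tumor_genome = tumor$genome,
    normal_genome = normal$genome, probes = probes, gaps = gaps,
    truth = truth, candidates = candidates,
    reads = list(tumor = tumor_sample, normal = normal_sample)
  )
}
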