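#' Read/write paired FASTQ
#'
#' @param reads Read tibble from [simulate_capture()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path,
      format = "fastq",
      qualities = Biostrings::BStringSet(quals)
    )
  }
  w(reads$read1_seq, reads$read1_qual, reads$read_id, r1_path)
  w(reads$read2_seq, reads$read2_qual, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pairs
#' @param path FASTQ path.
#' @return `read_fastq()` returns a tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write truth alignments as SAM
#'
#' Emits one ungapped record per Read 1 from simulated provenance (no
#' aligner involved): SEQ is stored forward-oriented with FLAG 16 for
#' reverse-strand reads, CIGAR is all-match, MAPQ 60.
#'
#' @param reads Read tibble from [simulate_capture()].
#' @param genome Genome the coordinates refer to (for `@SQ` lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, genome, path) {
  genome <- as_genome(genome)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome))
  )
  seq_fwd <- reads$read1_seq
  rev_idx <- reads$r1_strand == "-"
  seq_fwd[rev_idx] <- revcomp(seq_fwd[rev_idx])
  qual_fwd <- reads$read1_qual
  qual_fwd[rev_idx] <- vapply(
    strsplit(qual_fwd[rev_idx], "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""), character(1)
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    reads$read_id,
    ifelse(rev_idx, 16L, 0L),
    reads$chrom,
    reads$r1_start + 1L,
    60L,
    nchar(seq_fwd),
    seq_fwd,
    qual_fwd
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignment records from SAM
#'
#' Uses Rsamtools (SAM is converted to BAM internally, then scanned).
#'
#' @param path SAM file path.
#' @return Alignment tibble: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mapq`, `aligned_len`, `fully_aligned` (all-match
#'   CIGAR, no clips or gaps), `seq`, `qual`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
    indexDestination = FALSE
  )
  p <- Rsamtools::ScanBamParam(what = c(
    "qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"
  ))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  ref_len <- cigar_ref_len(b$cigar)
  tibble(
    read_id = b$qname,
    chrom = as.character(b$rname),
    start = b$pos - 1L,
    end = b$pos - 1L + ref_len,
    strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    mapq = b$mapq,
    aligned_len = ref_len,
    fully_aligned = grepl("^\\d+M$", b$cigar),
    seq = as.character(b$seq),
    qual = as.character(b$qual)
  )
}

# reference-consuming length of CIGAR strings
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]$", "", toks))[
      grepl("[MDN=X]$", toks)
    ])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read/write a probe catalog TSV
#'
#' @param design An `osseq_design` or probe tibble.
#' @param path TSV path.
#' @return Paths / tibbles.
#' @export
write_probe_catalog <- function(design, path) {
  probes <- if (inherits(design, "osseq_design")) design$probes else design
  readr::write_tsv(probes, path)
  invisible(path)
}

#' @rdname write_probe_catalog
#' @export
read_probe_catalog <- function(path) {
  readr::read_tsv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      probe_id = "c", chrom = "c", strand = "c", target_seq_40 = "c",
      oligo_101 = "c", parent_target = "c", slot = "c",
      anchor_start = "i", anchor_end = "i", gc_fraction = "d"
    )
  )
}

#' Write the expected-capture BED for a probe catalog
#'
#' One record per probe: the anchor enlarged by `flank` bases on each side
#' (0-based half-open), named by probe id.
#'
#' @param probes Probe catalog tibble or `osseq_design`.
#' @param path Output BED path.
#' @param flank Flank in bases (default 50).
#' @return `path`, invisibly.
#' @export
write_capture_bed <- function(probes, path, flank = 50L) {
  if (inherits(probes, "osseq_design")) probes <- probes$probes
  writeLines(sprintf(
    "%s\t%d\t%d\t%s", probes$chrom,
    pmax(probes$anchor_start - flank, 0L), probes$anchor_end + flank,
    probes$probe_id
  ), path)
  invisible(path)
}

#' Read targets or SNP positions from BED / VCF
#'
#' BED input is read with rtracklayer; columns 4 and 5 (when present) are
#' interpreted as `label` and `target_class`. VCF input (SNP positions only;
#' genotypes ignored, multi-allelic records collapse to one position) is
#' read with VariantAnnotation.
#'
#' @param path Input path.
#' @return `read_targets_bed()`: tibble `chrom`, `start`, `end`, `label`,
#'   `target_class`; `read_snp_positions()`: tibble `chrom`, `pos` (0-based).
#' @export
read_targets_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read BED files")
  }
  ncol <- length(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]])
  gr <- if (ncol >= 5L) {
    # five-column target file: chrom, start, end, label, class
    rtracklayer::import(path,
      format = "BED",
      colnames = c("chrom", "start", "end", "name"),
      extraCols = c(target_class = "character")
    )
  } else {
    rtracklayer::import(path, format = "BED")
  }
  has_class <- !is.null(gr$target_class)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) gr$name else paste0("target_", seq_along(gr)),
    target_class = if (has_class) gr$target_class else "LOCUS"
  )
}

#' @rdname read_targets_bed
#' @export
read_snp_positions <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE) ||
      !requireNamespace("SummarizedExperiment", quietly = TRUE)) {
      abort("VariantAnnotation is required to read VCF files")
    }
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    tibble(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L
    ) |> distinct()
  } else {
    read_targets_bed(path) |>
      select("chrom", pos = "start") |>
      distinct()
  }
}

#' Write a minimal VCF of allele-fraction calls
#'
#' @param calls Tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `depth`,
#'   `alt_count`, `af`, `called`.
#' @param path Output path.
#' @param called_only Write only called sites (default TRUE).
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(calls, path, called_only = TRUE) {
  x <- if (called_only) filter(calls, .data$called) else calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
    x$chrom, x$pos + 1L, x$ref, x$alt, x$depth, x$af
  )
  writeLines(c(header, body), path)
  invisible(path)
}
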