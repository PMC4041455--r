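#' Demultiplex read pairs by 7-base sample index tags
#'
#' Each pair's tag is compared to the sample table; a pair is assigned to the
#' unique sample whose tag lies within `max_mismatch` substitutions,
#' otherwise it falls into the `"unassigned"` bin. The tag table must be
#' unambiguous: all tags of length 7 and pairwise Hamming distance greater
#' than `2 * max_mismatch`.
#'
#' @param pairs Tibble of read pairs with a `tag` column.
#' @param sample_table Tibble with `sample_id` and `tag`.
#' @param max_mismatch Tag mismatches tolerated (default 0).
#' @return `pairs` with a `sample` column (`"unassigned"` when no tag
#'   matches); every input row appears exactly once.
#' @export
demultiplex <- function(pairs, sample_table, max_mismatch = 0L) {
  sample_table <- as_tibble(sample_table)
  tags <- toupper(sample_table$tag)
  if (any(nchar(tags) != 7L)) abort("all sample tags must be 7 bases")
  if (anyDuplicated(tags)) abort("duplicate sample tags")
  if (nrow(sample_table) > 1L) {
    pairs_idx <- utils::combn(length(tags), 2)
    dmin <- min(hamming(tags[pairs_idx[1, ]], tags[pairs_idx[2, ]]))
    if (dmin <= 2L * max_mismatch) {
      abort("ambiguous tag table: tags closer than 2*max_mismatch + 1")
    }
  }
  obs <- unique(pairs$tag)
  lookup <- vapply(obs, function(tg) {
    if (is.na(tg) || nchar(tg) != 7L) return("unassigned")
    d <- hamming(rep(toupper(tg), length(tags)), tags)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) sample_table$sample_id[hit] else "unassigned"
  }, character(1))
  mutate(as_tibble(pairs), sample = unname(lookup[match(.data$tag, obs)]))
}

#' Assign reads to probes via the Read 2 probe prefix
#'
#' The first `prefix_len` bases of Read 2 carry the synthetic probe sequence;
#' each read is assigned to the unique probe whose 40-mer prefix matches best
#' within `max_mismatch` substitutions. Ties and misses give `NA`
#' (unassigned). The default 20-base prefix suffices because catalogs are
#' built with unique terminal 20-mers; set `prefix_len = 40` for full-length
#' matching.
#'
#' @param read2_seq Character vector of Read 2 sequences (length >=
#'   `prefix_len`).
#' @param probes Probe catalog tibble (non-empty).
#' @param prefix_len Prefix length compared (default 20).
#' @param max_mismatch Mismatches tolerated (default 1).
#' @return Character vector of `probe_id` or `NA` per read.
#' @export
assign_probe <- function(read2_seq, probes, prefix_len = 20L,
                         max_mismatch = 1L) {
  probes <- as_tibble(probes)
  if (nrow(probes) == 0L) abort("empty probe catalog")
  if (any(nchar(read2_seq) < prefix_len)) {
    abort("Read 2 shorter than prefix_len")
  }
  n <- length(read2_seq)
  if (n == 0L) return(character())
  rp <- substr(read2_seq, 1L, prefix_len)
  pp <- substr(probes$target_seq_40, 1L, prefix_len)
  rmat <- matrix(
    unlist(strsplit(rp, "", fixed = TRUE), use.names = FALSE),
    nrow = prefix_len
  )
  d <- vapply(pp, function(p) {
    pch <- strsplit(p, "", fixed = TRUE)[[1]]
    colSums(rmat != pch)
  }, numeric(n))
  d <- matrix(d, nrow = n)
  best <- apply(d, 1L, function(row) {
    m <- min(row)
    if (m > max_mismatch || sum(row == m) > 1L) NA_integer_ else which.min(row)
  })
  probes$probe_id[best]
}

#' Classify Read 1 alignments as on- or off-target
#'
#' A read is on target when it aligns to its probe's chromosome, in the
#' orientation the capture chemistry implies (Read 1 aligns on the strand
#' opposite its probe, on the extension side of the anchor), and within
#' `on_target_dist` bases of the anchor (distance from the anchor's
#' extension-proximal end to the near end of the alignment). Reads between
#' `on_target_dist` and `max_insert` are flagged as a gray zone (captures are
#' occasionally recovered beyond 1 kb; inserts beyond 1.5 kb are always off
#' target); they remain `OFF_TARGET`/`DISTANCE_EXCEEDED` for default metrics.
#'
#' @param alns Alignment tibble: `read_id`, `probe_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param probes Probe catalog tibble.
#' @param on_target_dist On-target distance rule in bases (default 1000).
#' @param max_insert Gray-zone limit in bases (default 1500).
#' @return `alns` with `status` (`ON_TARGET`/`OFF_TARGET`), `reason`
#'   (`NA`, `WRONG_CHROM`, `WRONG_ORIENTATION`, `DISTANCE_EXCEEDED`),
#'   `distance`, and `gray` (within `(on_target_dist, max_insert]`).
#' @export
classify_on_target <- function(alns, probes, on_target_dist = 1000L,
                               max_insert = 1500L) {
  probes <- as_tibble(probes)
  if (anyNA(alns$probe_id)) {
    abort("classify_on_target() requires probe-assigned reads; drop NA probe_id")
  }
  x <- as_tibble(alns) |>
    left_join(
      probes |>
        select("probe_id",
          probe_chrom = "chrom", a0 = "anchor_start",
          a1 = "anchor_end", probe_strand = "strand"
        ),
      by = "probe_id"
    )
  expected <- ifelse(x$probe_strand == "+", "-", "+")
  dist <- ifelse(x$probe_strand == "+", x$start - x$a1, x$a0 - x$end)
  probe_len <- x$a1 - x$a0
  wrong_chrom <- x$chrom != x$probe_chrom
  wrong_orient <- !wrong_chrom & (x$strand != expected | dist < -probe_len)
  too_far <- !wrong_chrom & !wrong_orient & dist > on_target_dist
  reason <- rep(NA_character_, nrow(x))
  reason[wrong_chrom] <- "WRONG_CHROM"
  reason[wrong_orient] <- "WRONG_ORIENTATION"
  reason[too_far] <- "DISTANCE_EXCEEDED"
  x |>
    mutate(
      status = ifelse(is.na(reason), "ON_TARGET", "OFF_TARGET"),
      reason = reason,
      distance = dist,
      gray = !wrong_chrom & !wrong_orient &
        dist > on_target_dist & dist <= max_insert
    ) |>
    select(-"probe_chrom", -"a0", -"a1", -"probe_strand")
}

#' Per-probe on-target yield table
#'
#' Counts on-target reads per probe (zero-yield probes included), the capture
#' rate (fraction of probes with at least one on-target read) and the one-log
#' uniformity (fraction of probes within a factor of 10 of the median yield).
#'
#' @param classified Output of [classify_on_target()].
#' @param probes Probe catalog tibble.
#' @param include_gray Count gray-zone reads as on-target (default FALSE,
#'   the 1 kb convention).
#' @return A tibble of class `osseq_yield` with `probe_id` and `n_on`;
#'   attributes `capture_rate`, `uniformity_1log`, `n_assigned`, `n_on`.
#'   [generics::glance()] returns them as a one-row tibble.
#' @export
per_probe_yield <- function(classified, probes, include_gray = FALSE) {
  probes <- as_tibble(probes)
  on <- classified$status == "ON_TARGET" | (include_gray & classified$gray)
  counts <- classified |>
    filter(on) |>
    count(.data$probe_id, name = "n_on")
  out <- probes |>
    select("probe_id") |>
    left_join(counts, by = "probe_id") |>
    mutate(n_on = ifelse(is.na(.data$n_on), 0L, .data$n_on))
  structure(out,
    class = c("osseq_yield", class(out)),
    capture_rate = mean(out$n_on >= 1L),
    uniformity_1log = uniformity_1log(out$n_on),
    n_assigned = nrow(classified),
    n_on = sum(out$n_on)
  )
}

#' One-log yield uniformity
#'
#' Fraction of probes whose yield lies within one order of magnitude of the
#' median yield over all probes (zeros included): the window is
#' `[median/10, 10 * median]`, inclusive.
#'
#' @param yields Non-empty numeric vector of per-probe yields.
#' @return Fraction in `[0, 1]`.
#' @export
uniformity_1log <- function(yields) {
  if (length(yields) == 0L) abort("uniformity_1log() needs at least one probe")
  m <- median(yields)
  mean(yields >= m / 10 & yields <= 10 * m)
}

#' Region-of-interest coverage from Read 1 alignments
#'
#' ROIs are the probe anchors (or their parent targets) enlarged by `flank`
#' bases on each side and merged when overlapping. Depth counts Read 1
#' genomic bases only: any read whose alignment overlaps its originating
#' probe's 40-mer footprint is excluded, so synthetic probe sequence never
#' inflates coverage.
#'
#' @inheritParams classify_on_target
#' @param flank Flank added to each anchor (default 50).
#' @param thresholds Depth thresholds reported as fractions of ROI bases.
#' @param genome Optional genome (for sequence lengths).
#' @return Tibble with one row per merged ROI: `chrom`, `start`, `end`,
#'   `mean_cov` and one `frac_ge_<t>` column per threshold.
#' @export
roi_coverage <- function(alns, probes, flank = 50L,
                         thresholds = c(1L, 10L, 30L), genome = NULL) {
  probes <- as_tibble(probes)
  alns <- as_tibble(alns) |>
    left_join(
      probes |> select("probe_id", a0 = "anchor_start", a1 = "anchor_end"),
      by = "probe_id"
    ) |>
    filter(!is.na(.data$a0) & (.data$end <= .data$a0 | .data$start >= .data$a1))
  rois <- GenomicRanges::reduce(GenomicRanges::GRanges(
    probes$chrom,
    IRanges::IRanges(
      pmax(probes$anchor_start - flank, 0L) + 1L,
      probes$anchor_end + flank
    )
  ))
  cov <- if (nrow(alns) > 0) {
    GenomicRanges::coverage(GenomicRanges::GRanges(
      alns$chrom, IRanges::IRanges(alns$start + 1L, alns$end)
    ))
  } else {
    NULL
  }
  res <- lapply(seq_along(rois), function(i) {
    ch <- as.character(GenomicRanges::seqnames(rois))[i]
    s1 <- GenomicRanges::start(rois)[i]
    e1 <- GenomicRanges::end(rois)[i]
    v <- numeric(e1 - s1 + 1L)
    if (!is.null(cov) && ch %in% names(cov)) {
      r <- cov[[ch]]
      hi <- min(e1, length(r))
      if (hi >= s1) {
        v[seq_len(hi - s1 + 1L)] <- as.numeric(S4Vectors::window(r, s1, hi))
      }
    }
    row <- tibble(
      chrom = ch, start = s1 - 1L, end = e1, mean_cov = mean(v)
    )
    for (t in thresholds) row[[paste0("frac_ge_", t)]] <- mean(v >= t)
    row
  })
  bind_rows(res)
}

#' Fixed-threshold allele-fraction caller
#'
#' Re-implements the stated pileup thresholds: a site is called when depth
#' >= `min_coverage`, alternate fraction >= `min_var_freq` and mean base
#' quality >= `min_avg_qual`. The allele fraction is always reported.
#'
#' @param sites Tibble with `depth`, `alt_count`, `mean_qual` (e.g. from
#'   [count_alleles()]).
#' @param min_coverage Minimum depth (default 10).
#' @param min_var_freq Minimum alternate allele fraction (default 0.15).
#' @param min_avg_qual Minimum mean base quality (default 25).
#' @return `sites` with `af` and logical `called`.
#' @export
naive_af_call <- function(sites, min_coverage = 10L, min_var_freq = 0.15,
                          min_avg_qual = 25) {
  sites <- as_tibble(sites)
  stopifnot(all(sites$alt_count <= sites$depth))
  sites |>
    mutate(
      af = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
      called = .data$depth >= min_coverage &
        !is.na(.data$af) & .data$af >= min_var_freq &
        !is.na(.data$mean_qual) & .data$mean_qual >= min_avg_qual
    )
}

#' Truth alignments from simulated provenance
#'
#' Converts the provenance columns of [simulate_capture()] output into the
#' alignment records consumed by [classify_on_target()] and
#' [roi_coverage()], avoiding any aligner dependency.
#'
#' @param reads Read tibble from [simulate_capture()].
#' @return Alignment tibble: `read_id`, `probe_id`, `chrom`, `start`, `end`,
#'   `strand`, `mapq`, `fully_aligned`, `seq`, `qual` (sequence oriented to
#'   the forward strand, as an aligner would store it).
#' @export
reads_to_alignments <- function(reads) {
  seq_fwd <- reads$read1_seq
  rev_idx <- reads$r1_strand == "-"
  seq_fwd[rev_idx] <- revcomp(seq_fwd[rev_idx])
  tibble(
    read_id = reads$read_id,
    probe_id = reads$probe_id,
    chrom = reads$chrom,
    start = reads$r1_start,
    end = reads$r1_end,
    strand = reads$r1_strand,
    mapq = 60L,
    fully_aligned = TRUE,
    seq = seq_fwd,
    qual = reads$read1_qual
  )
}
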