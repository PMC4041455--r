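#' Simulation configuration
#'
#' Collects the knobs of the capture simulator. Defaults mirror the assay
#' this package models: library fragments of about 500 bases, 80 x 40
#' paired-end reads, a mean per-probe capture efficiency of 4.9% of eligible
#' library fragments, constant Phred 35 base qualities, and an independent
#' per-base substitution error rate of 1e-3 (no indel errors).
#'
#' @param seed Integer seed; every simulator function is deterministic given
#'   the config seed.
#' @param n_fragments Library fragments drawn per simulated sample.
#' @param fragment_mean,fragment_sd Normal fragment-length parameters (bases).
#' @param read1_len,read2_len Read lengths; Read 2 begins with the 40-base
#'   synthetic probe sequence.
#' @param efficiency Fixed per-probe capture efficiency; if `NULL`, per-probe
#'   efficiencies are drawn log-normally with mean `efficiency_mean` and
#'   coefficient of variation `efficiency_cv`.
#' @param efficiency_mean,efficiency_cv Parameters of the per-probe capture
#'   efficiency distribution.
#' @param error_rate Per-base substitution error rate.
#' @param base_qual Constant Phred quality assigned to simulated bases.
#' @return List of class `osseq_sim_config`.
#' @export
sim_config <- function(seed,
                       n_fragments = 10000L,
                       fragment_mean = 500, fragment_sd = 100,
                       read1_len = 80L, read2_len = 40L,
                       efficiency = NULL,
                       efficiency_mean = 0.049, efficiency_cv = 0.5,
                       error_rate = 0.001, base_qual = 35L) {
  stopifnot(
    !missing(seed), n_fragments > 0, fragment_mean > 0, fragment_sd >= 0,
    read1_len >= 20, read2_len >= 20, error_rate >= 0, error_rate <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_fragments = as.integer(n_fragments),
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      read1_len = as.integer(read1_len), read2_len = as.integer(read2_len),
      efficiency = efficiency, efficiency_mean = efficiency_mean,
      efficiency_cv = efficiency_cv, error_rate = error_rate,
      base_qual = as.integer(base_qual)
    ),
    class = "osseq_sim_config"
  )
}

#' Simulate a random genome, optionally with embedded tandem repeats
#'
#' Bases are drawn uniformly; repeat tracts (perfect tandem copies of
#' `repeat_unit`) are embedded at evenly spaced, non-overlapping positions
#' until `repeat_fraction` of the genome is repetitive, and annotated so that
#' mapability classification can be exercised against known repetitive
#' sequence.
#'
#' @param length Genome length in bases.
#' @param seed Integer seed.
#' @param chrom Sequence name.
#' @param repeat_fraction Fraction of the genome covered by repeat tracts.
#' @param repeat_unit Tandem repeat unit (default `"AT"`).
#' @param repeat_tract_len Length of each embedded tract (bases).
#' @return List with `genome` (named character vector) and `repeats`
#'   (tibble: `chrom`, `start`, `end`, 0-based half-open).
#' @export
simulate_genome <- function(length, seed, chrom = "chr1",
                            repeat_fraction = 0, repeat_unit = "AT",
                            repeat_tract_len = 200L) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  repeats <- tibble(chrom = character(), start = integer(), end = integer())
  if (repeat_fraction > 0) {
    n_tracts <- max(1L, ceiling(repeat_fraction * length / repeat_tract_len))
    gap <- length %/% (n_tracts + 1L)
    starts <- (seq_len(n_tracts) * gap) - repeat_tract_len %/% 2L
    starts <- pmax(0L, pmin(starts, length - repeat_tract_len))
    unit <- strsplit(repeat_unit, "", fixed = TRUE)[[1]]
    tract <- rep_len(unit, repeat_tract_len)
    for (s in starts) bases[(s + 1L):(s + repeat_tract_len)] <- tract
    repeats <- tibble(
      chrom = chrom, start = as.integer(starts),
      end = as.integer(starts + repeat_tract_len)
    )
  }
  genome <- setNames(paste(bases, collapse = ""), chrom)
  list(genome = genome, repeats = repeats)
}

#' Implant variants into a genome
#'
#' Applies non-overlapping SNVs, deletions, insertions and inversions to a
#' reference, returning the derived genome, a truth table of variant
#' coordinates (including every novel junction a structural variant creates,
#' in reference coordinates), and a block lift map translating reference to
#' derived coordinates.
#'
#' Deletions create one junction `(start, end)`; inversions create a left
#' junction (forward sequence fused at `start` to reverse-complement sequence
#' entering at `end`) and a right junction (reverse-complement sequence
#' leaving at `start` fused to forward sequence at `end`). Junctions are
#' reported as implanted; use [canonicalize_junction()] before comparing to
#' assembly output, since microhomology can make the junction representation
#' non-unique.
#'
#' @param genome Reference genome.
#' @param variants Tibble with `chrom`, `type` (`SNV`, `DEL`, `INS`, `INV`),
#'   `start`, `end` (0-based half-open; for SNV `end = start + 1`; for INS
#'   the insertion point with `end == start`), `alt` (SNV replacement base or
#'   INS sequence; ignored otherwise), and optional `label`.
#' @return List with `genome` (derived), `truth` (tibble: `label`, `type`,
#'   `side`, `chrom`, `pos1`, `strand1`, `pos2`, `strand2`), and `lift`
#'   (tibble: `chrom`, `ref_start`, `ref_end`, `derived_start`, `strand`).
#' @export
implant_variants <- function(genome, variants) {
  genome <- as_genome(genome)
  variants <- as_tibble(variants)
  if (!"label" %in% names(variants)) {
    variants$label <- paste0(tolower(variants$type), "_", variants$start)
  }
  out_seq <- genome
  truth <- list()
  lift <- list()
  for (ch in names(genome)) {
    v <- variants |>
      filter(.data$chrom == ch) |>
      arrange(.data$start)
    if (nrow(v) > 1 && any(v$start[-1] < v$end[-nrow(v)])) {
      abort("variants overlap after sorting")
    }
    ref <- genome[[ch]]
    L <- nchar(ref)
    pieces <- character()
    blocks <- list()
    cur_ref <- 0L
    cur_der <- 0L
    emit_block <- function(ref_start, ref_end, der_start, strand) {
      if (ref_end > ref_start) {
        blocks[[length(blocks) + 1L]] <<- tibble(
          chrom = ch, ref_start = ref_start, ref_end = ref_end,
          derived_start = der_start, strand = strand
        )
      }
    }
    for (i in seq_len(nrow(v))) {
      vi <- v[i, ]
      gap <- substr(ref, cur_ref + 1L, vi$start)
      pieces <- c(pieces, gap)
      emit_block(cur_ref, vi$start, cur_der, "+")
      cur_der <- cur_der + nchar(gap)
      if (vi$type == "SNV") {
        pieces <- c(pieces, toupper(vi$alt))
        emit_block(vi$start, vi$end, cur_der, "+")
        cur_der <- cur_der + 1L
        cur_ref <- vi$end
        truth[[length(truth) + 1L]] <- tibble(
          label = vi$label, type = "SNV", side = NA_character_, chrom = ch,
          pos1 = vi$start, strand1 = "+", pos2 = vi$start, strand2 = "+"
        )
      } else if (vi$type == "DEL") {
        cur_ref <- vi$end
        truth[[length(truth) + 1L]] <- tibble(
          label = vi$label, type = "DEL", side = NA_character_, chrom = ch,
          pos1 = vi$start, strand1 = "+", pos2 = vi$end, strand2 = "+"
        )
      } else if (vi$type == "INS") {
        ins <- toupper(vi$alt)
        pieces <- c(pieces, ins)
        cur_der <- cur_der + nchar(ins)
        cur_ref <- vi$start
        truth[[length(truth) + 1L]] <- tibble(
          label = vi$label, type = "INS", side = NA_character_, chrom = ch,
          pos1 = vi$start, strand1 = "+", pos2 = vi$start, strand2 = "+"
        )
      } else if (vi$type == "INV") {
        seg <- revcomp(substr(ref, vi$start + 1L, vi$end))
        pieces <- c(pieces, seg)
        emit_block(vi$start, vi$end, cur_der, "-")
        cur_der <- cur_der + nchar(seg)
        cur_ref <- vi$end
        truth[[length(truth) + 1L]] <- bind_rows(
          tibble(
            label = vi$label, type = "INV", side = "L", chrom = ch,
            pos1 = vi$start, strand1 = "+", pos2 = vi$end, strand2 = "-"
          ),
          tibble(
            label = vi$label, type = "INV", side = "R", chrom = ch,
            pos1 = vi$start, strand1 = "-", pos2 = vi$end, strand2 = "+"
          )
        )
      } else {
        abort(paste0("unknown variant type: ", vi$type))
      }
    }
    tail <- substr(ref, cur_ref + 1L, L)
    pieces <- c(pieces, tail)
    emit_block(cur_ref, L, cur_der, "+")
    out_seq[[ch]] <- paste(pieces, collapse = "")
    lift[[ch]] <- bind_rows(blocks)
  }
  list(
    genome = out_seq,
    truth = bind_rows(truth),
    lift = bind_rows(lift)
  )
}

#' Map a reference interval through a lift map
#'
#' Returns derived coordinates for intervals falling entirely within one
#' lift block; intervals broken by a variant map to `NA`.
#'
#' @param lift Lift tibble from [implant_variants()] (`NULL` = identity).
#' @param chrom,start,end Vectors of reference intervals (0-based half-open).
#' @return Tibble with `derived_start`, `derived_end`, `flipped` (interval
#'   lies in an inverted block).
#' @export
lift_interval <- function(lift, chrom, start, end) {
  n <- length(start)
  if (is.null(lift)) {
    return(tibble(
      derived_start = as.integer(start), derived_end = as.integer(end),
      flipped = rep(FALSE, n)
    ))
  }
  ds <- rep(NA_integer_, n)
  de <- rep(NA_integer_, n)
  fl <- rep(NA, n)
  for (i in seq_len(n)) {
    sel <- which(lift$chrom == chrom[i] &
      lift$ref_start <= start[i] & lift$ref_end >= end[i])
    if (length(sel) == 0L) next
    b <- lift[sel[1], ]
    if (b$strand == "+") {
      ds[i] <- b$derived_start + (start[i] - b$ref_start)
      de[i] <- ds[i] + (end[i] - start[i])
      fl[i] <- FALSE
    } else {
      ds[i] <- b$derived_start + (b$ref_end - end[i])
      de[i] <- ds[i] + (end[i] - start[i])
      fl[i] <- TRUE
    }
  }
  tibble(derived_start = ds, derived_end = de, flipped = fl)
}

#' Draw per-probe capture efficiencies
#'
#' @param probes Probe catalog tibble.
#' @param config [sim_config()].
#' @return `probes` with an `efficiency` column (fixed, or log-normal with
#'   the configured mean and CV).
#' @export
draw_probe_efficiencies <- function(probes, config) {
  if (!is.null(config$efficiency)) {
    probes$efficiency <- config$efficiency
    return(probes)
  }
  set.seed(config$seed + 101L)
  cv <- config$efficiency_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config$efficiency_mean) - sdlog^2 / 2
  probes$efficiency <- pmin(1, stats::rlnorm(nrow(probes), meanlog, sdlog))
  probes
}

#' Simulate on-flow-cell capture of a fragment library
#'
#' Fragments (length ~ Normal(`fragment_mean`, `fragment_sd`)) are drawn from
#' each source genome in proportion to its weight (a mixture or a
#' tumor/normal cellularity split). A fragment is eligible for a probe when
#' it fully contains the probe's 40-base anchor in the source frame (probe
#' anchors are lifted through each source's lift map; disrupted anchors
#' cannot capture), and is captured with the probe's efficiency.
#'
#' Read geometry follows the single-adapter chemistry: the probe anneals at
#' its anchor and is extended to the fragment end on the extension side; Read
#' 1 is then primed from the adapter at that fragment end and reads back
#' toward the probe, so read start positions are randomly distributed over
#' the captured span (and a fragment ending close to the anchor yields a read
#' overlapping the probe footprint). Read 2 is primed through the probe and
#' carries its synthetic 40-mer followed by adjacent genomic sequence.
#' Consequently a `+` probe's Read 1 aligns on the `-` strand downstream of
#' the anchor, and vice versa.
#'
#' @param genomes List of sources; each a list with `name`, `genome` (named
#'   character vector), `weight` (non-negative; normalized internally), and
#'   optional `lift` (from [implant_variants()]).
#' @param probes Probe catalog tibble (reference frame); an `efficiency`
#'   column is honored, otherwise drawn via [draw_probe_efficiencies()].
#' @param config [sim_config()].
#' @param tag Optional 7-base sample index tag stored with every pair.
#' @return Tibble of read pairs with full provenance: `read_id`, `source`,
#'   `probe_id`, `chrom`, `frag_start`, `frag_end`, `r1_start`, `r1_end`,
#'   `r1_strand`, `read1_seq`, `read1_qual`, `read2_seq`, `read2_qual`,
#'   `tag`. Coordinates are in the source genome frame, 0-based half-open.
#' @export
simulate_capture <- function(genomes, probes, config, tag = NA_character_) {
  stopifnot(inherits(config, "osseq_sim_config"))
  probes <- as_tibble(probes)
  if (nrow(probes) == 0L) abort("empty probe catalog")
  if (!"efficiency" %in% names(probes)) {
    probes <- draw_probe_efficiencies(probes, config)
  }
  set.seed(config$seed)
  weights <- vapply(genomes, `[[`, numeric(1), "weight")
  if (any(weights < 0) || sum(weights) <= 0) abort("invalid source weights")
  counts <- as.vector(rmultinom(1, config$n_fragments, weights / sum(weights)))
  qual_char <- rawToChar(as.raw(config$base_qual + 33L))
  out <- list()
  ridx <- 0L
  for (g in seq_along(genomes)) {
    src <- genomes[[g]]
    gen <- as_genome(src$genome)
    n_i <- counts[g]
    if (n_i == 0L) next
    lens <- pmax(100L, as.integer(round(
      rnorm(n_i, config$fragment_mean, config$fragment_sd)
    )))
    chr_lens <- nchar(gen)
    chrom_i <- sample(names(gen), n_i, replace = TRUE, prob = chr_lens)
    max_start <- pmax(0L, chr_lens[chrom_i] - lens)
    f0 <- as.integer(floor(runif(n_i) * (max_start + 1L)))
    f1 <- pmin(f0 + lens, chr_lens[chrom_i])
    frag_by_chrom <- split(seq_len(n_i), chrom_i)
    # probe anchors in this source's frame
    lifted <- lift_interval(
      src$lift, probes$chrom, probes$anchor_start, probes$anchor_end
    )
    eff_strand <- ifelse(lifted$flipped,
      ifelse(probes$strand == "+", "-", "+"), probes$strand
    )
    for (p in seq_len(nrow(probes))) {
      a0 <- lifted$derived_start[p]
      if (is.na(a0)) next
      a1 <- lifted$derived_end[p]
      on_chrom <- frag_by_chrom[[probes$chrom[p]]]
      if (is.null(on_chrom)) next
      elig <- on_chrom[f0[on_chrom] <= a0 & f1[on_chrom] >= a1]
      if (length(elig) == 0L) next
      cap <- elig[runif(length(elig)) < probes$efficiency[p]]
      if (length(cap) == 0L) next
      st <- eff_strand[p]
      seqs <- unname(gen[chrom_i[cap]])
      if (st == "+") {
        r1_end <- f1[cap]
        r1_start <- pmax(a0, r1_end - config$read1_len)
        r1_fwd <- substring(seqs, r1_start + 1L, r1_end)
        read1 <- revcomp(r1_fwd)
        r1_strand <- "-"
        extra <- config$read2_len - 40L
        read2 <- if (extra > 0) {
          paste0(
            probes$target_seq_40[p],
            substring(seqs, a1 + 1L, pmin(a1 + extra, f1[cap]))
          )
        } else {
          substr(rep(probes$target_seq_40[p], length(cap)), 1L, config$read2_len)
        }
      } else {
        r1_start <- f0[cap]
        r1_end <- pmin(a1, r1_start + config$read1_len)
        read1 <- substring(seqs, r1_start + 1L, r1_end)
        r1_strand <- "+"
        extra <- config$read2_len - 40L
        read2 <- if (extra > 0) {
          paste0(
            probes$target_seq_40[p],
            revcomp(substring(seqs, pmax(a0 - extra, f0[cap]) + 1L, a0))
          )
        } else {
          substr(rep(probes$target_seq_40[p], length(cap)), 1L, config$read2_len)
        }
      }
      read1 <- add_seq_errors(read1, config$error_rate)
      read2 <- add_seq_errors(read2, config$error_rate)
      out[[length(out) + 1L]] <- tibble(
        read_id = sprintf("rd%07d", ridx + seq_along(cap)),
        source = src$name,
        probe_id = probes$probe_id[p],
        chrom = chrom_i[cap],
        frag_start = f0[cap], frag_end = f1[cap],
        r1_start = as.integer(r1_start), r1_end = as.integer(r1_end),
        r1_strand = r1_strand,
        read1_seq = read1,
        read1_qual = strrep(qual_char, nchar(read1)),
        read2_seq = read2,
        read2_qual = strrep(qual_char, nchar(read2)),
        tag = tag
      )
      ridx <- ridx + length(cap)
    }
  }
  reads <- bind_rows(out)
  if (nrow(reads) == 0L) {
    reads <- tibble(
      read_id = character(), source = character(), probe_id = character(),
      chrom = character(), frag_start = integer(), frag_end = integer(),
      r1_start = integer(), r1_end = integer(), r1_strand = character(),
      read1_seq = character(), read1_qual = character(),
      read2_seq = character(), read2_qual = character(), tag = character()
    )
  }
  attr(reads, "sim_config") <- config
  reads
}

# independent per-base substitutions at rate `rate`
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Count alleles at sites from simulated reads
#'
#' Builds a pileup at each site from Read 1 provenance (reads are oriented to
#' the forward strand first) and tallies reference and alternate bases,
#' giving the observed depth, alternate count and mean base quality used by
#' [naive_af_call()].
#'
#' @param reads Read tibble from [simulate_capture()] (single coordinate
#'   frame across sources; mixture sites should be SNVs so frames agree).
#' @param sites Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @return `sites` with `depth`, `ref_count`, `alt_count`, `mean_qual`, `af`.
#' @export
count_alleles <- function(reads, sites) {
  sites <- as_tibble(sites)
  fwd <- reads$read1_seq
  rev_idx <- reads$r1_strand == "-"
  fwd[rev_idx] <- revcomp(fwd[rev_idx])
  qual_fwd <- reads$read1_qual
  qual_fwd[rev_idx] <- vapply(
    strsplit(qual_fwd[rev_idx], "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""), character(1)
  )
  res <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    cov <- which(reads$chrom == s$chrom &
      reads$r1_start <= s$pos & reads$r1_end > s$pos)
    if (length(cov) == 0L) {
      return(tibble(depth = 0L, ref_count = 0L, alt_count = 0L,
        mean_qual = NA_real_
      ))
    }
    off <- s$pos - reads$r1_start[cov] + 1L
    base <- substr(fwd[cov], off, off)
    qch <- substr(qual_fwd[cov], off, off)
    tibble(
      depth = length(cov),
      ref_count = sum(base == s$ref),
      alt_count = sum(base == s$alt),
      mean_qual = mean(utf8ToInt(paste(qch, collapse = "")) - 33L)
    )
  })
  dplyr::bind_cols(sites, bind_rows(res)) |>
    mutate(af = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_))
}
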