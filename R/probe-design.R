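#' Design parameters for primer probe placement
#'
#' Defaults encode the assay's standard placement criteria: GC content of the 40-mer
#' between 30% and 65%; probes tiled approximately every 200 bases on each
#' strand across long targets; flanking probes placed 100-200 bases up- and
#' downstream of short targets; no known SNP under the terminal 10 bases of
#' the probe (the extension-proximal end, most critical for hybridization and
#' extension); terminal 20-mer unique in the genome with a one-mismatch
#' margin; breakpoint probes 150-300 bases from the putative junction, four
#' per breakpoint on opposing strands.
#'
#' @param gc_min,gc_max Allowed GC fraction of the 40-mer (inclusive).
#' @param tile_spacing Nominal per-strand spacing for tiled probes (bases).
#' @param flank_lo,flank_hi Distance window between a flanking probe's
#'   extension-proximal end and the target boundary (bases).
#' @param snp_exclusion_len Terminal bases that must not overlap a known SNP.
#' @param uniqueness_margin Mismatch margin required of the terminal 20-mer
#'   (must match the margin of the mapability track).
#' @param bp_dist_lo,bp_dist_hi Distance window from a breakpoint probe's
#'   extension-proximal end to the putative junction (bases).
#' @param probes_per_breakpoint Probes attempted per breakpoint (split evenly
#'   between the two flanks/strands).
#' @param repeat_adjacent_len Extension-side window (bases) in which no
#'   `REPETITIVE` k-mer start may occur.
#' @param search_halfwidth Half-width of the anchor search window around each
#'   nominal tiled position (bases).
#' @param probe_len Length of the target-specific probe segment (40).
#' @param terminal_k Length of the terminal uniqueness k-mer (20).
#' @param universal_mid,p7_complement Universal oligo segments appended to the
#'   40-mer; their lengths must sum to 61 so the full oligo is a 101-mer.
#'   Defaults from [universal_segments()].
#' @return A named list of class `osseq_params`.
#' @export
design_params <- function(gc_min = 0.30, gc_max = 0.65,
                          tile_spacing = 200L,
                          flank_lo = 100L, flank_hi = 200L,
                          snp_exclusion_len = 10L,
                          uniqueness_margin = 1L,
                          bp_dist_lo = 150L, bp_dist_hi = 300L,
                          probes_per_breakpoint = 4L,
                          repeat_adjacent_len = 20L,
                          search_halfwidth = 30L,
                          probe_len = 40L, terminal_k = 20L,
                          universal_mid = NULL, p7_complement = NULL) {
  seg <- universal_segments()
  universal_mid <- universal_mid %||% seg$universal_mid
  p7_complement <- p7_complement %||% seg$p7_complement
  stopifnot(
    gc_min < gc_max, tile_spacing > 0, flank_lo > 0, flank_hi > flank_lo,
    bp_dist_lo > 0, bp_dist_hi > bp_dist_lo, probes_per_breakpoint >= 2
  )
  structure(
    list(
      gc_min = gc_min, gc_max = gc_max, tile_spacing = as.integer(tile_spacing),
      flank_lo = as.integer(flank_lo), flank_hi = as.integer(flank_hi),
      snp_exclusion_len = as.integer(snp_exclusion_len),
      uniqueness_margin = as.integer(uniqueness_margin),
      bp_dist_lo = as.integer(bp_dist_lo), bp_dist_hi = as.integer(bp_dist_hi),
      probes_per_breakpoint = as.integer(probes_per_breakpoint),
      repeat_adjacent_len = as.integer(repeat_adjacent_len),
      search_halfwidth = as.integer(search_halfwidth),
      probe_len = as.integer(probe_len), terminal_k = as.integer(terminal_k),
      universal_mid = universal_mid, p7_complement = p7_complement
    ),
    class = "osseq_params"
  )
}

#' Universal oligo segments
#'
#' The synthesized 101-mer is `target_seq_40 + universal_mid + p7_complement`.
#' The shipped defaults are a 37-base read-primer segment and a 24-base
#' segment complementary to the P7 lawn primer (together 61 bases); both are
#' configurable through a YAML file with keys `universal_mid` and
#' `p7_complement`.
#'
#' @param path Optional YAML file overriding the defaults.
#' @return List with `universal_mid` and `p7_complement`.
#' @export
universal_segments <- function(path = NULL) {
  path <- path %||% system.file("extdata", "universal_segments.yaml",
    package = "osseq"
  )
  if (nzchar(path) && file.exists(path)) {
    cfg <- yaml::read_yaml(path)
    return(list(
      universal_mid = toupper(cfg$universal_mid),
      p7_complement = toupper(cfg$p7_complement)
    ))
  }
  list(
    universal_mid = "GATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATC",
    p7_complement = "ATCTCGTATGCCGTCTTCTGCTTG"
  )
}

#' GC fraction of sequences
#'
#' @param seq Character vector of non-empty A/C/G/T sequences.
#' @return Numeric vector of (#G + #C) / length in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || any(grepl("[^ACGT]", seq))) {
    abort("gc_content() requires non-empty ACGT sequences")
  }
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

# genomic interval of the terminal (extension-proximal) m bases of an anchor
terminal_interval <- function(start, strand, probe_len, m) {
  lo <- ifelse(strand == "+", start + probe_len - m, start)
  cbind(lo = lo, hi = lo + m)
}

#' Evaluate probe candidates against the placement filters
#'
#' Applies the full placement rule set to each candidate anchor and reports
#' every violated rule among `CONTAINS_N`, `GC_RANGE`, `KMER_NOT_UNIQUE`
#' (terminal 20-mer not margin-unique), `SNP_IN_TERMINAL_10` (known SNP under
#' the extension-proximal 10 bases) and `REPEAT_ADJACENT` (a `REPETITIVE`
#' k-mer start within `repeat_adjacent_len` bases on the extension side).
#'
#' @param candidates Tibble with columns `chrom`, `anchor_start`, `strand`.
#' @param genome Genome as accepted by [as_genome()].
#' @param track `kmer_track` built with `k = terminal_k` and the params'
#'   uniqueness margin.
#' @param snps Known SNP positions: tibble with columns `chrom`, `pos`
#'   (0-based), or `NULL`.
#' @param params [design_params()].
#' @return `candidates` with added columns `target_seq_40`, `gc_fraction`,
#'   `pass` (logical) and `failures` (list of character codes).
#' @export
candidate_passes_filters <- function(candidates, genome, track, snps = NULL,
                                     params = design_params()) {
  genome <- as_genome(genome)
  check_track(track, params)
  pl <- params$probe_len
  cand <- as_tibble(candidates)
  n <- nrow(cand)
  if (n == 0L) {
    return(mutate(cand,
      target_seq_40 = character(), gc_fraction = numeric(),
      pass = logical(), failures = list()
    ))
  }
  glen <- nchar(genome)[cand$chrom]
  if (any(cand$anchor_start < 0L | cand$anchor_start + pl > glen)) {
    abort("candidate anchor outside the genome")
  }
  fwd <- unname(substring(
    genome[cand$chrom], cand$anchor_start + 1L, cand$anchor_start + pl
  ))
  has_n <- grepl("N", fwd, fixed = TRUE)
  seq40 <- fwd
  neg <- cand$strand == "-"
  if (any(neg & !has_n)) seq40[neg & !has_n] <- revcomp(fwd[neg & !has_n])
  gc <- rep(NA_real_, n)
  gc[!has_n] <- gc_content(seq40[!has_n])

  term_pos <- ifelse(cand$strand == "+",
    cand$anchor_start + pl - params$terminal_k, cand$anchor_start
  )
  term_code <- track_lookup(track, cand$chrom, term_pos)
  term_code[is.na(term_code)] <- "AMBIGUOUS"

  snp_fail <- rep(FALSE, n)
  if (!is.null(snps) && nrow(as_tibble(snps)) > 0) {
    snps <- as_tibble(snps)
    ti <- terminal_interval(
      cand$anchor_start, cand$strand, pl, params$snp_exclusion_len
    )
    snp_fail <- vapply(seq_len(n), function(i) {
      any(snps$chrom == cand$chrom[i] &
        snps$pos >= ti[i, "lo"] & snps$pos < ti[i, "hi"])
    }, logical(1))
  }

  ral <- params$repeat_adjacent_len
  rep_base <- ifelse(cand$strand == "+",
    cand$anchor_start + pl, cand$anchor_start - ral
  )
  rep_pos <- rep(rep_base, each = ral) + rep.int(seq_len(ral) - 1L, n)
  rep_codes <- track_lookup(track, rep(cand$chrom, each = ral), rep_pos)
  rep_fail <- colSums(
    matrix(!is.na(rep_codes) & rep_codes == "REPETITIVE", nrow = ral)
  ) > 0

  failures <- lapply(seq_len(n), function(i) {
    f <- character()
    if (has_n[i]) f <- c(f, "CONTAINS_N")
    if (!has_n[i] && (gc[i] < params$gc_min || gc[i] > params$gc_max)) {
      f <- c(f, "GC_RANGE")
    }
    if (term_code[i] != "UNIQUE_D1") f <- c(f, "KMER_NOT_UNIQUE")
    if (snp_fail[i]) f <- c(f, "SNP_IN_TERMINAL_10")
    if (rep_fail[i]) f <- c(f, "REPEAT_ADJACENT")
    f
  })
  mutate(cand,
    target_seq_40 = ifelse(has_n, NA_character_, seq40),
    gc_fraction = gc,
    pass = lengths(failures) == 0L,
    failures = failures
  )
}

check_track <- function(track, params) {
  if (!inherits(track, "kmer_track")) abort("`track` must be a kmer_track")
  if (attr(track, "k") != params$terminal_k) {
    abort("track k does not match params$terminal_k")
  }
  if (attr(track, "margin") != params$uniqueness_margin) {
    abort("track margin does not match params$uniqueness_margin")
  }
  invisible(track)
}

#' Placement slots for a target
#'
#' Enumerates the anchor-start windows the designer will try to fill for an
#' interval, SNP or breakpoint target. Exposed so that exhaustive enumeration
#' oracles can reason about exactly the same geometry as the designer.
#'
#' @param target One-row tibble with `chrom`, `start`, `end`, `target_class`
#'   (`EXON`, `LOCUS`, `SNP` or `BREAKPOINT`) and `label`. SNP targets have
#'   `end == start + 1`; breakpoint targets use `start` as the junction
#'   coordinate.
#' @param genome_len Length of the target's sequence.
#' @param params [design_params()].
#' @return Tibble with columns `slot`, `strand`, `lo`, `hi` (inclusive
#'   anchor-start bounds), `nominal`, and `feasible` (FALSE when the window is
#'   clipped away by the genome boundary).
#' @export
placement_slots <- function(target, genome_len, params = design_params()) {
  pl <- params$probe_len
  cls <- target$target_class
  t0 <- target$start
  t1 <- target$end
  slots <- if (cls %in% c("EXON", "LOCUS")) {
    s <- tibble(
      slot = c("flank_up", "flank_dn"),
      strand = c("+", "-"),
      lo = c(t0 - params$flank_hi - pl, t1 + params$flank_lo),
      hi = c(t0 - params$flank_lo - pl, t1 + params$flank_hi),
      nominal = as.integer(c(
        t0 - (params$flank_lo + params$flank_hi) / 2 - pl,
        t1 + (params$flank_lo + params$flank_hi) / 2
      ))
    )
    if (t1 - t0 > params$tile_spacing) {
      nom <- seq.int(t0, t1 - pl, by = params$tile_spacing)
      tiles <- tibble(
        slot = paste0(
          "tile", rep(seq_along(nom), 2), "_",
          rep(c("fwd", "rev"), each = length(nom))
        ),
        strand = rep(c("+", "-"), each = length(nom)),
        lo = rep(nom - params$search_halfwidth, 2),
        hi = rep(nom + params$search_halfwidth, 2),
        nominal = rep(as.integer(nom), 2)
      )
      s <- bind_rows(s, tiles)
    }
    s
  } else if (cls == "SNP") {
    pos <- t0
    tibble(
      slot = c("snp_up", "snp_dn"),
      strand = c("+", "-"),
      lo = c(pos - params$flank_hi - pl, pos + 1L + params$flank_lo),
      hi = c(pos - params$flank_lo - pl, pos + 1L + params$flank_hi),
      nominal = as.integer(c(
        pos - (params$flank_lo + params$flank_hi) / 2 - pl,
        pos + 1L + (params$flank_lo + params$flank_hi) / 2
      ))
    )
  } else if (cls == "BREAKPOINT") {
    pos <- t0
    n_side <- max(1L, params$probes_per_breakpoint %/% 2L)
    edges <- seq(params$bp_dist_lo, params$bp_dist_hi, length.out = n_side + 1L)
    sub_lo <- as.integer(floor(edges[-length(edges)]))
    sub_hi <- as.integer(floor(edges[-1]))
    tibble(
      slot = c(paste0("L", seq_len(n_side)), paste0("R", seq_len(n_side))),
      strand = rep(c("+", "-"), each = n_side),
      lo = c(pos - sub_hi - pl, pos + sub_lo),
      hi = c(pos - sub_lo - pl, pos + sub_hi),
      nominal = as.integer(c(
        pos - (sub_lo + sub_hi) / 2 - pl, pos + (sub_lo + sub_hi) / 2
      ))
    )
  } else {
    abort(paste0("unknown target_class: ", cls))
  }
  slots |>
    mutate(
      lo = pmax(.data$lo, 0L),
      hi = pmin(.data$hi, genome_len - pl),
      feasible = .data$lo <= .data$hi
    )
}

# fill one slot: candidates ordered by distance from nominal, first passing
fill_slot <- function(slot_row, target, genome, track, snps, params) {
  if (!slot_row$feasible) {
    return(list(probe = NULL, gap = gap_row(slot_row, target, "OUTSIDE_GENOME")))
  }
  starts <- seq.int(slot_row$lo, slot_row$hi)
  ord <- order(abs(starts - slot_row$nominal), starts)
  starts <- starts[ord]
  cand <- tibble(
    chrom = target$chrom, anchor_start = as.integer(starts),
    strand = slot_row$strand
  )
  dec <- candidate_passes_filters(cand, genome, track, snps, params)
  hit <- which(dec$pass)
  if (length(hit) == 0L) {
    return(list(
      probe = NULL,
      gap = gap_row(slot_row, target, "NO_PASSING_CANDIDATE")
    ))
  }
  i <- hit[1]
  probe <- tibble(
    probe_id = paste(target$label, slot_row$slot, sep = "_"),
    chrom = target$chrom,
    anchor_start = dec$anchor_start[i],
    anchor_end = dec$anchor_start[i] + params$probe_len,
    strand = dec$strand[i],
    target_seq_40 = dec$target_seq_40[i],
    gc_fraction = dec$gc_fraction[i],
    oligo_101 = assemble_oligo(
      dec$target_seq_40[i], params$universal_mid, params$p7_complement
    ),
    parent_target = target$label,
    slot = slot_row$slot
  )
  list(probe = probe, gap = NULL)
}

gap_row <- function(slot_row, target, reason) {
  tibble(
    parent_target = target$label, slot = slot_row$slot,
    strand = slot_row$strand, window_lo = slot_row$lo,
    window_hi = slot_row$hi, reason = reason
  )
}

new_design <- function(probes, gaps, params) {
  empty_probes <- tibble(
    probe_id = character(), chrom = character(), anchor_start = integer(),
    anchor_end = integer(), strand = character(), target_seq_40 = character(),
    gc_fraction = numeric(), oligo_101 = character(),
    parent_target = character(), slot = character()
  )
  empty_gaps <- tibble(
    parent_target = character(), slot = character(), strand = character(),
    window_lo = integer(), window_hi = integer(), reason = character()
  )
  structure(
    list(
      probes = if (is.null(probes) || ncol(probes) == 0L) empty_probes else probes,
      gaps = if (is.null(gaps) || ncol(gaps) == 0L) empty_gaps else gaps,
      params = params
    ),
    class = "osseq_design"
  )
}

design_slots <- function(target, genome, track, snps, params) {
  slots <- placement_slots(target, nchar(genome[[target$chrom]]), params)
  res <- lapply(seq_len(nrow(slots)), function(i) {
    fill_slot(slots[i, ], target, genome, track, snps, params)
  })
  new_design(
    bind_rows(lapply(res, `[[`, "probe")),
    bind_rows(lapply(res, `[[`, "gap")),
    params
  )
}

#' Design primer probes for an interval target
#'
#' Places a pair of flanking probes (one upstream on the forward strand, one
#' downstream on the reverse strand, extension reading into the target, each
#' 100-200 bases from the target boundary) and, for targets longer than the
#' tile spacing, additional probes on both strands approximately every
#' `tile_spacing` bases. Every emitted probe passes
#' [candidate_passes_filters()]; unfillable windows are reported as design
#' gaps, never as errors.
#'
#' A `+` probe's 40-mer equals the forward reference at its anchor and
#' extension proceeds toward increasing coordinates; a `-` probe's 40-mer is
#' the reverse complement and extension proceeds toward decreasing
#' coordinates. The terminal 20-mer/10 bases referenced by the uniqueness and
#' SNP rules are at the extension-proximal end of the synthesized 40-mer.
#'
#' @param target One-row tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `label`; `target_class` defaults to `LOCUS`.
#' @inheritParams candidate_passes_filters
#' @return An `osseq_design`: list with tibbles `probes` and `gaps` plus the
#'   params used. [generics::tidy()] returns the probe catalog.
#' @export
design_for_interval <- function(target, genome, track, snps = NULL,
                                params = design_params()) {
  genome <- as_genome(genome)
  target <- as_tibble(target)
  if (!"target_class" %in% names(target)) target$target_class <- "LOCUS"
  if (!"label" %in% names(target)) target$label <- "target"
  stopifnot(nrow(target) == 1L, target$start < target$end)
  design_slots(target, genome, track, snps, params)
}

#' Design the probe pair selecting a SNP position
#'
#' One probe per strand whose extension reads across the SNP, anchored
#' 100-200 bases away; the targeted SNP can never lie under a probe's
#' terminal bases because anchors never overlap it.
#'
#' @param position 0-based SNP coordinate.
#' @param chrom Sequence name.
#' @param label Target label (default `"snp_<pos>"`).
#' @inheritParams candidate_passes_filters
#' @return An `osseq_design`.
#' @export
design_for_snp <- function(position, chrom, genome, track, snps = NULL,
                           params = design_params(),
                           label = paste0("snp_", position)) {
  genome <- as_genome(genome)
  target <- tibble(
    chrom = chrom, start = as.integer(position),
    end = as.integer(position) + 1L, target_class = "SNP", label = label
  )
  design_slots(target, genome, track, snps, params)
}

#' Design probes flanking a putative structural variant
#'
#' For each of the candidate's two breakpoints, places
#' `probes_per_breakpoint` probes split between the two flanks, on opposing
#' strands, anchored 150-300 bases from the putative junction with extension
#' oriented toward it. Probes falling in repetitive or otherwise filtered
#' sequence yield design gaps.
#'
#' @param sv One-row tibble: `chrom1`, `pos1`, `chrom2`, `pos2` (0-based
#'   junction coordinates) and `label`.
#' @inheritParams candidate_passes_filters
#' @return An `osseq_design`; probe ids carry the breakpoint (`bp1`/`bp2`)
#'   and slot, and an added `locus` column ties all probes to `sv$label`.
#' @export
design_for_breakpoint <- function(sv, genome, track, snps = NULL,
                                  params = design_params()) {
  genome <- as_genome(genome)
  sv <- as_tibble(sv)
  stopifnot(nrow(sv) == 1L)
  if (!"label" %in% names(sv)) sv$label <- paste0("sv_", sv$pos1)
  parts <- lapply(1:2, function(b) {
    target <- tibble(
      chrom = sv[[paste0("chrom", b)]],
      start = as.integer(sv[[paste0("pos", b)]]),
      end = as.integer(sv[[paste0("pos", b)]]) + 1L,
      target_class = "BREAKPOINT",
      label = paste0(sv$label, "_bp", b)
    )
    design_slots(target, genome, track, snps, params)
  })
  d <- new_design(
    bind_rows(lapply(parts, function(p) p$probes)),
    bind_rows(lapply(parts, function(p) p$gaps)),
    params
  )
  if (nrow(d$probes) > 0) d$probes$locus <- sv$label
  if (nrow(d$gaps) > 0) d$gaps$locus <- sv$label
  d
}

#' Design probes for a table of targets
#'
#' Dispatches each row of `targets` on `target_class` (`EXON`/`LOCUS` to
#' [design_for_interval()], `SNP` to [design_for_snp()]) and combines the
#' results.
#'
#' @param targets Tibble with `chrom`, `start`, `end`, `target_class`,
#'   `label`.
#' @inheritParams candidate_passes_filters
#' @return An `osseq_design`.
#' @export
design_targets <- function(targets, genome, track, snps = NULL,
                           params = design_params()) {
  targets <- as_tibble(targets)
  parts <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    if (tg$target_class == "SNP") {
      design_for_snp(tg$start, tg$chrom, genome, track, snps, params,
        label = tg$label
      )
    } else {
      design_for_interval(tg, genome, track, snps, params)
    }
  })
  new_design(
    bind_rows(lapply(parts, function(p) p$probes)),
    bind_rows(lapply(parts, function(p) p$gaps)),
    params
  )
}

#' Assemble the synthesized 101-mer oligo
#'
#' The full oligo is the target-specific 40-mer followed by a universal
#' read-primer segment and a segment complementary to the P7 lawn primer; the
#' two universal segments must total 61 bases so the oligo is exactly 101.
#'
#' @param target_seq_40 Character vector of 40-mers (as synthesized).
#' @param universal_mid,p7_complement Universal segments.
#' @return Character vector of 101-mers.
#' @export
assemble_oligo <- function(target_seq_40,
                           universal_mid = universal_segments()$universal_mid,
                           p7_complement = universal_segments()$p7_complement) {
  if (any(nchar(target_seq_40) != 40L)) {
    abort("target_seq_40 must be exactly 40 bases")
  }
  if (nchar(universal_mid) + nchar(p7_complement) != 61L) {
    abort("universal segments must total 61 bases")
  }
  paste0(target_seq_40, universal_mid, p7_complement)
}

#' Probe density over a target set
#'
#' @param probes Probe catalog tibble (or `osseq_design`).
#' @param targets Target tibble with `start`, `end`.
#' @return Probes per kilobase of target.
#' @export
probe_density <- function(probes, targets) {
  if (inherits(probes, "osseq_design")) probes <- probes$probes
  targets <- as_tibble(targets)
  if (nrow(targets) == 0L) abort("targets must be non-empty")
  kb <- sum(targets$end - targets$start) / 1000
  nrow(probes) / kb
}

#' @export
print.osseq_design <- function(x, ...) {
  cat(sprintf(
    "<osseq_design> %d probes (%d gaps) over %d target(s)\n",
    nrow(x$probes), nrow(x$gaps),
    length(unique(x$probes$parent_target))
  ))
  invisible(x)
}
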