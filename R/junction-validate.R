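#' Junction representation and canonical form
#'
#' A breakpoint junction fuses two reference segments. It is represented by
#' the tuple `(chrom1, pos1, strand1, chrom2, pos2, strand2)` with 0-based
#' boundary coordinates: segment 1 approaches the junction reading toward
#' `pos1` (on `+` it occupies `[.., pos1)`; on `-` it occupies `[pos1, ..)`
#' read as reverse complement), segment 2 leaves the junction from `pos2`
#' (on `+` it occupies `[pos2, ..)`; on `-` it occupies `[.., pos2)` read as
#' reverse complement). A simple deletion of `[a, b)` is
#' `(chrom, a, "+", chrom, b, "+")`.
#'
#' Microhomology at the junction makes this representation non-unique: the
#' fused sequence is unchanged when a shared base is moved across the
#' junction. [canonicalize_junction()] enumerates every equivalent
#' representation (shifts across the homology tract and the orientation
#' flip that reads the junction from the other side) and returns the
#' lexicographically smallest `(chrom1, pos1, chrom2, pos2, strand1,
#' strand2)`, so that calls and truth coordinates can be compared exactly.
#'
#' @param reference Reference genome.
#' @param junction One-row tibble (or named list) with `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`.
#' @param max_shift Safety bound on homology shifts (default 500).
#' @return One-row tibble in canonical form.
#' @export
canonicalize_junction <- function(reference, junction, max_shift = 500L) {
  reference <- as_genome(reference)
  j <- as.list(junction)
  reps <- junction_equivalents(reference, j, max_shift)
  ord <- order(
    vapply(reps, `[[`, character(1), "chrom1"),
    vapply(reps, `[[`, numeric(1), "pos1"),
    vapply(reps, `[[`, character(1), "chrom2"),
    vapply(reps, `[[`, numeric(1), "pos2"),
    vapply(reps, `[[`, character(1), "strand1"),
    vapply(reps, `[[`, character(1), "strand2")
  )
  as_tibble(reps[[ord[1]]])
}

comp_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

char_at <- function(seq, i) {
  if (i < 0L || i >= nchar(seq)) return(NA_character_)
  substr(seq, i + 1L, i + 1L)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

flip_junction <- function(j) {
  list(
    chrom1 = j$chrom2, pos1 = j$pos2, strand1 = flip_strand(j$strand2),
    chrom2 = j$chrom1, pos2 = j$pos1, strand2 = flip_strand(j$strand1)
  )
}

# last base segment 1 contributes before the junction
junction_lastchar1 <- function(ref, j) {
  s <- ref[[j$chrom1]]
  if (j$strand1 == "+") char_at(s, j$pos1 - 1L) else comp_base(char_at(s, j$pos1))
}

# first base segment 2 contributes after the junction
junction_firstchar2 <- function(ref, j) {
  s <- ref[[j$chrom2]]
  if (j$strand2 == "+") char_at(s, j$pos2) else comp_base(char_at(s, j$pos2 - 1L))
}

# move the boundary one base left (seg1's last base reassigned to seg2)
shift_junction_left <- function(ref, j) {
  b <- junction_lastchar1(ref, j)
  if (is.na(b)) return(NULL)
  s2 <- ref[[j$chrom2]]
  ext <- if (j$strand2 == "+") {
    char_at(s2, j$pos2 - 1L)
  } else {
    comp_base(char_at(s2, j$pos2))
  }
  if (is.na(ext) || ext != b) return(NULL)
  j$pos1 <- j$pos1 + if (j$strand1 == "+") -1L else 1L
  j$pos2 <- j$pos2 + if (j$strand2 == "+") -1L else 1L
  j
}

# move the boundary one base right (seg2's first base reassigned to seg1)
shift_junction_right <- function(ref, j) {
  b <- junction_firstchar2(ref, j)
  if (is.na(b)) return(NULL)
  s1 <- ref[[j$chrom1]]
  ext <- if (j$strand1 == "+") {
    char_at(s1, j$pos1)
  } else {
    comp_base(char_at(s1, j$pos1 - 1L))
  }
  if (is.na(ext) || ext != b) return(NULL)
  j$pos1 <- j$pos1 + if (j$strand1 == "+") 1L else -1L
  j$pos2 <- j$pos2 + if (j$strand2 == "+") 1L else -1L
  j
}

junction_equivalents <- function(ref, j, max_shift = 500L) {
  base <- list(j)
  cur <- j
  for (i in seq_len(max_shift)) {
    cur <- shift_junction_left(ref, cur)
    if (is.null(cur)) break
    base[[length(base) + 1L]] <- cur
  }
  cur <- j
  for (i in seq_len(max_shift)) {
    cur <- shift_junction_right(ref, cur)
    if (is.null(cur)) break
    base[[length(base) + 1L]] <- cur
  }
  c(base, lapply(base, flip_junction))
}

junction_key <- function(j) {
  sprintf(
    "%s:%d:%s|%s:%d:%s",
    j$chrom1, j$pos1, j$strand1, j$chrom2, j$pos2, j$strand2
  )
}

common_prefix_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0L) n else d[1] - 1L
}

common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a))
  rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0L) n else d[1] - 1L
}

# exact occurrences (0-based starts) of pattern in each reference sequence
pattern_hits <- function(pattern, reference) {
  out <- list()
  for (ch in names(reference)) {
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(reference[[ch]]))
    if (length(m) > 0L) {
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = Biostrings::start(m) - 1L
      )
    }
  }
  bind_rows(out)
}

#' Validate a contig as a breakpoint junction by split alignment
#'
#' Searches for a representation `contig = prefix . suffix` in which prefix
#' and suffix each align exactly to the reference (either strand, anchors of
#' at least `min_anchor` bases) at discontinuous locations: seeds taken from
#' the contig ends are located exactly and extended. A contig matching the
#' reference contiguously is rejected `FULLY_REFERENCE`; a split whose
#' segments land off the expected chromosome is rejected `WRONG_CHROM`; a
#' junction also derivable from the matched normal's contigs is reported
#' with reason `GERMLINE` and `somatic = FALSE`; otherwise the canonical
#' junction is returned as an accepted call. When microhomology makes the
#' split ambiguous the reported split maximizes matched bases with the
#' smallest `pos1` (canonical form), and the homology length is recorded.
#'
#' @param contig Contig sequence (character scalar).
#' @param reference Reference genome.
#' @param normal_contigs Optional character vector of matched-normal contigs.
#' @param expected_chrom Optional chromosome both segments must lie on.
#' @param min_anchor Minimum exact anchor on each side (default 20).
#' @return One-row tibble: `status`, `reason`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `sv_type`, `homology_len`, `somatic`,
#'   `contig`.
#' @export
validate_contig <- function(contig, reference, normal_contigs = NULL,
                            expected_chrom = NULL, min_anchor = 20L) {
  reference <- as_genome(reference)
  len <- nchar(contig)
  rejection <- function(reason) {
    tibble(
      status = "REJECT", reason = reason,
      chrom1 = NA_character_, pos1 = NA_integer_, strand1 = NA_character_,
      chrom2 = NA_character_, pos2 = NA_integer_, strand2 = NA_character_,
      sv_type = NA_character_, homology_len = NA_integer_,
      somatic = NA, contig = contig
    )
  }
  if (len < 2L * min_anchor) return(rejection("NO_SPLIT"))
  rc_contig <- revcomp(contig)
  full_hit <- any(vapply(names(reference), function(ch) {
    grepl(contig, reference[[ch]], fixed = TRUE) ||
      grepl(rc_contig, reference[[ch]], fixed = TRUE)
  }, logical(1)))
  if (full_hit) return(rejection("FULLY_REFERENCE"))

  splits <- contig_splits(contig, reference, min_anchor)
  if (nrow(splits) == 0L) return(rejection("NO_SPLIT"))
  if (!is.null(expected_chrom)) {
    on_chrom <- splits$chrom1 == expected_chrom & splits$chrom2 == expected_chrom
    if (!any(on_chrom)) return(rejection("WRONG_CHROM"))
    splits <- splits[on_chrom, ]
  }
  # canonicalize each candidate split and take the smallest
  canon <- lapply(seq_len(nrow(splits)), function(i) {
    canonicalize_junction(reference, splits[i, c(
      "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2"
    )])
  })
  ord <- order(
    vapply(canon, function(x) x$chrom1, character(1)),
    vapply(canon, function(x) x$pos1, numeric(1)),
    vapply(canon, function(x) x$chrom2, character(1)),
    vapply(canon, function(x) x$pos2, numeric(1))
  )
  best <- canon[[ord[1]]]
  hom <- splits$homology_len[ord[1]]
  somatic <- TRUE
  reason <- NA_character_
  if (!is.null(normal_contigs) && length(normal_contigs) > 0L) {
    normal_keys <- unlist(lapply(normal_contigs, function(nc) {
      s <- contig_splits(nc, reference, min_anchor)
      if (nrow(s) == 0L) return(character())
      vapply(seq_len(nrow(s)), function(i) {
        junction_key(canonicalize_junction(reference, s[i, c(
          "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2"
        )]))
      }, character(1))
    }))
    if (junction_key(best) %in% normal_keys) {
      somatic <- FALSE
      reason <- "GERMLINE"
    }
  }
  sv_type <- if (best$strand1 != best$strand2) {
    "INV"
  } else if (best$chrom1 != best$chrom2) {
    "TRA"
  } else if (best$pos1 < best$pos2) "DEL" else "DUP"
  tibble(
    status = if (is.na(reason)) "ACCEPT" else "REJECT",
    reason = reason,
    chrom1 = best$chrom1, pos1 = as.integer(best$pos1), strand1 = best$strand1,
    chrom2 = best$chrom2, pos2 = as.integer(best$pos2), strand2 = best$strand2,
    sv_type = sv_type, homology_len = as.integer(hom),
    somatic = somatic, contig = contig
  )
}

# enumerate split representations prefix.suffix with exact anchored segments
contig_splits <- function(contig, reference, min_anchor = 20L) {
  len <- nchar(contig)
  seed1 <- substr(contig, 1L, min_anchor)
  seed2 <- substr(contig, len - min_anchor + 1L, len)
  pref <- list()
  # prefix anchors: forward
  h1 <- pattern_hits(seed1, reference)
  for (i in seq_len(nrow(h1))) {
    ch <- h1$chrom[i]
    a <- h1$start[i]
    refseg <- substr(reference[[ch]], a + 1L, min(nchar(reference[[ch]]), a + len))
    e1 <- common_prefix_len(contig, refseg)
    pref[[length(pref) + 1L]] <- tibble(chrom = ch, strand = "+", anchor = a, e1 = e1)
  }
  # prefix anchors: reverse (contig prefix is rc of reference)
  h1r <- pattern_hits(revcomp(seed1), reference)
  for (i in seq_len(nrow(h1r))) {
    ch <- h1r$chrom[i]
    h <- h1r$start[i] + min_anchor - 1L # ref pos of contig[0]
    lo <- max(0L, h - len + 1L)
    refseg <- revcomp(substr(reference[[ch]], lo + 1L, h + 1L))
    e1 <- common_prefix_len(contig, refseg)
    pref[[length(pref) + 1L]] <- tibble(chrom = ch, strand = "-", anchor = h, e1 = e1)
  }
  suf <- list()
  # suffix anchors: forward
  h2 <- pattern_hits(seed2, reference)
  for (i in seq_len(nrow(h2))) {
    ch <- h2$chrom[i]
    r <- h2$start[i] # ref pos of contig[len - min_anchor]
    hi <- r + min_anchor
    lo <- max(0L, hi - len)
    refseg <- substr(reference[[ch]], lo + 1L, hi)
    b2 <- common_suffix_len(contig, refseg)
    suf[[length(suf) + 1L]] <- tibble(chrom = ch, strand = "+", anchor = r, b2 = b2)
  }
  # suffix anchors: reverse
  h2r <- pattern_hits(revcomp(seed2), reference)
  for (i in seq_len(nrow(h2r))) {
    ch <- h2r$chrom[i]
    u <- h2r$start[i] # ref pos paired with contig[len-1]
    refseg <- revcomp(substr(
      reference[[ch]], u + 1L, min(nchar(reference[[ch]]), u + len)
    ))
    b2 <- common_suffix_len(contig, refseg)
    suf[[length(suf) + 1L]] <- tibble(chrom = ch, strand = "-", anchor = u, b2 = b2)
  }
  pref <- bind_rows(pref)
  suf <- bind_rows(suf)
  out <- list()
  for (i in seq_len(nrow(pref))) {
    for (jj in seq_len(nrow(suf))) {
      p <- pref[i, ]
      s <- suf[jj, ]
      j_lo <- max(len - s$b2, min_anchor)
      j_hi <- min(p$e1, len - min_anchor)
      if (j_lo > j_hi) next
      # skip the contiguous (same alignment) pairing
      if (p$strand == "+" && s$strand == "+" &&
        p$anchor == s$anchor + min_anchor - len) {
        next
      }
      if (p$strand == "-" && s$strand == "-" &&
        p$anchor + 1L == s$anchor + len) {
        next
      }
      j <- j_lo
      pos1 <- if (p$strand == "+") p$anchor + j else p$anchor - j + 1L
      pos2 <- if (s$strand == "+") {
        s$anchor + min_anchor - len + j
      } else {
        s$anchor + len - j
      }
      out[[length(out) + 1L]] <- tibble(
        chrom1 = p$chrom, pos1 = as.integer(pos1), strand1 = p$strand,
        chrom2 = s$chrom, pos2 = as.integer(pos2), strand2 = s$strand,
        homology_len = as.integer(p$e1 - (len - s$b2))
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      chrom1 = character(), pos1 = integer(), strand1 = character(),
      chrom2 = character(), pos2 = integer(), strand2 = character(),
      homology_len = integer()
    ))
  }
  distinct(bind_rows(out))
}

#' Probe-grouped breakpoint calling pipeline
#'
#' Runs the full resolution chain for tumor/normal read sets against a
#' breakpoint probe catalog: Read 2 probe assignment, locus grouping,
#' assembly-read filtering (quality, reference match, primer 2), local de
#' Bruijn assembly, and contig validation with germline subtraction. Every
#' locus is summarized whether or not it produced a call.
#'
#' @param probes Probe catalog with a `locus` (or `locus_id`) column, e.g.
#'   from [design_for_breakpoint()].
#' @param tumor_reads,normal_reads Read tibbles (as from
#'   [simulate_capture()] or built from FASTQ input).
#' @param reference Reference genome.
#' @param expected_chroms Optional named character vector mapping locus id
#'   to the expected chromosome (defaults to each locus's probe chromosome
#'   when unique).
#' @param k,min_contig_len,min_coverage,kmer_min_count Assembly parameters
#'   (see [assemble_locus()]).
#' @param min_anchor Split-validation anchor (default 20).
#' @param prefix_len,max_mismatch Probe-assignment parameters (see
#'   [assign_probe()]).
#' @return List with `calls` (validated tumor junctions, somatic and
#'   germline), `normal_calls` (junctions validated from the normal),
#'   `summary` (per locus: read and contig counts per sample).
#' @export
call_breakpoints <- function(probes, tumor_reads, normal_reads, reference,
                             expected_chroms = NULL,
                             k = 19L, min_contig_len = 50L, min_coverage = 4,
                             kmer_min_count = 2L, min_anchor = 20L,
                             prefix_len = 20L, max_mismatch = 1L) {
  probes <- as_tibble(probes)
  if (!"locus" %in% names(probes) && "locus_id" %in% names(probes)) {
    probes$locus <- probes$locus_id
  }
  reference <- as_genome(reference)
  prep <- function(reads) {
    reads <- as_tibble(reads)
    reads$probe_id <- assign_probe(reads$read2_seq, probes,
      prefix_len = prefix_len, max_mismatch = max_mismatch
    )
    build_locus_groups(
      reads, probes |> select("probe_id", locus_id = "locus")
    )
  }
  t_groups <- prep(tumor_reads)
  n_groups <- prep(normal_reads)
  loci <- unique(probes$locus)
  if (is.null(expected_chroms)) {
    expected_chroms <- vapply(loci, function(l) {
      ch <- unique(probes$chrom[probes$locus == l])
      if (length(ch) == 1L) ch else NA_character_
    }, character(1))
    names(expected_chroms) <- loci
  }
  calls <- list()
  normal_calls <- list()
  summary_rows <- list()
  for (l in loci) {
    tg <- filter(t_groups, .data$locus_id == l)
    ng <- filter(n_groups, .data$locus_id == l)
    tf <- filter_reads_for_assembly(tg, reference = reference)
    nf <- filter_reads_for_assembly(ng, reference = reference)
    tc <- assemble_locus(tf,
      k = k, min_contig_len = min_contig_len,
      min_coverage = min_coverage, kmer_min_count = kmer_min_count
    )
    nc <- assemble_locus(nf,
      k = k, min_contig_len = min_contig_len,
      min_coverage = min_coverage, kmer_min_count = kmer_min_count
    )
    ech <- expected_chroms[[l]]
    if (nrow(tc) > 0L) {
      v <- bind_rows(lapply(tc$contig, validate_contig,
        reference = reference, normal_contigs = nc$contig,
        expected_chrom = if (is.na(ech)) NULL else ech,
        min_anchor = min_anchor
      ))
      v$locus_id <- l
      v$sample <- "tumor"
      calls[[length(calls) + 1L]] <- v
    }
    if (nrow(nc) > 0L) {
      v <- bind_rows(lapply(nc$contig, validate_contig,
        reference = reference, normal_contigs = NULL,
        expected_chrom = if (is.na(ech)) NULL else ech,
        min_anchor = min_anchor
      ))
      v$locus_id <- l
      v$sample <- "normal"
      v$somatic <- FALSE
      normal_calls[[length(normal_calls) + 1L]] <- v
    }
    summary_rows[[length(summary_rows) + 1L]] <- tibble(
      locus_id = l,
      tumor_reads = nrow(tg), normal_reads = nrow(ng),
      tumor_assembly_reads = nrow(tf), normal_assembly_reads = nrow(nf),
      tumor_contig = nrow(tc) > 0L, normal_contig = nrow(nc) > 0L
    )
  }
  list(
    calls = bind_rows(calls),
    normal_calls = bind_rows(normal_calls),
    summary = bind_rows(summary_rows)
  )
}
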