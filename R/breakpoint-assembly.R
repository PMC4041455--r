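#' Filter whole-genome SV candidates by support, germline and plausibility
#'
#' Applies the discovery-side post-filters: a candidate survives when its
#' read support reaches 20 in at least one tumor sample or 10 in both, it is
#' absent from the matched normal, its chromosomes are plausible for the
#' subject's sex (no Y involvement in a female), both junction anchors are at
#' least `min_anchor` bases, and neither anchor falls in highly repetitive
#' (masked) sequence.
#'
#' @param candidates Tibble with `chrom1`, `pos1`, `chrom2`, `pos2`, `type`,
#'   `support_tumor1`, `support_tumor2` (either may be absent: treated as 0),
#'   `in_normal` (logical) and optionally `anchor1_len`, `anchor2_len`.
#' @param sex `"male"` or `"female"`.
#' @param min_reads_single Support required in a single tumor (default 20).
#' @param min_reads_shared Support required in each of two tumors
#'   (default 10).
#' @param repeat_mask Optional tibble `chrom`, `start`, `end` of repetitive
#'   intervals (0-based half-open).
#' @param min_anchor Minimum anchor length in bases (default 20).
#' @param annotate Return all rows with `keep`/`drop_reason` instead of the
#'   filtered subset.
#' @return Filtered candidate tibble (or annotated, see `annotate`).
#' @export
filter_sv_candidates <- function(candidates, sex = c("female", "male"),
                                 min_reads_single = 20L,
                                 min_reads_shared = 10L,
                                 repeat_mask = NULL, min_anchor = 20L,
                                 annotate = FALSE) {
  sex <- match.arg(sex)
  x <- as_tibble(candidates)
  col_or <- function(nm, default) {
    if (nm %in% names(x)) x[[nm]] else rep(default, nrow(x))
  }
  t1 <- col_or("support_tumor1", 0L)
  t2 <- col_or("support_tumor2", 0L)
  support_ok <- t1 >= min_reads_single | t2 >= min_reads_single |
    (t1 >= min_reads_shared & t2 >= min_reads_shared)
  in_normal <- col_or("in_normal", FALSE)
  y_chroms <- c("chrY", "Y")
  sex_ok <- if (sex == "female") {
    !(x$chrom1 %in% y_chroms | x$chrom2 %in% y_chroms)
  } else {
    rep(TRUE, nrow(x))
  }
  a1 <- col_or("anchor1_len", min_anchor)
  a2 <- col_or("anchor2_len", min_anchor)
  anchor_ok <- a1 >= min_anchor & a2 >= min_anchor
  in_mask <- function(chrom, pos) {
    if (is.null(repeat_mask) || nrow(repeat_mask) == 0L) {
      return(rep(FALSE, length(pos)))
    }
    vapply(seq_along(pos), function(i) {
      any(repeat_mask$chrom == chrom[i] &
        repeat_mask$start < pos[i] + min_anchor &
        repeat_mask$end > pos[i] - min_anchor)
    }, logical(1))
  }
  mask_fail <- in_mask(x$chrom1, x$pos1) | in_mask(x$chrom2, x$pos2)
  reason <- rep(NA_character_, nrow(x))
  reason[!support_ok] <- "INSUFFICIENT_SUPPORT"
  reason[support_ok & in_normal] <- "GERMLINE"
  reason[support_ok & !in_normal & !sex_ok] <- "SEX_IMPLAUSIBLE"
  reason[support_ok & !in_normal & sex_ok & !anchor_ok] <- "ANCHOR_TOO_SHORT"
  reason[support_ok & !in_normal & sex_ok & anchor_ok & mask_fail] <-
    "REPEAT_MASKED"
  x <- mutate(x, keep = is.na(reason), drop_reason = reason)
  if (annotate) x else filter(x, .data$keep) |> select(-"keep", -"drop_reason")
}

#' Group probe-assigned reads into rearrangement locus groups
#'
#' Reads are partitioned by the locus of the probe their Read 2 prefix was
#' assigned to; reads with no probe assignment, or whose probe belongs to no
#' locus, are discarded. Samples stay separate through a `sample` column.
#'
#' @param reads Read tibble with a `probe_id` column (e.g. after
#'   [assign_probe()]).
#' @param probe_locus_map Tibble `probe_id`, `locus_id` (a probe catalog with
#'   a `locus` column is accepted).
#' @return `reads` with a `locus_id` column, unassigned reads dropped.
#' @export
build_locus_groups <- function(reads, probe_locus_map) {
  m <- as_tibble(probe_locus_map)
  if (!"locus_id" %in% names(m) && "locus" %in% names(m)) {
    m <- rename(m, locus_id = "locus")
  }
  m <- select(m, "probe_id", "locus_id") |> distinct()
  as_tibble(reads) |>
    filter(!is.na(.data$probe_id)) |>
    left_join(m, by = "probe_id") |>
    filter(!is.na(.data$locus_id))
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Select reads suitable for local assembly
#'
#' Retains reads with mean base quality above `min_mean_qual` that do not
#' match the reference genome and do not contain sequencing primer 2 (or its
#' reverse complement) anywhere in the read. Reference matching is tolerant,
#' mirroring aligner behavior: a read is "matching" when some reference
#' location (either strand) carries it with at most `match_max_mismatch`
#' substitutions ([reference_matches()]); alternatively an alignment table
#' with a `fully_aligned` flag may be supplied.
#'
#' @param reads Read tibble with `read_id`, `read1_seq`, `read1_qual`.
#' @param reference Reference genome (used when `alignments` is `NULL`).
#' @param alignments Optional alignment tibble with `read_id`,
#'   `fully_aligned`.
#' @param min_mean_qual Minimum mean Phred quality, exclusive (default 25).
#' @param primer2 Sequencing primer 2 (its reverse complement is also
#'   screened).
#' @param match_max_mismatch Substitutions tolerated when testing reference
#'   identity (default 3).
#' @return The retained subset of `reads`.
#' @export
filter_reads_for_assembly <- function(reads, reference = NULL,
                                      alignments = NULL,
                                      min_mean_qual = 25,
                                      primer2 = "AGATCGGAAGAGCGGT",
                                      match_max_mismatch = 3L) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) return(reads)
  keep <- mean_phred(reads$read1_qual) > min_mean_qual
  p2rc <- revcomp(primer2)
  keep <- keep & !grepl(primer2, reads$read1_seq, fixed = TRUE) &
    !grepl(p2rc, reads$read1_seq, fixed = TRUE)
  if (!is.null(alignments)) {
    al <- as_tibble(alignments)
    matched_ids <- al$read_id[al$fully_aligned]
    keep <- keep & !(reads$read_id %in% matched_ids)
  } else if (!is.null(reference)) {
    idx <- which(keep)
    if (length(idx) > 0L) {
      m <- reference_matches(reads$read1_seq[idx], reference,
        max_mismatch = match_max_mismatch
      )
      keep[idx] <- !m
    }
  } else {
    abort("supply `reference` or `alignments`")
  }
  reads[keep, ]
}

#' Does each read match the reference within a mismatch budget?
#'
#' Seed-and-verify search: each read (both orientations) is split into
#' `max_mismatch + 1` seeds of 20 bases, so any match within the budget must
#' contain one exact seed; seed hits are located with Biostrings and
#' verified by Hamming distance at the implied offset.
#'
#' @param seqs Character vector of read sequences (length >= 20).
#' @param reference Reference genome.
#' @param max_mismatch Substitutions tolerated (default 3).
#' @param seed_len Seed length (default 20).
#' @return Logical vector.
#' @export
reference_matches <- function(seqs, reference, max_mismatch = 3L,
                              seed_len = 20L) {
  reference <- as_genome(reference)
  n <- length(seqs)
  out <- rep(FALSE, n)
  if (n == 0L) return(out)
  orients <- list(fwd = seqs, rev = revcomp(seqs))
  # seed table: read index, orientation, offset, seed
  seed_tab <- list()
  for (o in names(orients)) {
    ss <- orients[[o]]
    for (i in seq_len(n)) {
      L <- nchar(ss[i])
      if (L < seed_len) next
      n_seeds <- max_mismatch + 1L
      offs <- unique(as.integer(floor(
        seq(0L, L - seed_len, length.out = n_seeds)
      )))
      seed_tab[[length(seed_tab) + 1L]] <- tibble(
        read = i, orient = o, offset = offs,
        seed = substring(ss[i], offs + 1L, offs + seed_len)
      )
    }
  }
  seed_tab <- bind_rows(seed_tab)
  if (nrow(seed_tab) == 0L) return(out)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tab$seed))
  for (ch in names(reference)) {
    subj <- Biostrings::DNAString(reference[[ch]])
    hits <- Biostrings::matchPDict(pd, subj)
    starts <- IRanges::start(hits) # list per seed
    ns <- lengths(starts)
    if (all(ns == 0L)) next
    hidx <- rep(seq_along(ns), ns)
    hpos <- unlist(starts, use.names = FALSE) - 1L
    ref_seq <- reference[[ch]]
    ref_len <- nchar(ref_seq)
    for (j in seq_along(hidx)) {
      si <- hidx[j]
      ri <- seed_tab$read[si]
      if (out[ri]) next
      rd <- orients[[seed_tab$orient[si]]][ri]
      L <- nchar(rd)
      s0 <- hpos[j] - seed_tab$offset[si]
      if (s0 < 0L || s0 + L > ref_len) next
      refsub <- substr(ref_seq, s0 + 1L, s0 + L)
      if (sum(charToRaw(rd) != charToRaw(refsub)) <= max_mismatch) {
        out[ri] <- TRUE
      }
    }
  }
  out
}

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Local de Bruijn assembly of a read set
#'
#' Builds the k-mer graph of the reads (k-mers canonicalized across strands),
#' prunes k-mers seen fewer than `kmer_min_count` times (the error-removal
#' counterpart of a coverage cutoff), and emits maximal non-branching paths
#' (unitigs). Contigs shorter than `min_contig_len` or with mean k-mer
#' coverage below `min_coverage` are suppressed.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `read1_seq` (or `seq`) column.
#' @param k k-mer length (default 19; odd k avoids palindromic k-mers).
#' @param min_contig_len Minimum contig length in bases (default 50).
#' @param min_coverage Minimum mean k-mer coverage of a contig (default 4).
#' @param kmer_min_count Minimum k-mer multiplicity retained in the graph
#'   (default 2; use 1 for error-free read sets).
#' @param min_branch_frac At a branching node, alternative edges whose k-mer
#'   count is below this fraction of the dominant alternative are treated as
#'   sequencing noise and removed (default 0.1; equal-coverage branches are
#'   never pruned, so genuine allelic branches survive).
#' @return Tibble of contigs: `contig` (canonical orientation), `length`,
#'   `mean_coverage`.
#' @export
assemble_locus <- function(reads, k = 19L, min_contig_len = 50L,
                           min_coverage = 4, kmer_min_count = 2L,
                           min_branch_frac = 0.1) {
  if (is.data.frame(reads)) {
    col <- intersect(c("read1_seq", "seq"), names(reads))[1]
    if (is.na(col)) abort("reads tibble needs a read1_seq or seq column")
    reads <- reads[[col]]
  }
  empty <- tibble(
    contig = character(), length = integer(), mean_coverage = numeric()
  )
  reads <- reads[!is.na(reads) & nchar(reads) >= k]
  if (length(reads) == 0L) return(empty)
  kmers <- unlist(lapply(reads, seq_windows, k = k), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) return(empty)
  counts <- table(canonical_kmer(kmers))
  counts <- counts[counts >= kmer_min_count]
  if (length(counts) == 0L) return(empty)
  canon <- names(counts)
  cnt <- as.integer(counts)
  oriented <- unique(c(canon, revcomp(canon)))
  # adjacency: which single-base extensions are present
  succ_of <- function(nodes) {
    suf <- substr(nodes, 2L, k)
    cand <- paste0(rep(suf, each = 4L), c("A", "C", "G", "T"))
    keep <- canonical_kmer(cand) %in% canon
    split(cand[keep], rep(seq_along(nodes), each = 4L)[keep])
  }
  pred_of <- function(nodes) {
    pre <- substr(nodes, 1L, k - 1L)
    cand <- paste0(rep(c("A", "C", "G", "T"), times = length(nodes)),
      rep(pre, each = 4L)
    )
    keep <- canonical_kmer(cand) %in% canon
    split(cand[keep], rep(seq_along(nodes), each = 4L)[keep])
  }
  succs <- succ_of(oriented)
  preds <- pred_of(oriented)
  node_index <- stats::setNames(seq_along(oriented), oriented)
  cnt_of <- function(x) cnt[match(canonical_kmer(x), canon)]
  # drop edges far below the dominant alternative (sequencing noise)
  dominant <- function(lst) {
    lapply(lst, function(v) {
      if (length(v) < 2L) return(v)
      cv <- cnt_of(v)
      v[cv >= min_branch_frac * max(cv)]
    })
  }
  succs <- dominant(succs)
  preds <- dominant(preds)
  raw_succ <- function(node) {
    s <- succs[[as.character(node_index[[node]])]]
    if (is.null(s)) character() else s
  }
  raw_pred <- function(node) {
    p <- preds[[as.character(node_index[[node]])]]
    if (is.null(p)) character() else p
  }
  # an edge survives only if both endpoints keep it
  get_succ <- function(node) {
    s <- raw_succ(node)
    s[vapply(s, function(w) node %in% raw_pred(w), logical(1))]
  }
  get_pred <- function(node) {
    p <- raw_pred(node)
    p[vapply(p, function(u) node %in% raw_succ(u), logical(1))]
  }
  outdeg <- stats::setNames(
    vapply(oriented, function(v) length(get_succ(v)), integer(1)), oriented
  )
  # a node starts a unitig when it cannot be reached by a simple edge
  is_start <- vapply(oriented, function(v) {
    pv <- get_pred(v)
    !(length(pv) == 1L && outdeg[[pv]] == 1L)
  }, logical(1))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(v) {
    path <- v
    assign(v, TRUE, envir = visited)
    repeat {
      sv <- get_succ(v)
      if (length(sv) != 1L) break
      w <- sv[[1]]
      if (length(get_pred(w)) != 1L) break
      if (!is.null(visited[[w]])) break
      path <- c(path, w)
      assign(w, TRUE, envir = visited)
      v <- w
    }
    path
  }
  paths <- list()
  for (v in oriented[is_start]) {
    if (is.null(visited[[v]])) paths[[length(paths) + 1L]] <- walk(v)
  }
  for (v in oriented) { # leftover cycles
    if (is.null(visited[[v]])) paths[[length(paths) + 1L]] <- walk(v)
  }
  if (length(paths) == 0L) return(empty)
  contigs <- vapply(paths, function(p) {
    paste0(p[1], paste(substr(p[-1], k, k), collapse = ""))
  }, character(1))
  covs <- vapply(paths, function(p) {
    mean(cnt[match(canonical_kmer(p), canon)])
  }, numeric(1))
  res <- tibble(
    contig = ifelse(contigs <= revcomp(contigs), contigs, revcomp(contigs)),
    length = nchar(contigs),
    mean_coverage = covs
  ) |>
    distinct(.data$contig, .keep_all = TRUE) |>
    filter(.data$length >= min_contig_len, .data$mean_coverage >= min_coverage) |>
    arrange(dplyr::desc(.data$length), .data$contig)
  res
}
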