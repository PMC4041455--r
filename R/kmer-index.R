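#' k-mer mapability: multiplicity, margin uniqueness and position tracks
#'
#' Probe specificity rests on the mapability of the terminal 20-mer of each
#' probe: it must occur at exactly one physical site in the genome and no other
#' site may match it within a configurable number of substitutions (the
#' "margin"). These functions build the underlying k-mer structures.
#'
#' Occurrences are counted on both strands: an occurrence of a k-mer on the
#' reverse strand is an occurrence of its reverse complement on the forward
#' strand. A k-mer equal to its own reverse complement is counted once per
#' physical site. Windows containing `N` are skipped (and classified
#' `AMBIGUOUS` in position tracks).
#'
#' @name kmer_index
NULL

KMER_CODES <- c("AMBIGUOUS", "REPETITIVE", "UNIQUE_STRICT", "UNIQUE_D1")

# forward windows per sequence with N windows set to NA
genome_windows <- function(genome, k) {
  lapply(genome, function(s) {
    w <- seq_windows(s, k)
    w[grepl("N", w, fixed = TRUE)] <- NA_character_
    w
  })
}

#' Count k-mer occurrences on both strands
#'
#' Every k-length window of every sequence (on both strands) contributes one
#' count to its literal k-mer string; windows containing `N` are skipped.
#' Equivalently, the count of k-mer `x` is the number of forward windows equal
#' to `x` plus the number equal to `revcomp(x)`, with a palindromic k-mer
#' counted once per physical site.
#'
#' @param genome Genome as accepted by [as_genome()].
#' @param k k-mer length (default 20).
#' @return A tibble with columns `kmer` and `count`, one row per distinct
#'   k-mer observed on either strand.
#' @export
build_multiplicity <- function(genome, k = 20L) {
  genome <- as_genome(genome)
  stopifnot(k >= 1L)
  if (all(nchar(genome) < k)) {
    warn("all sequences shorter than k; empty multiplicity")
    return(tibble(kmer = character(), count = integer()))
  }
  fwd <- unlist(genome_windows(genome, k), use.names = FALSE)
  fwd <- fwd[!is.na(fwd)]
  cf <- table(fwd)
  keys <- names(cf)
  rc_keys <- revcomp(keys)
  all_keys <- union(keys, rc_keys)
  cnt_of <- function(x) {
    i <- match(x, keys)
    out <- as.integer(cf)[i]
    out[is.na(out)] <- 0L
    out
  }
  rc_all <- revcomp(all_keys)
  n <- cnt_of(all_keys) + ifelse(all_keys == rc_all, 0L, cnt_of(rc_all))
  tibble(kmer = all_keys, count = as.integer(n)) |> arrange(.data$kmer)
}

#' Classify every genome position by k-mer mapability
#'
#' Each position admitting a full k-mer window is labelled:
#' * `UNIQUE_D1` — the k-mer occurs at exactly one physical site and no other
#'   site matches it within `margin_mismatches` substitutions on either strand;
#' * `UNIQUE_STRICT` — exact-unique, but another site lies within the margin;
#' * `REPETITIVE` — more than one exact site;
#' * `AMBIGUOUS` — the window contains `N`.
#'
#' With `margin_mismatches = 0` the margin test is vacuous, so every
#' exact-unique position is `UNIQUE_D1`. The near-match search enumerates the
#' Hamming neighborhood of each window against a hash of exact counts rather
#' than scanning all window pairs.
#'
#' @inheritParams build_multiplicity
#' @param margin_mismatches Mismatch margin required beyond exact uniqueness
#'   (default 1: a second site must differ by at least 2 bases).
#' @return A `kmer_track`: tibble with columns `seqname`, `pos` (0-based
#'   window start), `kmer`, `code`; attributes `k`, `margin`, `genome_digest`.
#' @export
classify_positions <- function(genome, k = 20L, margin_mismatches = 1L) {
  genome <- as_genome(genome)
  stopifnot(k >= 1L, margin_mismatches >= 0L)
  wins <- genome_windows(genome, k)
  fwd <- unlist(wins, use.names = FALSE)
  if (length(fwd) == 0L) {
    warn("no sequence admits a full k-mer window")
    track <- tibble(
      seqname = character(), pos = integer(),
      kmer = character(), code = character()
    )
  } else {
    rc <- rep(NA_character_, length(fwd))
    ok <- !is.na(fwd)
    rc[ok] <- revcomp(fwd[ok])
    codes <- cpp_classify_kmers(fwd, rc, as.integer(margin_mismatches))
    track <- tibble(
      seqname = rep(names(wins), lengths(wins)),
      pos = unlist(lapply(lengths(wins), function(n) seq_len(n) - 1L),
        use.names = FALSE
      ),
      kmer = fwd,
      code = KMER_CODES[codes + 1L]
    )
  }
  structure(track,
    class = c("kmer_track", class(track)),
    k = as.integer(k), margin = as.integer(margin_mismatches),
    genome_digest = genome_digest(genome)
  )
}

#' Is a genomic k-mer unique with a mismatch margin?
#'
#' `TRUE` iff the k-mer occurs at exactly one physical site in the genome
#' (both strands considered) and no other site matches it within
#' `margin_mismatches` substitutions.
#'
#' @param kmer k-mer string; must occur in the genome on either strand.
#' @inheritParams classify_positions
#' @return Logical scalar.
#' @export
is_unique_with_margin <- function(kmer, genome, margin_mismatches = 1L) {
  genome <- as_genome(genome)
  kmer <- toupper(kmer)
  k <- nchar(kmer)
  fwd <- unlist(genome_windows(genome, k), use.names = FALSE)
  fwd <- fwd[!is.na(fwd)]
  rc <- revcomp(kmer)
  e <- sum(fwd == kmer) + if (kmer == rc) 0L else sum(fwd == rc)
  if (e == 0L) {
    abort("k-mer does not occur in the genome; uniqueness is undefined")
  }
  if (e > 1L) return(FALSE)
  if (margin_mismatches == 0L) return(TRUE)
  nb <- unique(c(
    hamming_neighbors(kmer, margin_mismatches),
    if (kmer != rc) hamming_neighbors(rc, margin_mismatches)
  ))
  sum(fwd %in% nb) == 1L
}

# all strings within Hamming distance d of x (including x)
hamming_neighbors <- function(x, d) {
  out <- x
  frontier <- x
  for (step in seq_len(d)) {
    k <- nchar(x)
    nxt <- unlist(lapply(frontier, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      unlist(lapply(seq_len(k), function(i) {
        alt <- setdiff(c("A", "C", "G", "T"), ch[i])
        vapply(alt, function(b) {
          v <- ch
          v[i] <- b
          paste(v, collapse = "")
        }, character(1))
      }))
    }))
    frontier <- setdiff(unique(nxt), out)
    out <- c(out, frontier)
  }
  out
}

#' Write a mapability track as BED
#'
#' Consecutive positions sharing a classification are merged into one BED
#' record whose name is the classification code. Coordinates are the 0-based,
#' half-open window starts.
#'
#' @param track A `kmer_track` from [classify_positions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  runs <- track |>
    group_by(.data$seqname) |>
    mutate(run = cumsum(c(TRUE, diff(.data$pos) != 1L) |
      c(TRUE, .data$code[-1] != .data$code[-n()]))) |>
    group_by(.data$seqname, .data$run) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      name = first(.data$code), .groups = "drop"
    )
  lines <- sprintf("%s\t%d\t%d\t%s", runs$seqname, runs$start, runs$end, runs$name)
  writeLines(lines, path)
  invisible(path)
}

#' Look up track codes at positions
#'
#' @param track A `kmer_track`.
#' @param seqname Sequence name (scalar).
#' @param pos Integer vector of 0-based window starts.
#' @return Character vector of codes (`NA` outside the track).
#' @export
track_code_at <- function(track, seqname, pos) {
  track_lookup(track, rep(seqname, length(pos)), pos)
}

# vectorized (chrom, pos) -> code lookup; one scan per distinct chrom
track_lookup <- function(track, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (uc in unique(chrom)) {
    sel <- chrom == uc
    idx <- which(track$seqname == uc)
    if (length(idx) == 0L) next
    out[sel] <- track$code[idx][match(pos[sel], track$pos[idx])]
  }
  out
}
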