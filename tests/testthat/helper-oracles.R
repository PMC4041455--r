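# Brute-force oracles, independent of the package internals they check.

all_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  substring(seq, 1:(L - k + 1L), k:L)
}

# window-scan multiplicity over both strands; palindromes once per site
oracle_multiplicity <- function(genome, k) {
  genome <- as_genome(genome)
  fwd <- unlist(lapply(genome, all_windows, k = k), use.names = FALSE)
  fwd <- fwd[!grepl("N", fwd, fixed = TRUE)]
  rwin <- unlist(
    lapply(revcomp(unname(genome)), all_windows, k = k),
    use.names = FALSE
  )
  rwin <- rwin[!grepl("N", rwin, fixed = TRUE)]
  tab <- table(c(fwd, rwin))
  keys <- names(tab)
  counts <- as.integer(tab)
  pal <- keys == revcomp(keys)
  counts[pal] <- counts[pal] %/% 2L
  tibble::tibble(kmer = keys, count = counts) |> dplyr::arrange(kmer)
}

# all-pairs Hamming classification (both strands)
oracle_classify <- function(genome, k, margin) {
  genome <- as_genome(genome)
  fwd <- unlist(lapply(genome, all_windows, k = k), use.names = FALSE)
  ok <- !grepl("N", fwd, fixed = TRUE)
  idx <- which(ok)
  n <- length(idx)
  codes <- rep("AMBIGUOUS", length(fwd))
  if (n == 0L) return(codes)
  M <- do.call(rbind, strsplit(fwd[idx], "", fixed = TRUE))
  R <- do.call(rbind, strsplit(revcomp(fwd[idx]), "", fixed = TRUE))
  ham <- matrix(as.numeric(k), n, n)
  hamrc <- matrix(as.numeric(k), n, n)
  for (b in c("A", "C", "G", "T")) {
    Mb <- (M == b) * 1
    Rb <- (R == b) * 1
    ham <- ham - Mb %*% t(Mb)
    hamrc <- hamrc - Mb %*% t(Rb)
  }
  for (ii in seq_len(n)) {
    d <- pmin(ham[ii, ], hamrc[ii, ]) # best-strand distance to each site
    if (sum(d == 0) > 1L) {
      codes[idx[ii]] <- "REPETITIVE"
    } else if (sum(d <= margin) > 1L) {
      codes[idx[ii]] <- "UNIQUE_STRICT"
    } else {
      codes[idx[ii]] <- "UNIQUE_D1"
    }
  }
  codes
}

# unique-successor overlap walk; valid when the k-mer graph is a simple path
oracle_overlap_walk <- function(reads, k) {
  kmers <- unique(unlist(lapply(reads, all_windows, k = k), use.names = FALSE))
  kmers <- unique(c(kmers, revcomp(kmers)))
  succ <- function(x) {
    cand <- paste0(substr(x, 2L, k), c("A", "C", "G", "T"))
    cand[cand %in% kmers]
  }
  pred <- function(x) {
    cand <- paste0(c("A", "C", "G", "T"), substr(x, 1L, k - 1L))
    cand[cand %in% kmers]
  }
  starts <- kmers[vapply(kmers, function(x) length(pred(x)) == 0L, logical(1))]
  stopifnot(length(starts) >= 1L)
  cur <- sort(starts)[1]
  out <- cur
  repeat {
    nx <- succ(cur)
    if (length(nx) == 0L) break
    stopifnot(length(nx) == 1L)
    out <- paste0(out, substr(nx, k, k))
    cur <- nx
  }
  min(out, revcomp(out))
}

# naive per-base pileup over an interval from alignment records
oracle_pileup <- function(alns, chrom, start, end) {
  depth <- numeric(end - start)
  for (i in seq_len(nrow(alns))) {
    if (alns$chrom[i] != chrom) next
    lo <- max(alns$start[i], start)
    hi <- min(alns$end[i], end)
    if (hi > lo) depth[(lo - start + 1L):(hi - start)] <-
      depth[(lo - start + 1L):(hi - start)] + 1
  }
  depth
}

# sequence realized around a junction representation (for equivalence checks)
junction_local_seq <- function(reference, j, w = 30L) {
  reference <- as_genome(reference)
  s1 <- reference[[j$chrom1]]
  s2 <- reference[[j$chrom2]]
  left <- if (j$strand1 == "+") {
    substr(s1, j$pos1 - w + 1L, j$pos1)
  } else {
    revcomp(substr(s1, j$pos1 + 1L, j$pos1 + w))
  }
  right <- if (j$strand2 == "+") {
    substr(s2, j$pos2 + 1L, j$pos2 + w)
  } else {
    revcomp(substr(s2, j$pos2 - w + 1L, j$pos2))
  }
  paste0(left, right)
}

# two representations realize the same junction iff their fused local
# sequences coincide up to a boundary shift (microhomology) and orientation
junctions_equivalent <- function(reference, ja, jb, w = 50L, max_shift = 12L) {
  sa <- junction_local_seq(reference, as.list(ja), w)
  sb <- junction_local_seq(reference, as.list(jb), w)
  slide_match <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    a <- substr(a, 1, n)
    b <- substr(b, 1, n)
    for (d in -max_shift:max_shift) {
      if (d >= 0) {
        if (substr(a, 1 + d, n) == substr(b, 1, n - d)) return(TRUE)
      } else {
        if (substr(b, 1 - d, n) == substr(a, 1, n + d)) return(TRUE)
      }
    }
    FALSE
  }
  slide_match(sa, sb) || slide_match(sa, revcomp(sb))
}

random_genome_chr <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
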