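#' @useDynLib osseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr mutate filter select arrange left_join group_by summarise
#'   ungroup bind_rows n row_number across all_of first rename count distinct
#'   if_else slice pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median rnorm runif setNames rbinom
#' @keywords internal
"_PACKAGE"

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Normalize a genome to a named uppercase character vector
#'
#' A genome is represented throughout the package as a named character vector
#' of uppercase sequences over the alphabet A/C/G/T/N; names are the sequence
#' (chromosome/contig) identifiers. Coordinates are 0-based, half-open
#' everywhere inside the package; conversion to 1-based happens only when
#' reading or writing standard file formats.
#'
#' @param genome A named character vector, a `Biostrings::DNAStringSet`, or a
#'   single unnamed string (named `"seq1"`).
#' @return Named uppercase character vector.
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    abort("`genome` must be a character vector or DNAStringSet")
  }
  if (is.null(names(genome))) {
    if (length(genome) == 1L) {
      names(genome) <- "seq1"
    } else {
      abort("multi-sequence genomes must be named")
    }
  }
  genome <- toupper(genome)
  bad <- gsub("[ACGTN]", "", genome)
  if (any(nzchar(bad))) {
    abort(paste0(
      "non-ACGTN characters in sequence(s): ",
      paste(names(genome)[nzchar(bad)], collapse = ", ")
    ))
  }
  genome
}

#' Read / write a genome FASTA
#'
#' @param path File path.
#' @return `read_genome_fasta()` returns a named character vector (see
#'   [as_genome()]); `write_genome_fasta()` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Reverse complement of character sequences
#'
#' Vectorized over a character vector; `N` maps to `N`.
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Extract a subsequence using 0-based half-open coordinates
#'
#' @param genome Named character vector genome.
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  seqs <- genome[chrom]
  if (anyNA(seqs)) abort("unknown sequence name")
  substr(seqs, start + 1L, end)
}

# All k-length windows of one sequence, NA where the window runs off the end.
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Hamming distance between equal-length strings
#'
#' Vectorized over `x` against a single `y` (or elementwise when both have the
#' same length). Used by demultiplexing and probe assignment; exposed because
#' it is also handy when writing oracles against the package.
#'
#' @param x Character vector.
#' @param y Character scalar or vector recycled against `x`.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(x, y) {
  if (length(y) == 1L) y <- rep(y, length(x))
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer())
  if (any(nchar(x) != nchar(y))) abort("hamming(): unequal string lengths")
  mapply(function(a, b) {
    sum(charToRaw(a) != charToRaw(b))
  }, x, y, USE.NAMES = FALSE)
}

genome_digest <- function(genome) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(names(genome), genome), tmp)
  unname(tools::md5sum(tmp))
}
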