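#' @useDynLib modbarcode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Check that strings are valid nucleotide sequences
#'
#' Designed sequences (variable regions, overhangs) must be uppercase A/C/G/T;
#' templates and primers may additionally carry `N` wildcards.
#'
#' @param x character vector of sequences.
#' @param allow_n allow `N` wildcard positions.
#' @return `x`, invisibly, after validation.
#' @export
check_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("invalid nucleotide sequence (uppercase ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T",
         " only): ", paste(head(x[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  check_dna(x, allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of sequences
#'
#' @param x character vector of sequences.
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest homopolymer run
#'
#' @param x character vector of sequences.
#' @return integer vector: longest identical-base run per sequence.
#' @export
longest_run <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(0L)
    max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Enumerate all k-mers over A/C/G/T
#'
#' Returns all `4^k` sequences of length `k` in deterministic lexicographic
#' order (A < C < G < T).
#'
#' @param k word length, between 1 and 16.
#' @return character vector of `4^k` sequences.
#' @export
enumerate_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 1L || k > 16L) {
    stop("k must be a single integer in 1..16 (size limit)", call. = FALSE)
  }
  k <- as.integer(k)
  out <- ""
  for (i in seq_len(k)) {
    out <- paste0(rep(out, each = 4L), DNA_BASES)
  }
  out
}

#' Filter sequences by maximum homopolymer run
#'
#' Keeps exactly those sequences whose longest identical-base run is at most
#' `max_run`, preserving input order. The library default (`max_run = 3`)
#' removes runs of four or more identical consecutive bases.
#'
#' @param seqs character vector of sequences.
#' @param max_run maximum allowed run length (>= 1).
#' @return the retained subset of `seqs`.
#' @export
filter_homopolymers <- function(seqs, max_run = 3L) {
  if (!is.numeric(max_run) || max_run < 1L) {
    stop("max_run must be >= 1", call. = FALSE)
  }
  if (length(seqs) == 0L) return(character(0))
  pat <- sprintf("([ACGTN])\\1{%d,}", as.integer(max_run))
  seqs[!grepl(pat, seqs, perl = TRUE)]
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b sequences of equal length.
#' @return integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance requires equal-length sequences", call. = FALSE)
  }
  sum(charToRaw(a) != charToRaw(b))
}

#' Minimum Hamming distance under a +/-1 register shift
#'
#' Compares the two (k-1)-length overlaps of `a` against `b` shifted by one
#' position in either direction and returns the smaller mismatch count. This
#' guards code identifiability against a single indel shifting the register.
#'
#' @param a,b sequences of equal length k >= 2.
#' @return integer minimum shifted distance.
#' @export
shifted_hamming_min <- function(a, b) {
  k <- nchar(a)
  if (k != nchar(b)) {
    stop("shifted_hamming_min requires equal-length sequences", call. = FALSE)
  }
  if (k < 2L) stop("shifted_hamming_min requires length >= 2", call. = FALSE)
  min(
    hamming_distance(substr(a, 1L, k - 1L), substr(b, 2L, k)),
    hamming_distance(substr(a, 2L, k), substr(b, 1L, k - 1L))
  )
}

# Encode equal-length sequences as an n x k byte matrix for vectorized
# pairwise comparisons.
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(raw(0), 0, 0))
  k <- nchar(seqs[[1]])
  stopifnot(all(nchar(seqs) == k))
  m <- vapply(seqs, charToRaw, raw(k), USE.NAMES = FALSE)
  t(matrix(m, nrow = k))
}

# Hamming distances from one encoded sequence (raw vector) to each row of an
# encoded matrix.
ham_to_all <- function(row, mat) {
  if (nrow(mat) == 0L) return(integer(0))
  rowSums(mat != matrix(row, nrow(mat), length(row), byrow = TRUE))
}

# All pairwise Hamming distances of a character vector; returns a data.frame
# (i, j, d) over distinct unordered pairs.
pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), d = integer(0)))
  mat <- seq_matrix(seqs)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    out[[i]] <- data.frame(i = i, j = rest,
                           d = ham_to_all(mat[i, ], mat[rest, , drop = FALSE]))
  }
  do.call(rbind, out)
}

# Pairwise minimum shifted-register distances over distinct pairs.
pairwise_shifted <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), d = integer(0)))
  k <- nchar(seqs[[1]])
  left  <- substr(seqs, 1L, k - 1L)
  right <- substr(seqs, 2L, k)
  ml <- seq_matrix(left)
  mr <- seq_matrix(right)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    d1 <- ham_to_all(ml[i, ], mr[rest, , drop = FALSE])
    d2 <- ham_to_all(mr[i, ], ml[rest, , drop = FALSE])
    out[[i]] <- data.frame(i = i, j = rest, d = pmin(d1, d2))
  }
  do.call(rbind, out)
}

#' Heuristic cross-hybridization score
#'
#' Length of the longest contiguous stretch of `a` that is Watson-Crick
#' complementary to a contiguous stretch of reversed `b`; equivalently the
#' longest common substring of `a` and the reverse complement of `b`. Used as
#' a screening score against off-target pairing between single-stranded
#' domains; symmetric in its arguments. An external thermodynamic scorer can
#' be plugged in wherever this score is consumed (see [design_overhangs()]).
#'
#' @param a,b nucleotide sequences.
#' @return integer score (0 when no complementary stretch exists).
#' @export
cross_hybridization_score <- function(a, b) {
  x <- charToRaw(a)
  y <- charToRaw(revcomp(b))
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0L)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match <- which(y == x[i])
    if (length(match)) {
      cur[match] <- 1L + c(0L, prev)[match]
      best <- max(best, cur[match])
    }
    prev <- cur
  }
  as.integer(best)
}
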