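#' Sequencing error model
#'
#' Independent per-base substitution, insertion and deletion probabilities,
#' with an optional 4x4 row-stochastic substitution-type matrix (rows = from
#' base, zero diagonal). Indel events are applied before substitutions and
#' at most one indel event occurs per position.
#'
#' @param sub_rate,ins_rate,del_rate per-base event probabilities in [0, 1].
#' @param sub_bias optional 4x4 matrix of substitution type probabilities
#'   (dimnames A/C/G/T); default uniform over the three alternatives.
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                        sub_bias = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (is.null(sub_bias)) {
    sub_bias <- matrix(1 / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    diag(sub_bias) <- 0
  } else {
    stopifnot(is.matrix(sub_bias), all(dim(sub_bias) == 4L))
    if (is.null(dimnames(sub_bias))) {
      dimnames(sub_bias) <- list(DNA_BASES, DNA_BASES)
    }
    if (any(abs(rowSums(sub_bias) - 1) > 1e-8) || any(diag(sub_bias) != 0)) {
      stop("sub_bias rows must sum to 1 with zero diagonal", call. = FALSE)
    }
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, sub_bias = sub_bias),
            class = "error_model")
}

#' Illumina-like substitution bias preset
#'
#' A substitution-type matrix with the qualitative trends of short-read
#' sequencers: C and G leave their base most often, with T and A the most
#' frequent substitution targets (C->A, C->T and G->T elevated).
#'
#' @return a 4x4 row-stochastic matrix usable as `sub_bias`.
#' @export
illumina_sub_bias <- function() {
  m <- matrix(c(
    # to: A     C     G     T        from:
         0.00, 0.20, 0.30, 0.50,   # A
         0.45, 0.00, 0.10, 0.45,   # C
         0.25, 0.10, 0.00, 0.65,   # G
         0.40, 0.15, 0.45, 0.00),  # T
    4, 4, byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES))
  m / rowSums(m)
}

#' Sample relative abundances over a log-uniform decade range
#'
#' Emulates the wide per-member read distribution of a pooled library whose
#' members were mixed from imprecisely quantified stocks: `n` weights drawn
#' log-uniformly over `log10_range` decades, normalized to sum to 1.
#'
#' @param n number of members.
#' @param log10_range lower/upper log10 bounds (default `c(3, 6)`).
#' @param seed integer seed.
#' @return numeric vector of `n` relative abundances summing to 1.
#' @export
sample_abundances <- function(n, log10_range = c(3, 6), seed = 1L) {
  stopifnot(n >= 1L, log10_range[1] <= log10_range[2])
  set.seed(as.integer(seed))
  w <- 10^runif(n, log10_range[1], log10_range[2])
  w / sum(w)
}

#' Pool specification for read simulation
#'
#' @param amplicons character vector of member amplicon sequences.
#' @param traptags per-member TrapTag (recycled), recorded as ground truth.
#' @param abundances positive relative abundances (normalized internally).
#' @param member_ids member labels (default `m1..mN` or names of
#'   `amplicons`).
#' @param spike_ins optional data.frame with columns `sequence` and
#'   `fraction` (off-target products injected at fixed read fractions; the
#'   fractions must sum to < 1).
#' @return an object of class `pool_spec`.
#' @export
pool_spec <- function(amplicons, traptags = NA_character_,
                      abundances = 1, member_ids = NULL,
                      spike_ins = NULL) {
  n <- length(amplicons)
  stopifnot(n >= 0L)
  traptags <- rep_len(traptags, n)
  abundances <- rep_len(abundances, n)
  if (n && any(abundances <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (is.null(member_ids)) {
    member_ids <- if (!is.null(names(amplicons))) names(amplicons)
                  else sprintf("m%d", seq_len(n))
  }
  if (!is.null(spike_ins)) {
    stopifnot(all(c("sequence", "fraction") %in% names(spike_ins)))
    if (any(spike_ins$fraction < 0) || sum(spike_ins$fraction) >= 1) {
      stop("spike-in fractions must be in [0, 1) and sum to < 1",
           call. = FALSE)
    }
  }
  structure(list(amplicons = unname(amplicons), traptags = traptags,
                 abundances = abundances / max(sum(abundances), 1e-300),
                 member_ids = member_ids, spike_ins = spike_ins),
            class = "pool_spec")
}

mutate_read <- function(seqchars, n_ins, n_del, n_sub, bias) {
  # indels first, at most one indel event per position
  L <- length(seqchars)
  if (n_ins + n_del > 0L) {
    k <- min(n_ins + n_del, L)
    pos <- sample.int(L, k)
    ins_pos <- pos[seq_len(min(n_ins, k))]
    del_pos <- setdiff(pos, ins_pos)
    keep <- rep(TRUE, L)
    keep[del_pos] <- FALSE
    add <- rep("", L)
    if (length(ins_pos)) {
      add[ins_pos] <- sample(DNA_BASES, length(ins_pos), replace = TRUE)
    }
    seqchars <- unlist(lapply(seq_len(L), function(i) {
      c(if (keep[i]) seqchars[i], if (nzchar(add[i])) add[i])
    }))
    L <- length(seqchars)
  }
  if (n_sub > 0L && L > 0L) {
    pos <- sample.int(L, min(n_sub, L))
    for (p in pos) {
      from <- seqchars[p]
      seqchars[p] <- sample(DNA_BASES, 1L, prob = bias[from, ])
    }
  }
  seqchars
}

#' Simulate amplicon sequencing reads
#'
#' Each read is drawn from the pool members (and spike-ins) proportionally
#' to abundance, then per-base errors are applied independently under the
#' error model. Reads model joined, adapter-trimmed single-end amplicon
#' copies. Read ids encode the ground truth (member id, TrapTag, applied
#' error counts) for downstream evaluation; the quality string is a
#' constant Q37.
#'
#' @param pool a [pool_spec()].
#' @param n_reads number of reads.
#' @param model an [error_model()].
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return data.frame with columns `id`, `sequence`, `quality`, `member`,
#'   `traptag`, `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_reads <- function(pool, n_reads, model = error_model(), seed = 1L) {
  if (n_reads < 0L) stop("n_reads must be >= 0", call. = FALSE)
  n_spike <- if (is.null(pool$spike_ins)) 0L else nrow(pool$spike_ins)
  n_mem <- length(pool$amplicons)
  if (n_mem + n_spike == 0L && n_reads > 0L) {
    stop("cannot simulate reads from an empty pool", call. = FALSE)
  }
  set.seed(as.integer(seed))
  spike_frac <- if (n_spike) sum(pool$spike_ins$fraction) else 0
  probs <- c(pool$abundances * (1 - spike_frac),
             if (n_spike) pool$spike_ins$fraction)
  src <- sample.int(n_mem + n_spike, n_reads, replace = TRUE, prob = probs)
  seqs <- c(pool$amplicons,
            if (n_spike) pool$spike_ins$sequence)
  members <- c(pool$member_ids,
               if (n_spike) sprintf("spike%d", seq_len(n_spike)))
  tags <- c(pool$traptags, if (n_spike) rep(NA_character_, n_spike))
  lens <- nchar(seqs)[src]
  n_sub <- rbinom(n_reads, lens, model$sub_rate)
  n_ins <- rbinom(n_reads, lens, model$ins_rate)
  n_del <- rbinom(n_reads, lens, model$del_rate)
  out_seq <- seqs[src]
  mutate_idx <- which(n_sub + n_ins + n_del > 0L)
  for (i in mutate_idx) {
    chars <- strsplit(out_seq[i], "", fixed = TRUE)[[1]]
    chars <- mutate_read(chars, n_ins[i], n_del[i], n_sub[i],
                         model$sub_bias)
    out_seq[i] <- paste(chars, collapse = "")
  }
  ids <- sprintf("r%07d|src=%s|tag=%s|sub=%d|ins=%d|del=%d",
                 seq_len(n_reads), members[src], tags[src],
                 n_sub, n_ins, n_del)
  data.frame(id = ids, sequence = out_seq,
             quality = strrep("F", nchar(out_seq)),
             member = members[src], traptag = tags[src],
             n_sub = n_sub, n_ins = n_ins, n_del = n_del,
             stringsAsFactors = FALSE)
}

#' Downsample reads uniformly without replacement
#'
#' Keeps input order (order-stable); returns all reads when `n` exceeds the
#' input size.
#'
#' @param reads data.frame of reads (any row content).
#' @param n target number of reads.
#' @param seed integer seed.
#' @return the sampled subset of `reads`.
#' @export
downsample <- function(reads, n, seed = 1L) {
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  if (n >= nrow(reads)) return(reads)
  set.seed(as.integer(seed))
  keep <- sort(sample.int(nrow(reads), n))
  reads[keep, , drop = FALSE]
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `sequence`, `quality` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- Biostrings::PhredQuality(reads$quality)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence), qual)
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file.
#' @return data.frame with `id` and `sequence` columns.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse simulator ground truth from read ids
#'
#' @param ids read ids produced by [simulate_reads()].
#' @return data.frame with `member`, `traptag`, `n_sub`, `n_ins`, `n_del`.
#' @export
parse_read_truth <- function(ids) {
  f <- function(key, convert = identity) {
    m <- regmatches(ids, regexpr(sprintf("(?<=\\|%s=)[^|]+", key), ids,
                                 perl = TRUE))
    convert(m)
  }
  data.frame(member = f("src"), traptag = f("tag"),
             n_sub = f("sub", as.integer), n_ins = f("ins", as.integer),
             n_del = f("del", as.integer), stringsAsFactors = FALSE)
}
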