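#' Combinatorial code constraints
#'
#' Bundles the design rules a variable-region (or overhang) code must obey:
#' word length, homopolymer limit, minimum pairwise Hamming distance, minimum
#' pairwise distance under a +/-1 register shift, duplicate policy, and the
#' number of nick-adjacent terminal bases required to be unique across block
#' junctions. Shipped presets: the first-generation library uses k = 6 with a
#' post-hoc minimum distance of 3; the second generation uses k = 12 with an
#' explicit minimum distance of 7 and shifted-register minimum of 5.
#'
#' @param k variable-region length (nt).
#' @param max_homopolymer_run longest allowed identical-base run (>= 2).
#' @param min_hamming minimum pairwise Hamming distance.
#' @param min_shifted_hamming minimum pairwise shifted-register distance.
#' @param forbid_duplicates disallow duplicate sequences in a set.
#' @param unique_terminal_nt number of nick-adjacent terminal bases required
#'   unique across junction overhangs (0 disables the check).
#' @return an object of class `code_constraints`.
#' @export
code_constraints <- function(k,
                             max_homopolymer_run = 3L,
                             min_hamming = 1L,
                             min_shifted_hamming = 1L,
                             forbid_duplicates = TRUE,
                             unique_terminal_nt = 0L) {
  k <- as.integer(k)
  min_hamming <- as.integer(min_hamming)
  min_shifted_hamming <- as.integer(min_shifted_hamming)
  max_homopolymer_run <- as.integer(max_homopolymer_run)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (max_homopolymer_run < 2L) {
    stop("max_homopolymer_run must be >= 2", call. = FALSE)
  }
  if (min_shifted_hamming < 1L || min_shifted_hamming > min_hamming ||
      min_hamming > k) {
    stop("need 1 <= min_shifted_hamming <= min_hamming <= k", call. = FALSE)
  }
  structure(list(k = k,
                 max_homopolymer_run = max_homopolymer_run,
                 min_hamming = min_hamming,
                 min_shifted_hamming = min_shifted_hamming,
                 forbid_duplicates = isTRUE(forbid_duplicates),
                 unique_terminal_nt = as.integer(unique_terminal_nt)),
            class = "code_constraints")
}

#' @export
print.code_constraints <- function(x, ...) {
  cat("Code constraints: k =", x$k,
      "| max run", x$max_homopolymer_run,
      "| min Hamming", x$min_hamming,
      "| min shifted Hamming", x$min_shifted_hamming,
      "| duplicates", if (x$forbid_duplicates) "forbidden" else "allowed",
      "| unique terminal nt", x$unique_terminal_nt, "\n")
  invisible(x)
}

search_failure <- function(msg, best_size) {
  stop(structure(class = c("modbarcode_search_failure", "error", "condition"),
                 list(message = sprintf("%s (best partial set size: %d)",
                                        msg, best_size),
                      call = NULL, best_size = best_size)))
}

# One greedy accretion pass over a candidate order; returns the accepted
# sequences (up to n_total).
greedy_accrete <- function(pool, n_total, min_h, min_sh, check_shift) {
  k <- nchar(pool[[1]])
  left  <- substr(pool, 1L, k - 1L)
  right <- substr(pool, 2L, k)
  mat <- seq_matrix(pool)
  ml <- if (check_shift) seq_matrix(left)
  mr <- if (check_shift) seq_matrix(right)
  sel <- integer(0)
  for (i in seq_along(pool)) {
    ok <- TRUE
    if (length(sel)) {
      if (any(ham_to_all(mat[i, ], mat[sel, , drop = FALSE]) < min_h)) {
        ok <- FALSE
      } else if (check_shift) {
        d1 <- ham_to_all(ml[i, ], mr[sel, , drop = FALSE])
        d2 <- ham_to_all(mr[i, ], ml[sel, , drop = FALSE])
        if (any(pmin(d1, d2) < min_sh)) ok <- FALSE
      }
    }
    if (ok) {
      sel <- c(sel, i)
      if (length(sel) == n_total) break
    }
  }
  pool[sel]
}

#' Select a set of variable-region sequences
#'
#' Greedy accretion with a random candidate order and restarts: candidates are
#' visited in a seeded random order and accepted when they keep every pairwise
#' Hamming distance at or above `constraints$min_hamming` and every pairwise
#' shifted-register distance at or above `constraints$min_shifted_hamming`.
#' The first restart that reaches `n_blocks * variants_per_block` accepted
#' sequences wins; accepted sequences are assigned to blocks in consecutive
#' groups. Deterministic given `seed`.
#'
#' @param pool candidate sequences, all of length `constraints$k` and already
#'   homopolymer-filtered.
#' @param n_blocks number of blocks.
#' @param variants_per_block variants per block.
#' @param constraints a [code_constraints()] object.
#' @param seed integer seed driving the candidate shuffles.
#' @param restarts maximum number of shuffled passes before giving up.
#' @return an object of class `variable_region_set` with fields `sequences`
#'   (list of per-block character vectors), `constraints`, `provenance`.
#' @export
select_variable_regions <- function(pool, n_blocks, variants_per_block,
                                    constraints, seed = 1L, restarts = 100L) {
  check_dna(pool)
  k <- constraints$k
  if (any(nchar(pool) != k)) {
    stop("all pool sequences must have length k = ", k, call. = FALSE)
  }
  if (any(longest_run(pool) > constraints$max_homopolymer_run)) {
    stop("pool must be homopolymer-filtered first", call. = FALSE)
  }
  n_total <- n_blocks * variants_per_block
  if (n_total > length(pool)) {
    search_failure("candidate pool smaller than requested set", 0L)
  }
  pool <- unique(pool)
  if (n_total > length(pool)) {
    search_failure("candidate pool smaller than requested set (after dedup)",
                   0L)
  }
  check_shift <- k >= 2L
  best <- character(0)
  set.seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    ord <- sample.int(length(pool))
    got <- greedy_accrete(pool[ord], n_total,
                          constraints$min_hamming,
                          constraints$min_shifted_hamming,
                          check_shift)
    if (length(got) > length(best)) best <- got
    if (length(best) == n_total) break
  }
  if (length(best) < n_total) {
    search_failure("no feasible set found within restart budget", length(best))
  }
  # Lexicographic tie-break for a canonical presentation within each block.
  blocks <- split(best, rep(seq_len(n_blocks), each = variants_per_block))
  blocks <- lapply(unname(blocks), sort)
  structure(list(sequences = blocks,
                 constraints = constraints,
                 provenance = sprintf(
                   "greedy accretion; seed=%d; pool=%d; restarts<=%d",
                   as.integer(seed), length(pool), restarts)),
            class = "variable_region_set")
}

#' Construct a variable-region set from explicit per-block sequences
#'
#' @param blocks list of character vectors, one per block position.
#' @param constraints a [code_constraints()] object.
#' @param provenance free-text origin note.
#' @return a `variable_region_set`.
#' @export
variable_region_set <- function(blocks, constraints,
                                provenance = "explicit") {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  for (b in blocks) check_dna(b)
  lens <- unlist(lapply(blocks, nchar))
  if (any(lens != constraints$k)) {
    stop("all sequences must have length k = ", constraints$k, call. = FALSE)
  }
  structure(list(sequences = lapply(blocks, unname),
                 constraints = constraints,
                 provenance = provenance),
            class = "variable_region_set")
}

#' @export
print.variable_region_set <- function(x, ...) {
  nb <- length(x$sequences)
  cat("Variable-region set:", nb, "blocks x",
      paste(vapply(x$sequences, length, integer(1)), collapse = "/"),
      "variants, k =", x$constraints$k, "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

vset_labels <- function(vset) {
  unlist(lapply(seq_along(vset$sequences), function(b) {
    sprintf("b%d.v%d", b, seq_along(vset$sequences[[b]]))
  }))
}

#' Validate a variable-region set against its code constraints
#'
#' Pure function of the input. Reports, per constraint, pass/fail together
#' with the worst offending pair (or sequence) and the measured value:
#' duplicate sequences, homopolymer runs, minimum pairwise Hamming distance
#' within blocks and globally (reported separately), and minimum pairwise
#' shifted-register distance (distinct pairs only).
#'
#' @param vset a `variable_region_set`.
#' @param constraints optionally override `vset$constraints`.
#' @return a data.frame with columns `constraint`, `status`, `worst_pair`,
#'   `value`.
#' @export
validate_variable_set <- function(vset, constraints = vset$constraints) {
  seqs <- unlist(vset$sequences)
  labs <- vset_labels(vset)
  block_of <- rep(seq_along(vset$sequences),
                  vapply(vset$sequences, length, integer(1)))
  rows <- list()
  add <- function(constraint, status, worst, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      constraint = constraint, status = status,
      worst_pair = worst, value = value, stringsAsFactors = FALSE)
  }

  dup <- duplicated(seqs) | duplicated(seqs, fromLast = TRUE)
  if (any(dup)) {
    d1 <- which(dup)[1:2]
    worst <- paste0(labs[d1], collapse = "|")
    add("duplicates",
        if (constraints$forbid_duplicates) "fail" else "pass",
        worst, sum(duplicated(seqs)))
  } else {
    add("duplicates", "pass", NA_character_, 0)
  }

  runs <- longest_run(seqs)
  w <- which.max(runs)
  add("homopolymer_run",
      if (max(runs) <= constraints$max_homopolymer_run) "pass" else "fail",
      labs[w], max(runs))

  ph <- pairwise_hamming(seqs)
  if (nrow(ph)) {
    wb <- ph[block_of[ph$i] == block_of[ph$j], , drop = FALSE]
    if (nrow(wb)) {
      w <- which.min(wb$d)
      add("min_hamming_within_block",
          if (wb$d[w] >= constraints$min_hamming) "pass" else "fail",
          paste0(labs[wb$i[w]], "|", labs[wb$j[w]]), wb$d[w])
    }
    w <- which.min(ph$d)
    add("min_hamming_global",
        if (ph$d[w] >= constraints$min_hamming) "pass" else "fail",
        paste0(labs[ph$i[w]], "|", labs[ph$j[w]]), ph$d[w])

    if (constraints$k >= 2L) {
      ps <- pairwise_shifted(seqs)
      w <- which.min(ps$d)
      add("min_shifted_hamming_global",
          if (ps$d[w] >= constraints$min_shifted_hamming) "pass" else "fail",
          paste0(labs[ps$i[w]], "|", labs[ps$j[w]]), ps$d[w])
    }
  }
  do.call(rbind, rows)
}

#' Design junction overhang sequences
#'
#' Seeded random search for `count` single-stranded overhangs of the given
#' length satisfying: homopolymer limit, GC fraction within `gc_bounds`,
#' pairwise Hamming distance of at least
#' `ceiling(min_hamming * length / k)` (the variable-region distance rule
#' rescaled to the overhang length), no overhang equal to or the reverse
#' complement of another, heuristic cross-hybridization score below
#' `max_cross_hyb` for every ordered pair (including self-complementarity),
#' and - when `constraints$unique_terminal_nt > 0` - distinct nick-adjacent
#' terminal bases across all overhangs. Overhangs are reported in top-strand
#' orientation; the nick-adjacent terminal bases are the last
#' `unique_terminal_nt` bases in that orientation (the 5' terminus of the
#' bottom strand that presents the overhang).
#'
#' @param count number of overhangs (junctions) to design.
#' @param length overhang length in nt (default 10).
#' @param constraints a [code_constraints()] object (supplies the homopolymer
#'   limit, the distance rule via `min_hamming`/`k`, and
#'   `unique_terminal_nt`).
#' @param gc_bounds allowed GC-fraction interval.
#' @param seed integer seed.
#' @param restarts candidate-draw budget multiplier.
#' @param max_cross_hyb reject pairs with a complementary stretch of at least
#'   this many bases (default 6).
#' @param external_scorer optional function(a, b) -> numeric overriding the
#'   heuristic cross-hybridization score (higher = worse).
#' @return character vector of `count` overhang sequences.
#' @export
design_overhangs <- function(count, length = 10L, constraints,
                             gc_bounds = c(0.4, 0.6), seed = 1L,
                             restarts = 100L, max_cross_hyb = 6L,
                             external_scorer = NULL) {
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  if (length < 4L) stop("overhang length must be >= 4", call. = FALSE)
  utn <- constraints$unique_terminal_nt
  if (utn > 0L && count > 4L^utn) {
    search_failure(sprintf(
      "only %d distinct terminal %d-mers exist for %d overhangs",
      4L^utn, utn, count), 0L)
  }
  min_h <- as.integer(ceiling(constraints$min_hamming * length /
                                constraints$k))
  score <- if (is.null(external_scorer)) cross_hybridization_score
           else external_scorer
  set.seed(as.integer(seed))
  sel <- character(0)
  tried <- 0L
  budget <- restarts * 200L
  while (length(sel) < count && tried < budget) {
    tried <- tried + 1L
    cand <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    if (longest_run(cand) > constraints$max_homopolymer_run) next
    gc <- gc_fraction(cand)
    if (gc < gc_bounds[1] || gc > gc_bounds[2]) next
    if (score(cand, cand) >= max_cross_hyb) next
    ok <- TRUE
    for (s in sel) {
      if (cand == s || cand == revcomp(s) ||
          hamming_distance(cand, s) < min_h ||
          score(cand, s) >= max_cross_hyb) { ok <- FALSE; break }
    }
    if (ok && utn > 0L) {
      term <- substr(cand, length - utn + 1L, length)
      terms <- substr(sel, nchar(sel) - utn + 1L, nchar(sel))
      if (term %in% terms) ok <- FALSE
    }
    if (ok) sel <- c(sel, cand)
  }
  if (length(sel) < count) {
    search_failure("overhang search budget exhausted", length(sel))
  }
  sel
}

#' Check a primer against every sequence of a library
#'
#' Scans both strands of every library member for sites where the primer's
#' 3'-terminal `min_anchor` bases match exactly (primer `N`s match any base)
#' and the total number of mismatches over the full primer span is at most
#' `max_mismatch`. Reports every such site; a hit matching the supplied
#' intended location is flagged on-target.
#'
#' @param primer primer sequence, 5' to 3' (may contain `N`).
#' @param library character vector of library sequences (top strands).
#' @param min_anchor exact-match 3' anchor length (default 12).
#' @param max_mismatch maximum mismatches over the full primer (default 2).
#' @param intended_strand,intended_start optional intended binding site: the
#'   strand (`"+"`/`"-"`) and 1-based start of the primer's aligned span in
#'   top-strand coordinates.
#' @return data.frame with columns `index`, `strand`, `position` (1-based
#'   start of the aligned span in top-strand coordinates), `mismatches`,
#'   `on_target`.
#' @export
primer_library_specificity <- function(primer, library, min_anchor = 12L,
                                       max_mismatch = 2L,
                                       intended_strand = NULL,
                                       intended_start = NULL) {
  check_dna(primer, allow_n = TRUE)
  m <- nchar(primer)
  if (m < min_anchor) {
    stop("primer shorter than min_anchor", call. = FALSE)
  }
  praw <- charToRaw(primer)
  is_n <- praw == charToRaw("N")
  anchor_idx <- (m - min_anchor + 1L):m
  hits <- list()
  scan_strand <- function(seq_raw, L) {
    if (L < m) return(NULL)
    starts <- seq_len(L - m + 1L)
    res <- NULL
    for (s in starts) {
      win <- seq_raw[s:(s + m - 1L)]
      diff <- (win != praw) & !is_n
      if (any(diff[anchor_idx])) next
      mm <- sum(diff)
      if (mm <= max_mismatch) {
        res <- rbind(res, c(s, mm))
      }
    }
    res
  }
  for (i in seq_along(library)) {
    top <- library[[i]]
    L <- nchar(top)
    r_top <- charToRaw(top)
    r_bot <- charToRaw(revcomp(top))
    h <- scan_strand(r_top, L)
    if (!is.null(h)) {
      hits[[length(hits) + 1L]] <- data.frame(
        index = i, strand = "+", position = h[, 1], mismatches = h[, 2])
    }
    h <- scan_strand(r_bot, L)
    if (!is.null(h)) {
      # report in top-strand coordinates: start of the spanned region
      hits[[length(hits) + 1L]] <- data.frame(
        index = i, strand = "-", position = L - (h[, 1] + m - 1L) + 1L,
        mismatches = h[, 2])
    }
  }
  if (!length(hits)) {
    return(data.frame(index = integer(0), strand = character(0),
                      position = integer(0), mismatches = integer(0),
                      on_target = logical(0)))
  }
  out <- do.call(rbind, hits)
  out$on_target <- FALSE
  if (!is.null(intended_strand) && !is.null(intended_start)) {
    out$on_target <- out$strand == intended_strand &
      out$position == intended_start & out$mismatches == 0L
  }
  rownames(out) <- NULL
  out
}
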