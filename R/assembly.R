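# Adapter scaffold constants used by the four-stage overhang-PCR library
# preparation (Illumina-style read-1/read-2 adapters and flow-cell ends).
READ1_ADAPTER <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
READ2_ADAPTER <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
P5_EXTENSION  <- "AATGATACGGCGACCACCGAGATCT"
P7_EXTENSION  <- "CAAGCAGAAGACGGCATACGAGAT"
INDEX_SPACER  <- "ATATTCAC"

#' Build the four nested overhang-PCR primer sets
#'
#' Given a library's forward, reverse and TrapTag primers, constructs the
#' four primer pairs used in sequence to amplify the barcode, append the
#' 8-nt TrapTag UMI, and attach the sequencing adapters and 10-nt sample
#' index. `N` runs mark the UMI (set 2) and index (set 4) wildcards.
#'
#' @param fwd,rev,traptag library primer sequences, 5' to 3'.
#' @return data.frame with columns `set`, `fwd`, `rev`.
#' @export
overhang_pcr_sets <- function(fwd, rev, traptag) {
  data.frame(
    set = 1:4,
    fwd = c(paste0(READ1_ADAPTER, fwd),
            READ1_ADAPTER,
            READ1_ADAPTER,
            paste0(P5_EXTENSION, READ1_ADAPTER)),
    rev = c(rev,
            paste0(traptag, strrep("N", 8L), rev),
            paste0(READ2_ADAPTER, traptag),
            paste0(P7_EXTENSION, strrep("N", 10L), INDEX_SPACER,
                   READ2_ADAPTER)),
    stringsAsFactors = FALSE)
}

#' Enumerate the combinatorial barcode library
#'
#' Cartesian product over block positions in deterministic odometer order
#' (last position fastest). Record ids join 0-based variant indices with
#' underscores, e.g. `bc_1_3_0_2`.
#'
#' @param design a `library_design`.
#' @return data.frame with columns `id`, one `v<i>` column of 1-based variant
#'   indices per block, and `sequence`.
#' @export
enumerate_library <- function(design) {
  nv <- vapply(design$blocks, length, integer(1))
  n_blocks <- length(nv)
  idx <- rev(expand.grid(rev(lapply(nv, seq_len)), KEEP.OUT.ATTRS = FALSE))
  idx <- as.matrix(idx)
  colnames(idx) <- sprintf("v%d", seq_len(n_blocks))
  layout <- design$layout
  var_rows <- which(layout$role == "variable")
  seqs <- rep(design$template, nrow(idx))
  for (bi in seq_len(n_blocks)) {
    r <- var_rows[bi]
    substr(seqs, layout$start0[r] + 1L, layout$end0[r]) <-
      design$vset$sequences[[bi]][idx[, bi]]
  }
  ids <- apply(idx - 1L, 1L, function(v) paste0("bc_", paste(v, collapse = "_")))
  out <- data.frame(id = ids, idx, sequence = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' In-silico annealing and ligation of one barcode
#'
#' Assembles the chosen block variants, verifying that every designed
#' junction is exactly complementary over the full overhang and that the
#' strands flanking each nick carry the required 5' phosphate. Junction
#' overhangs are counted once, so the duplex length equals the layout total.
#'
#' @param design a `library_design`.
#' @param variants integer vector of 1-based variant indices, one per block.
#' @return list with `sequence` (top strand), `length`, `nicks_top`,
#'   `nicks_bottom` (0-based nick coordinates), `ligated`.
#' @export
assemble_target <- function(design, variants) {
  n_blocks <- length(design$blocks)
  if (length(variants) != n_blocks) {
    stop("need one variant per block position", call. = FALSE)
  }
  specs <- lapply(seq_len(n_blocks),
                  function(i) design$blocks[[i]][[variants[i]]])
  jc <- junction_coords(design$layout)
  ligated <- TRUE
  for (i in seq_len(n_blocks - 1L)) {
    a <- specs[[i]]    # provides bottom-strand 5' overhang at the junction
    b <- specs[[i + 1L]]  # provides top-strand 5' overhang
    oh_len <- nchar(design$overhangs[i])
    # top-strand image of a's bottom overhang (last oh_len bases of its span)
    a_img <- substr(revcomp(a$bottom_strand),
                    nchar(a$bottom_strand) - oh_len + 1L,
                    nchar(a$bottom_strand))
    b_oh <- substr(b$top_strand, 1L, oh_len)
    if (a_img != b_oh) {
      stop(sprintf("junction %d not complementary over the overhang", i),
           call. = FALSE)
    }
    if (!isTRUE(unname(b$five_prime_phosphate["top"])) ||
        !isTRUE(unname(a$five_prime_phosphate["bottom"]))) {
      warning(sprintf("junction %d nick not ligatable: missing 5' phosphate",
                      i))
      ligated <- FALSE
    }
  }
  seq <- paste(vapply(specs, function(s) s$top_strand, character(1)),
               collapse = "")
  list(sequence = seq, length = nchar(seq),
       nicks_top = jc$t, nicks_bottom = jc$b, ligated = ligated)
}

fill_n_run <- function(primer, fill) {
  m <- regexpr("N+", primer)
  if (m < 0L) stop("primer has no N run to fill", call. = FALSE)
  n_len <- attr(m, "match.length")
  if (nchar(fill) != n_len) {
    stop(sprintf("wildcard fill must be %d nt, got %d", n_len, nchar(fill)),
         call. = FALSE)
  }
  sub("N+", fill, primer)
}

# Locate the unique binding site of a primer's 3' anchor on a strand
# (raw template vector); primer N matches any base, template N never
# matches (wildcard template positions cannot template a primer). Returns
# the 0-based end (exclusive) of the annealed span and the annealed length.
find_priming_site <- function(template_raw, primer, min_anchor) {
  m <- nchar(primer)
  if (m < min_anchor) stop("primer shorter than min_anchor", call. = FALSE)
  praw <- charToRaw(primer)
  nraw <- charToRaw("N")
  anchor <- praw[(m - min_anchor + 1L):m]
  anchor_n <- anchor == nraw
  L <- length(template_raw)
  hits <- integer(0)
  if (L >= min_anchor) {
    for (s in 0:(L - min_anchor)) {
      win <- template_raw[(s + 1L):(s + min_anchor)]
      if (all(anchor_n | win == anchor)) {
        hits <- c(hits, s + min_anchor)  # 0-based exclusive end
      }
    }
  }
  if (length(hits) != 1L) {
    stop(sprintf(
      "priming error: %d candidate sites for 3' anchor %s (need exactly 1)%s",
      length(hits), rawToChar(anchor),
      if (length(hits)) paste0(" at ends: ",
                               paste(hits, collapse = ", ")) else ""),
      call. = FALSE)
  }
  e <- hits
  # extend the annealed span 5'-ward while template remains and bases match
  j <- min_anchor
  while (j < m && e - j - 1L >= 0L) {
    pb <- praw[m - j]
    tb <- template_raw[e - j]
    if ((pb != tb || tb == nraw) && pb != nraw) break
    j <- j + 1L
  }
  c(end0 = e, annealed = j)
}

#' Overhang PCR extension of a duplex template
#'
#' Models one PCR stage: the forward primer's 3'-terminal `min_anchor` bases
#' must match the top strand exactly at one site, and the reverse primer's at
#' one site on the bottom strand, with the forward site upstream. The product
#' is the forward primer's unmatched 5' extension, the template span between
#' the two binding sites inclusive, and the reverse complement of the reverse
#' primer's unmatched 5' extension. `N` wildcards in primers match any base
#' and are carried into the product.
#'
#' @param template top strand of the duplex template.
#' @param fwd,rev primer sequences, 5' to 3' (may contain `N` runs).
#' @param min_anchor exact-match 3' anchor length (default 12).
#' @return list with `sequence`, `length`, `fwd_extension`, `rev_extension`
#'   (unmatched 5' extension lengths).
#' @export
pcr_extend <- function(template, fwd, rev, min_anchor = 12L) {
  traw <- charToRaw(template)
  L <- length(traw)
  braw <- charToRaw(revcomp(template))
  f <- find_priming_site(traw, fwd, min_anchor)
  r <- find_priming_site(braw, rev, min_anchor)
  r_start0_top <- L - r["end0"]  # top-strand start of the rev annealed span
  if (f["end0"] > r_start0_top) {
    stop("priming error: forward site not upstream of reverse site",
         call. = FALSE)
  }
  mid <- substr(template, f["end0"] + 1L, r_start0_top)
  seqv <- paste0(fwd, mid, revcomp(rev))
  # replace the annealed portions by the primer sequences themselves: the
  # product starts with the full fwd primer and ends with revcomp(rev), with
  # the template span between the annealed spans in the middle
  list(sequence = seqv,
       length = nchar(seqv),
       fwd_extension = unname(nchar(fwd) - f["annealed"]),
       rev_extension = unname(nchar(rev) - r["annealed"]))
}

#' Simulate the four-stage overhang-PCR library preparation
#'
#' Applies the design's four nested primer sets in order to a ligated
#' barcode, substituting the 8-nt TrapTag UMI into the set-2 wildcard run and
#' the 10-nt sample index into the set-4 run. Tags and indices are given in
#' top-strand orientation as they appear on the final amplicon, so the fills
#' insert their reverse complements into the reverse primers. Stage-by-stage
#' product lengths are recorded. The final amplicon carries, left to right:
#' flow-cell P5 extension, read-1 adapter, barcode, TrapTag, TrapTag-primer
#' region, read-2 adapter, spacer, sample index, P7 extension.
#'
#' @param barcode top strand of the ligated barcode duplex.
#' @param traptag 8-nt TrapTag UMI (or `NULL` to leave the wildcards as `N`).
#' @param sample_index 10-nt sample index (or `NULL` to leave as `N`).
#' @param design a `library_design` providing `primer_sets`.
#' @param min_anchor exact-match 3' anchor length for priming.
#' @return list with `amplicon`, `stage_lengths`, and `segments` (0-based
#'   half-open spans of `barcode`, `traptag` and `sample_index` in the final
#'   amplicon).
#' @export
simulate_library_prep <- function(barcode, traptag, sample_index, design,
                                  min_anchor = 12L) {
  if (!is.null(traptag)) {
    check_dna(traptag)
    if (nchar(traptag) != 8L) stop("traptag must be 8 nt", call. = FALSE)
  }
  if (!is.null(sample_index)) {
    check_dna(sample_index)
    if (nchar(sample_index) != 10L) {
      stop("sample_index must be 10 nt", call. = FALSE)
    }
  }
  ps <- design$primer_sets
  cur <- barcode
  bc_start0 <- 0L
  stage_lengths <- integer(nrow(ps))
  for (s in seq_len(nrow(ps))) {
    res <- pcr_extend(cur, ps$fwd[s], ps$rev[s], min_anchor = min_anchor)
    cur <- res$sequence
    bc_start0 <- bc_start0 + res$fwd_extension
    stage_lengths[s] <- res$length
  }
  # the UMI and index wildcard runs survive as N runs on the product top
  # strand (reverse complement of the reverse-primer N runs)
  runs <- gregexpr("N+", cur)[[1]]
  segs <- list(barcode = c(bc_start0, bc_start0 + nchar(barcode)))
  if (runs[1] != -1L) {
    lens <- attr(runs, "match.length")
    bc_end0 <- bc_start0 + nchar(barcode)
    for (i in seq_along(runs)) {
      st0 <- runs[i] - 1L
      if (st0 < bc_start0 || st0 >= bc_end0) {
        nm <- if (lens[i] == 8L) "traptag"
              else if (lens[i] == 10L) "sample_index"
              else next
        segs[[nm]] <- c(st0, st0 + lens[i])
      }
    }
  }
  if (!is.null(traptag) && !is.null(segs$traptag)) {
    substr(cur, segs$traptag[1] + 1L, segs$traptag[2]) <- traptag
  }
  if (!is.null(sample_index) && !is.null(segs$sample_index)) {
    substr(cur, segs$sample_index[1] + 1L, segs$sample_index[2]) <-
      sample_index
  }
  list(amplicon = cur, stage_lengths = stage_lengths, segments = segs)
}
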