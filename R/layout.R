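#' Amplicon layout configuration
#'
#' An ordered segment list describing one barcode generation's top strand,
#' left to right. Segment roles: `primer_fwd` (first), `constant` (pad),
#' `variable`, `junction_overhang`, `primer_rev` (last). Coordinates are
#' 0-based half-open on the top strand. Each junction overhang together with
#' the following pad forms a display "constant region" (the regions shown in
#' deletion heatmaps); the forward primer plus the first pad is constant
#' region 1 and the reverse primer region is the last constant region.
#'
#' @param segments data.frame with columns `name`, `role`, `length`.
#' @param total expected total length (bp); checked when supplied.
#' @return an object of class `layout_config` (the segment table with
#'   coordinates, block and display-region assignments, plus attributes
#'   `n_blocks` and `total`).
#' @export
layout_config <- function(segments, total = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("name", "role", "length") %in% names(segments)))
  roles <- c("primer_fwd", "primer_rev", "constant", "variable",
             "junction_overhang")
  if (!all(segments$role %in% roles)) {
    stop("unknown segment role", call. = FALSE)
  }
  if (any(segments$length < 1L)) stop("segment lengths must be >= 1",
                                      call. = FALSE)
  n <- nrow(segments)
  if (sum(segments$role == "primer_fwd") != 1L ||
      segments$role[1] != "primer_fwd" ||
      sum(segments$role == "primer_rev") != 1L ||
      segments$role[n] != "primer_rev") {
    stop("layout needs exactly one primer_fwd segment (first) and one ",
         "primer_rev segment (last)", call. = FALSE)
  }
  n_var <- sum(segments$role == "variable")
  n_junc <- sum(segments$role == "junction_overhang")
  if (n_var >= 1L && n_junc != n_var - 1L) {
    stop("number of junction overhangs must equal number of blocks - 1",
         call. = FALSE)
  }
  L <- sum(segments$length)
  if (!is.null(total) && L != total) {
    stop(sprintf("layout totals %d bp, expected %d", L, total), call. = FALSE)
  }
  seg <- segments
  seg$end0 <- cumsum(seg$length)
  seg$start0 <- seg$end0 - seg$length
  # block assignment: block i runs from junction_{i-1} (inclusive) up to
  # junction_i (exclusive); block 1 starts at the forward primer.
  junc_rows <- which(seg$role == "junction_overhang")
  blk <- integer(n)
  b <- 1L
  for (i in seq_len(n)) {
    if (i %in% junc_rows) b <- b + 1L
    blk[i] <- if (i %in% junc_rows) b else b
  }
  seg$block <- blk
  n_blocks <- n_var
  # display regions for deletion reporting
  region <- character(n)
  ci <- 1L
  for (i in seq_len(n)) {
    if (seg$role[i] == "variable") {
      region[i] <- seg$name[i]
    } else if (seg$role[i] == "junction_overhang") {
      ci <- ci + 1L
      region[i] <- sprintf("constant_%d", ci)
    } else if (seg$role[i] == "primer_rev") {
      region[i] <- sprintf("constant_%d", ci + 1L)
    } else {
      region[i] <- sprintf("constant_%d", ci)
    }
  }
  seg$region <- region
  structure(seg, class = c("layout_config", "data.frame"),
            n_blocks = n_blocks, total = L)
}

#' @export
print.layout_config <- function(x, ...) {
  cat("Layout:", attr(x, "total"), "bp,", attr(x, "n_blocks"), "blocks\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

std_layout <- function(n_blocks, var_len, pad_len, overhang_len = 10L,
                       primer_len = 18L, total = NULL) {
  rows <- list(data.frame(name = "primer_fwd", role = "primer_fwd",
                          length = primer_len))
  for (i in seq_len(n_blocks)) {
    if (i > 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("junction_%d", i - 1L), role = "junction_overhang",
        length = overhang_len)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("pad_%d", i), role = "constant", length = pad_len)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("variable_%d", i), role = "variable", length = var_len)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "primer_rev", role = "primer_rev", length = primer_len)
  layout_config(do.call(rbind, rows), total = total)
}

#' Shipped first-generation layout (102 bp)
#'
#' Four blocks, 6-nt variable regions, 3-nt constant pads, 10-nt junction
#' overhangs, 18-nt primer regions; the variable region sits immediately
#' adjacent to each block's ligatable nick.
#'
#' @return a `layout_config` totalling 102 bp.
#' @export
gen1_layout <- function() std_layout(4L, 6L, 3L, total = 102L)

#' Shipped second-generation layout (128 bp)
#'
#' Three blocks, 12-nt variable regions, 12-nt constant pads, 10-nt junction
#' overhangs, 18-nt primer regions.
#'
#' @return a `layout_config` totalling 128 bp.
#' @export
gen2_layout <- function() std_layout(3L, 12L, 12L, total = 128L)

seg_lookup <- function(layout, name) {
  i <- match(name, layout$name)
  if (is.na(i)) stop("no layout segment named ", name, call. = FALSE)
  c(start0 = layout$start0[i], end0 = layout$end0[i])
}

# Junction coordinates: for junction i, top-strand nick at its start
# (t_i) and bottom-strand nick at its end (b_i).
junction_coords <- function(layout) {
  j <- layout[layout$role == "junction_overhang", , drop = FALSE]
  data.frame(junction = seq_len(nrow(j)), t = j$start0, b = j$end0,
             name = j$name)
}

# Per-block strand spans in top-strand 0-based half-open coordinates.
# Top strand of block i: [t_{i-1}, t_i); bottom strand (as top-strand image):
# [b_{i-1}, b_i); with t_0 = b_0 = 0 and t_n = b_n = total.
block_spans <- function(layout) {
  jc <- junction_coords(layout)
  n <- attr(layout, "n_blocks")
  L <- attr(layout, "total")
  t_cuts <- c(0L, jc$t, L)
  b_cuts <- c(0L, jc$b, L)
  data.frame(block = seq_len(n),
             top_start = t_cuts[seq_len(n)], top_end = t_cuts[seq_len(n) + 1L],
             bot_start = b_cuts[seq_len(n)], bot_end = b_cuts[seq_len(n) + 1L])
}

random_pad <- function(len, max_run = 3L) {
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (longest_run(s) <= max_run) return(s)
  }
}

#' Compile block oligos for a combinatorial barcode library
#'
#' Builds the per-generation design template (forward primer, seeded constant
#' pads, junction overhangs, reverse-primer region, `N` at variable
#' positions) and emits top and bottom single-stranded oligos for every block
#' variant. Constant padding is generated deterministically from `seed` and
#' is identical across variants of a position. Strands whose 5' end flanks a
#' ligatable nick are flagged as requiring a 5' phosphate (top strands of
#' blocks 2..n, bottom strands of blocks 1..n-1).
#'
#' @param layout a [layout_config()].
#' @param vset a `variable_region_set` with one block per layout variable
#'   segment.
#' @param overhangs character vector of junction overhang sequences
#'   (top-strand orientation), length = blocks - 1.
#' @param primers list with elements `fwd`, `rev`, `traptag` (primer
#'   sequences, 5' to 3').
#' @param traptag_whitelist character vector of 8-nt TrapTag UMIs (top-strand
#'   orientation as read on the final amplicon).
#' @param primer_sets data.frame of overhang-PCR primer pairs (columns
#'   `set`, `fwd`, `rev`); defaults to [overhang_pcr_sets()] built from
#'   `primers`.
#' @param seed integer seed for the constant padding.
#' @return an object of class `library_design`.
#' @export
compile_blocks <- function(layout, vset, overhangs, primers,
                           traptag_whitelist = make_traptag_whitelist(),
                           primer_sets = NULL, seed = 1L) {
  n_blocks <- attr(layout, "n_blocks")
  L <- attr(layout, "total")
  if (length(vset$sequences) != n_blocks) {
    stop("variable set has ", length(vset$sequences),
         " blocks; layout expects ", n_blocks, call. = FALSE)
  }
  var_rows <- which(layout$role == "variable")
  var_lens <- layout$length[var_rows]
  if (any(var_lens != vset$constraints$k)) {
    stop("layout variable segment lengths do not match k = ",
         vset$constraints$k, call. = FALSE)
  }
  if (length(overhangs) != max(0L, n_blocks - 1L)) {
    stop("need exactly blocks - 1 overhangs", call. = FALSE)
  }
  junc_rows <- which(layout$role == "junction_overhang")
  if (length(junc_rows) &&
      any(nchar(overhangs) != layout$length[junc_rows])) {
    stop("overhang lengths do not match layout junction segments",
         call. = FALSE)
  }
  check_dna(unlist(primers[c("fwd", "rev")]))

  set.seed(as.integer(seed))
  tmpl <- character(nrow(layout))
  ji <- 0L
  for (i in seq_len(nrow(layout))) {
    tmpl[i] <- switch(layout$role[i],
      primer_fwd = primers$fwd,
      primer_rev = revcomp(primers$rev),
      junction_overhang = { ji <- ji + 1L; overhangs[ji] },
      constant = random_pad(layout$length[i]),
      variable = strrep("N", layout$length[i]))
    if (nchar(tmpl[i]) != layout$length[i]) {
      stop("segment ", layout$name[i], " sequence length mismatch",
           call. = FALSE)
    }
  }
  template <- paste(tmpl, collapse = "")

  if (is.null(primer_sets)) {
    primer_sets <- overhang_pcr_sets(primers$fwd, primers$rev,
                                     primers$traptag)
  }

  spans <- block_spans(layout)
  subst_vars <- function(variants) {
    s <- template
    for (bi in seq_len(n_blocks)) {
      r <- var_rows[bi]
      substr(s, layout$start0[r] + 1L, layout$end0[r]) <-
        vset$sequences[[bi]][variants[bi]]
    }
    s
  }
  blocks <- vector("list", n_blocks)
  for (bi in seq_len(n_blocks)) {
    nv <- length(vset$sequences[[bi]])
    blocks[[bi]] <- vector("list", nv)
    r <- var_rows[bi]
    for (vi in seq_len(nv)) {
      full <- template
      substr(full, layout$start0[r] + 1L, layout$end0[r]) <-
        vset$sequences[[bi]][vi]
      top <- substr(full, spans$top_start[bi] + 1L, spans$top_end[bi])
      bot_img <- substr(full, spans$bot_start[bi] + 1L, spans$bot_end[bi])
      blocks[[bi]][[vi]] <- structure(list(
        block_index = bi,
        variant_index = vi,
        top_strand = top,
        bottom_strand = revcomp(bot_img),
        left_overhang = if (bi > 1L) overhangs[bi - 1L] else "",
        right_overhang = if (bi < n_blocks) overhangs[bi] else "",
        variable_region = vset$sequences[[bi]][vi],
        variable_start0 = layout$start0[r],
        top_start0 = spans$top_start[bi],
        bot_start0 = spans$bot_start[bi],
        five_prime_phosphate = c(top = bi > 1L, bottom = bi < n_blocks)),
        class = "block_spec")
    }
  }
  structure(list(layout = layout,
                 blocks = blocks,
                 template = template,
                 vset = vset,
                 overhangs = overhangs,
                 primers = primers,
                 traptag_whitelist = traptag_whitelist,
                 primer_sets = primer_sets,
                 seed = as.integer(seed)),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  nv <- vapply(x$blocks, length, integer(1))
  cat("Modular barcode library design\n")
  cat("  blocks:", length(x$blocks), "(", paste(nv, collapse = " x "),
      "variants ) ->", prod(nv), "barcodes,",
      2L * sum(nv), "oligos\n")
  cat("  amplicon:", attr(x$layout, "total"), "bp; overhangs:",
      paste(x$overhangs, collapse = ", "), "\n")
  cat("  TrapTag whitelist:", length(x$traptag_whitelist), "tags\n")
  invisible(x)
}

#' Number of single-stranded oligos in a design
#' @param design a `library_design`.
#' @return integer oligo count (2 per block variant).
#' @export
oligo_count <- function(design) {
  2L * sum(vapply(design$blocks, length, integer(1)))
}

#' Oligo order sheet
#'
#' One row per single-stranded oligo, mirroring a synthesis order: name,
#' sequence (5' to 3') and whether the oligo requires a 5' phosphate for
#' ligation.
#'
#' @param design a `library_design`.
#' @return data.frame with columns `name`, `sequence`,
#'   `five_prime_phosphate`.
#' @export
oligo_sheet <- function(design) {
  rows <- list()
  for (blk in design$blocks) {
    for (bs in blk) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("b%d_v%d_top", bs$block_index, bs$variant_index),
        sequence = bs$top_strand,
        five_prime_phosphate = unname(bs$five_prime_phosphate["top"]))
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("b%d_v%d_bottom", bs$block_index, bs$variant_index),
        sequence = bs$bottom_strand,
        five_prime_phosphate = unname(bs$five_prime_phosphate["bottom"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a TrapTag UMI whitelist
#'
#' Greedy selection of 8-nt tags with pairwise Hamming distance >= 3 and no
#' homopolymer run over 3, from a seeded random stream. A synthetic stand-in
#' for a purchased adapter-derived tag set.
#'
#' @param n number of tags (default 96).
#' @param seed integer seed.
#' @param tag_len tag length (default 8).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @return character vector of `n` tags.
#' @export
make_traptag_whitelist <- function(n = 96L, seed = 7L, tag_len = 8L,
                                   min_dist = 3L) {
  set.seed(as.integer(seed))
  sel <- character(0)
  tries <- 0L
  while (length(sel) < n && tries < 100000L) {
    tries <- tries + 1L
    cand <- paste(sample(DNA_BASES, tag_len, replace = TRUE), collapse = "")
    if (longest_run(cand) > 3L) next
    if (length(sel) &&
        any(ham_to_all(charToRaw(cand), seq_matrix(sel)) < min_dist)) next
    sel <- c(sel, cand)
  }
  if (length(sel) < n) {
    search_failure("could not build TrapTag whitelist", length(sel))
  }
  sel
}
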