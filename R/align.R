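#' Build the generic (N-wildcard) alignment template
#'
#' The decoding template carries `N` at every variable position: for
#' `full = FALSE`, the bare barcode duplex top strand (variable regions as
#' `N`); for `full = TRUE`, the complete sequencing amplicon produced by
#' running the four-stage library preparation on the barcode template, with
#' additional `N` runs at the TrapTag UMI and sample index. The segment map
#' locates every layout segment (plus, for the full template, the adapter
#' spans, `traptag` and `sample_index`) in 0-based half-open template
#' coordinates.
#'
#' @param design a `library_design`.
#' @param full build the full-amplicon template instead of the bare barcode.
#' @return an object of class `generic_template` with fields `sequence`,
#'   `segments` (name, start0, end0, role, region), `barcode_offset0`,
#'   `barcode_length`, `layout`, `design`.
#' @export
make_generic_template <- function(design, full = FALSE) {
  layout <- design$layout
  L <- attr(layout, "total")
  segs <- data.frame(name = layout$name, start0 = layout$start0,
                     end0 = layout$end0, role = layout$role,
                     region = layout$region, stringsAsFactors = FALSE)
  if (!full) {
    return(structure(list(sequence = design$template, segments = segs,
                          barcode_offset0 = 0L, barcode_length = L,
                          layout = layout, design = design),
                     class = "generic_template"))
  }
  prep <- simulate_library_prep(design$template, NULL, NULL, design)
  off <- prep$segments$barcode[1]
  segs$start0 <- segs$start0 + off
  segs$end0 <- segs$end0 + off
  extra <- list()
  add <- function(name, s0, e0, role) {
    if (e0 > s0) {
      extra[[length(extra) + 1L]] <<- data.frame(
        name = name, start0 = s0, end0 = e0, role = role, region = name,
        stringsAsFactors = FALSE)
    }
  }
  total <- nchar(prep$amplicon)
  bc <- prep$segments$barcode + off * 0L  # already in final coordinates
  tag <- prep$segments$traptag
  idx <- prep$segments$sample_index
  add("adapter_5p", 0L, bc[1], "adapter")
  if (!is.null(tag)) {
    add("pre_traptag", bc[2], tag[1], "adapter")
    add("traptag", tag[1], tag[2], "umi")
    nxt <- tag[2]
  } else nxt <- bc[2]
  if (!is.null(idx)) {
    add("pre_index", nxt, idx[1], "adapter")
    add("sample_index", idx[1], idx[2], "umi")
    add("adapter_3p", idx[2], total, "adapter")
  } else {
    add("adapter_3p", nxt, total, "adapter")
  }
  segs <- rbind(segs, do.call(rbind, extra))
  segs <- segs[order(segs$start0), ]
  rownames(segs) <- NULL
  structure(list(sequence = prep$amplicon, segments = segs,
                 barcode_offset0 = off, barcode_length = L,
                 layout = layout, design = design),
            class = "generic_template")
}

#' @export
print.generic_template <- function(x, ...) {
  cat("Generic template:", nchar(x$sequence), "nt; barcode at [",
      x$barcode_offset0, ",", x$barcode_offset0 + x$barcode_length,
      "); ", sum(charToRaw(x$sequence) == charToRaw("N")),
      " wildcard positions\n", sep = "")
  invisible(x)
}

#' Globally align a read against the generic template
#'
#' Global alignment under unit edit costs with template `N` matching any
#' base at zero cost. Among minimum-cost alignments, ties prefer
#' substitutions over paired indels and fewer, longer gap runs over
#' scattered ones (an infinitesimal gap-opening surcharge); remaining ties
#' place gap runs at their rightmost equivalent position, which anchors a
#' chimeric deletion at its ligatable nick instead of letting it slide
#' through zero-cost wildcard columns. The edit script applied to the
#' template reproduces the read exactly.
#'
#' @param read read sequence.
#' @param template a `generic_template` (or plain template string).
#' @return an object of class `alignment_result`: `cost`, `edits`
#'   (data.frame `op`, `tpos` 1-based, `base`), `n_sub`, `n_ins`, `n_del`,
#'   `projected` (per-template-position read bases, `NA` at deletions),
#'   `segment_deletions` (deleted nt per template segment, when a segment
#'   map is available), `read_length`, `template_length`.
#' @export
align_read <- function(read, template) {
  tseq <- if (inherits(template, "generic_template")) template$sequence
          else template
  if (!nzchar(read)) stop("read must be non-empty", call. = FALSE)
  if (nchar(read) > 3L * nchar(tseq)) {
    stop("read longer than 3x template: rejecting as foreign sequence",
         call. = FALSE)
  }
  res <- align_nw_cpp(read, tseq)
  finish_alignment(res, read, template)
}

# Shared constructor for alignment_result objects from the C++ edit script.
finish_alignment <- function(res, read, template) {
  tseq <- if (inherits(template, "generic_template")) template$sequence
          else template
  n <- nchar(tseq)
  op <- res$op
  keep <- op != 0L
  edits <- data.frame(op = c("match", "sub", "del", "ins", "nfill")[op[keep] + 1L],
                      tpos = res$tpos[keep],
                      base = res$base[keep], stringsAsFactors = FALSE)
  projected <- rep(NA_character_, n)
  cons <- op %in% c(0L, 1L, 4L)
  projected[res$tpos[cons]] <- res$base[cons]
  seg_del <- NULL
  if (inherits(template, "generic_template")) {
    segs <- template$segments
    del_pos <- res$tpos[op == 2L]
    seg_del <- vapply(seq_len(nrow(segs)), function(i) {
      sum(del_pos > segs$start0[i] & del_pos <= segs$end0[i])
    }, integer(1))
    names(seg_del) <- segs$name
  }
  structure(list(cost = res$cost,
                 edits = edits,
                 n_sub = sum(op == 1L),
                 n_ins = sum(op == 3L),
                 n_del = sum(op == 2L),
                 projected = projected,
                 segment_deletions = seg_del,
                 read_length = nchar(read),
                 template_length = n),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Alignment: cost", x$cost, "(", x$n_sub, "sub,", x$n_del, "del,",
      x$n_ins, "ins ) read", x$read_length, "nt vs template",
      x$template_length, "nt\n")
  invisible(x)
}

#' Reconstruct a read from the template and an edit script
#'
#' Inverse of [align_read()]: applying the edit script to the template must
#' reproduce the read exactly.
#'
#' @param template template string or `generic_template`.
#' @param aln an `alignment_result`.
#' @return the reconstructed read string.
#' @export
apply_alignment <- function(template, aln) {
  tseq <- if (inherits(template, "generic_template")) template$sequence
          else template
  n <- nchar(tseq)
  chars <- strsplit(tseq, "", fixed = TRUE)[[1]]
  ins_after <- vector("list", n + 1L)  # ins_after[[t + 1]]: bases after pos t
  e <- aln$edits
  for (k in seq_len(nrow(e))) {
    t <- e$tpos[k]
    switch(e$op[k],
      sub = , nfill = { chars[t] <- e$base[k] },
      del = { chars[t] <- NA_character_ },
      ins = { ins_after[[t + 1L]] <- c(ins_after[[t + 1L]], e$base[k]) })
  }
  pieces <- character(0)
  for (t in 0:n) {
    if (t > 0L && !is.na(chars[t])) pieces <- c(pieces, chars[t])
    if (!is.null(ins_after[[t + 1L]])) {
      pieces <- c(pieces, ins_after[[t + 1L]])
    }
  }
  paste(pieces, collapse = "")
}
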