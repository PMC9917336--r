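# Read decoding: alignment to the N-wildcard amplicon template, TrapTag
# demultiplexing, variable-region decoding, read classification, and the
# downstream reports (recovery, deletion profiles, substitution spectra).
#
# Reads whose length equals the template and whose non-wildcard mismatch
# count is at most 2 are handled by a vectorized substitutions-only fast
# path (provably a minimum-cost alignment there: any alignment containing an
# indel pair costs at least 2, and ties prefer substitutions). All other
# reads go through the C++ global aligner.

raw_matrix <- function(strings, width) {
  matrix(unlist(lapply(strings, charToRaw), use.names = FALSE),
         nrow = length(strings), ncol = width, byrow = TRUE)
}

# Nearest-unique whitelist assignment of extracted tag strings.
match_tags <- function(tags, whitelist, max_mismatch = 1L) {
  out <- whitelist[match(tags, whitelist)]
  todo <- which(is.na(out) & !is.na(tags) & nchar(tags) == nchar(whitelist[1]))
  if (length(todo)) {
    wmat <- seq_matrix(whitelist)
    for (i in todo) {
      d <- ham_to_all(charToRaw(tags[i]), wmat)
      dmin <- min(d)
      if (dmin <= max_mismatch && sum(d == dmin) == 1L) {
        out[i] <- whitelist[which.min(d)]
      }
    }
  }
  out
}

#' Demultiplex one amplicon read by its TrapTag UMI
#'
#' Locates the 8-nt UMI window by exact (then near, up to 2 mismatches)
#' match of the flanking TrapTag-primer sequence and assigns the unique
#' whitelist tag within `max_mismatch`. Returns `NA` when the flank cannot
#' be located, no tag is close enough, or two tags tie.
#'
#' @param amplicon read sequence.
#' @param whitelist character vector of equal-length tags.
#' @param template the full-amplicon `generic_template` (supplies the flank
#'   sequence downstream of the UMI).
#' @param max_mismatch whitelist matching tolerance (default 1).
#' @return the assigned tag or `NA_character_`.
#' @export
demultiplex <- function(amplicon, whitelist, template, max_mismatch = 1L) {
  if (!length(whitelist)) stop("whitelist must be non-empty", call. = FALSE)
  if (length(unique(nchar(whitelist))) != 1L) {
    stop("whitelist tags must have equal length", call. = FALSE)
  }
  tag_len <- nchar(whitelist[1])
  segs <- template$segments
  ti <- match("traptag", segs$name)
  if (is.na(ti)) stop("template has no traptag segment", call. = FALSE)
  flank_len <- 18L
  flank <- substr(template$sequence, segs$end0[ti] + 1L,
                  min(segs$end0[ti] + flank_len, nchar(template$sequence)))
  p <- regexpr(flank, amplicon, fixed = TRUE)[1]
  if (p < 0L) {
    # near match: best Hamming placement of the flank, up to 2 mismatches
    L <- nchar(amplicon)
    fl <- nchar(flank)
    best <- c(pos = -1L, mm = fl + 1L)
    fraw <- charToRaw(flank)
    araw <- charToRaw(amplicon)
    if (L >= fl) {
      for (s in 0:(L - fl)) {
        mm <- sum(araw[(s + 1L):(s + fl)] != fraw)
        if (mm < best["mm"]) best <- c(pos = s + 1L, mm = mm)
      }
    }
    if (best["mm"] > 2L) return(NA_character_)
    p <- best["pos"]
  }
  if (p - tag_len < 1L) return(NA_character_)
  tag <- substr(amplicon, p - tag_len, p - 1L)
  match_tags(tag, whitelist, max_mismatch)
}

#' Decode the variable regions of an aligned read
#'
#' Reads off the aligned bases at each variable region and assigns the
#' variant with the unique minimum Hamming distance, provided that distance
#' is at most `max_per_region_distance`. A deletion overlapping any variable
#' region, a missing unique minimum, or an over-threshold distance yields no
#' assignment.
#'
#' @param aln an `alignment_result` against the design's generic template.
#' @param design the `library_design`.
#' @param template the `generic_template` the read was aligned to.
#' @param max_per_region_distance per-region tolerance; default
#'   `floor(min_hamming / 2)` from the design's code constraints.
#' @return 1-based integer vector of variant indices (one per block), or
#'   `NULL` when unassignable.
#' @export
assign_barcode <- function(aln, design, template,
                           max_per_region_distance = NULL) {
  if (is.null(max_per_region_distance)) {
    max_per_region_distance <-
      floor(design$vset$constraints$min_hamming / 2)
  }
  segs <- template$segments
  vrows <- which(segs$role == "variable")
  out <- integer(length(vrows))
  for (bi in seq_along(vrows)) {
    r <- vrows[bi]
    obs <- aln$projected[(segs$start0[r] + 1L):segs$end0[r]]
    if (anyNA(obs)) return(NULL)
    obs_raw <- charToRaw(paste(obs, collapse = ""))
    d <- ham_to_all(obs_raw, seq_matrix(design$vset$sequences[[bi]]))
    dmin <- min(d)
    if (dmin > max_per_region_distance || sum(d == dmin) != 1L) return(NULL)
    out[bi] <- which.min(d)
  }
  out
}

barcode_id <- function(variants) {
  paste0("bc_", paste(variants - 1L, collapse = "_"))
}

#' Classify one aligned read
#'
#' Category rules over the barcode span of the alignment: any insertion
#' makes the read `unclassified`; otherwise any deletion makes it a
#' `deletion_variant` (regardless of co-occurring substitutions); otherwise
#' a read with zero substitutions and a full variable-region assignment is
#' `perfect`, exactly one substitution is `substitution_1nt`, and anything
#' else is `unclassified`. Substitutions inside variable regions are counted
#' against the assigned (or nearest) variant.
#'
#' @param aln an `alignment_result` against the full generic template.
#' @param assignment result of [assign_barcode()] (or `NULL`).
#' @param design the `library_design`.
#' @param template the `generic_template`.
#' @return an object of class `classified_read`: `category`, `barcode`
#'   (id or `NA`), `n_sub`, `n_ins`, `n_del`, `deletion_signature` (named
#'   per-display-region deleted nt, when applicable).
#' @export
classify_read <- function(aln, assignment, design, template) {
  segs <- template$segments
  b0 <- template$barcode_offset0
  b1 <- b0 + template$barcode_length
  e <- aln$edits
  in_bc <- e$tpos > b0 & e$tpos <= b1
  n_ins <- sum(e$op == "ins" & e$tpos >= b0 & e$tpos <= b1)
  n_del <- sum(e$op == "del" & in_bc)
  n_sub_const <- sum(e$op == "sub" & in_bc)
  # variable-region mismatches vs the assigned (or nearest) variant
  vrows <- which(segs$role == "variable")
  n_sub_var <- 0L
  for (bi in seq_along(vrows)) {
    r <- vrows[bi]
    obs <- aln$projected[(segs$start0[r] + 1L):segs$end0[r]]
    if (anyNA(obs)) next  # deleted bases already counted as deletions
    obs_raw <- charToRaw(paste(obs, collapse = ""))
    if (!is.null(assignment)) {
      v <- design$vset$sequences[[bi]][assignment[bi]]
      n_sub_var <- n_sub_var + sum(obs_raw != charToRaw(v))
    } else {
      d <- ham_to_all(obs_raw, seq_matrix(design$vset$sequences[[bi]]))
      n_sub_var <- n_sub_var + min(d)
    }
  }
  n_sub <- n_sub_const + n_sub_var
  sig <- NULL
  if (n_ins == 0L && n_del > 0L) {
    brows <- segs$name %in% design$layout$name
    sd <- aln$segment_deletions[segs$name[brows]]
    reg <- segs$region[brows]
    sig <- tapply(sd, reg, sum)
    sig <- sig[sig > 0L]
  }
  category <- if (n_ins > 0L) "unclassified"
    else if (n_del > 0L) "deletion_variant"
    else if (n_sub == 0L && !is.null(assignment)) "perfect"
    else if (n_sub == 1L) "substitution_1nt"
    else "unclassified"
  structure(list(category = category,
                 barcode = if (!is.null(assignment)) barcode_id(assignment)
                           else NA_character_,
                 n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                 deletion_signature = sig),
            class = "classified_read")
}

signature_string <- function(sig) {
  if (is.null(sig) || !length(sig)) return(NA_character_)
  paste(sprintf("%s:%d", names(sig), as.integer(sig)), collapse = ";")
}

#' Decode a batch of reads
#'
#' End-to-end decoding: align each read to the full-amplicon N-wildcard
#' template, extract and demultiplex the TrapTag, decode the variable
#' regions, and classify the read. Same-length low-mismatch reads take a
#' vectorized substitutions-only fast path; all others use the global
#' aligner.
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @param design a `library_design`.
#' @param max_mismatch_tag whitelist tolerance for TrapTag assignment.
#' @param max_per_region_distance per-region variable-region tolerance;
#'   default `floor(min_hamming / 2)`.
#' @param chunk_size fast-path chunk size (memory guard).
#' @return an object of class `decoded_reads`: a data.frame with one row per
#'   read (`category`, `barcode`, `traptag`, `n_sub`, `n_ins`, `n_del`,
#'   `full_length_noindel`, `deletion_signature`), with the substitution
#'   events (`read`, `bpos`, `from`, `to`) in `attr(, "sub_events")` and the
#'   template in `attr(, "template")`.
#' @export
decode_reads <- function(reads, design, max_mismatch_tag = 1L,
                         max_per_region_distance = NULL,
                         chunk_size = 20000L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  template <- make_generic_template(design, full = TRUE)
  if (is.null(max_per_region_distance)) {
    max_per_region_distance <-
      floor(design$vset$constraints$min_hamming / 2)
  }
  n <- nchar(template$sequence)
  traw <- charToRaw(template$sequence)
  n_pos <- traw == charToRaw("N")
  segs <- template$segments
  b0 <- template$barcode_offset0
  b1 <- b0 + template$barcode_length
  bc_cols <- (b0 + 1L):b1
  ti <- match("traptag", segs$name)
  tag_cols <- if (!is.na(ti)) (segs$start0[ti] + 1L):segs$end0[ti]
  vrows <- which(segs$role == "variable")
  vcols <- lapply(vrows, function(r) (segs$start0[r] + 1L):segs$end0[r])
  vmats <- lapply(design$vset$sequences, seq_matrix)
  whitelist <- design$traptag_whitelist

  nr <- length(reads)
  category <- character(nr)
  barcode <- rep(NA_character_, nr)
  traptag <- rep(NA_character_, nr)
  n_sub <- integer(nr); n_ins <- integer(nr); n_del <- integer(nr)
  flni <- logical(nr)
  delsig <- rep(NA_character_, nr)
  events <- list()

  lens <- nchar(reads)
  fast_candidate <- which(lens == n)
  slow <- which(lens != n)

  # ---- fast path, chunked ----
  for (chunk in split(fast_candidate,
                      ceiling(seq_along(fast_candidate) / chunk_size))) {
    m <- raw_matrix(reads[chunk], n)
    tmat <- matrix(traw, length(chunk), n, byrow = TRUE)
    mm <- (m != tmat) & matrix(!n_pos, length(chunk), n, byrow = TRUE)
    cnt <- rowSums(mm)
    ok <- cnt <= 2L
    if (any(!ok)) slow <- c(slow, chunk[!ok])
    if (!any(ok)) next
    ridx <- chunk[ok]
    mo <- m[ok, , drop = FALSE]
    mmo <- mm[ok, , drop = FALSE]
    cnt_bc <- rowSums(mmo[, bc_cols, drop = FALSE])
    # variable-region decoding
    nb <- length(vcols)
    assign_mat <- matrix(NA_integer_, length(ridx), nb)
    dmin_mat <- matrix(0L, length(ridx), nb)
    for (bi in seq_len(nb)) {
      sub <- mo[, vcols[[bi]], drop = FALSE]
      vm <- vmats[[bi]]
      dv <- vapply(seq_len(nrow(vm)), function(v) {
        rowSums(sub != matrix(vm[v, ], nrow(sub), ncol(vm), byrow = TRUE))
      }, numeric(nrow(sub)))
      if (!is.matrix(dv)) dv <- matrix(dv, nrow = nrow(sub))
      dmin <- do.call(pmin, as.data.frame(dv))
      namb <- rowSums(dv == dmin)
      best <- max.col(-dv, ties.method = "first")
      assign_mat[, bi] <- ifelse(namb == 1L & dmin <= max_per_region_distance,
                                 best, NA_integer_)
      dmin_mat[, bi] <- as.integer(dmin)
    }
    assigned <- rowSums(is.na(assign_mat)) == 0L
    nsub_tot <- as.integer(cnt_bc + rowSums(dmin_mat))
    # TrapTag
    if (!is.null(tag_cols)) {
      tag_sub <- mo[, tag_cols, drop = FALSE]
      big <- rawToChar(as.raw(t(tag_sub)))
      tl <- length(tag_cols)
      tags <- substring(big, seq(1L, tl * nrow(tag_sub), tl),
                        seq(tl, tl * nrow(tag_sub), tl))
      traptag[ridx] <- match_tags(tags, whitelist, max_mismatch_tag)
    }
    barcode[ridx] <- ifelse(assigned,
                            apply(assign_mat, 1L, function(v)
                              if (anyNA(v)) NA_character_ else barcode_id(v)),
                            NA_character_)
    n_sub[ridx] <- nsub_tot
    flni[ridx] <- TRUE
    category[ridx] <- ifelse(nsub_tot == 0L & assigned, "perfect",
                       ifelse(nsub_tot == 1L, "substitution_1nt",
                              "unclassified"))
    # substitution events within the barcode span
    w <- which(mmo[, bc_cols, drop = FALSE], arr.ind = TRUE)
    if (nrow(w)) {
      tp <- bc_cols[w[, 2]]
      events[[length(events) + 1L]] <- data.frame(
        read = ridx[w[, 1]], bpos = tp - b0,
        from = strsplit(rawToChar(traw[tp]), "")[[1]],
        to = strsplit(rawToChar(as.raw(mo[w])), "")[[1]],
        stringsAsFactors = FALSE)
    }
    # variable-position events vs the assigned variant
    for (bi in seq_len(nb)) {
      rows <- which(!is.na(assign_mat[, bi]) & dmin_mat[, bi] > 0L)
      if (!length(rows)) next
      sub <- mo[rows, vcols[[bi]], drop = FALSE]
      exp_mat <- vmats[[bi]][assign_mat[rows, bi], , drop = FALSE]
      w <- which(sub != exp_mat, arr.ind = TRUE)
      if (nrow(w)) {
        tp <- vcols[[bi]][w[, 2]]
        events[[length(events) + 1L]] <- data.frame(
          read = ridx[rows[w[, 1]]], bpos = tp - b0,
          from = strsplit(rawToChar(as.raw(exp_mat[w])), "")[[1]],
          to = strsplit(rawToChar(as.raw(sub[w])), "")[[1]],
          stringsAsFactors = FALSE)
      }
    }
  }

  # ---- slow path: global alignment ----
  for (i in slow) {
    aln <- tryCatch(align_read(reads[i], template),
                    error = function(e) NULL)
    if (is.null(aln)) { category[i] <- "unclassified"; next }
    assignment <- assign_barcode(aln, design, template,
                                 max_per_region_distance)
    cl <- classify_read(aln, assignment, design, template)
    category[i] <- cl$category
    barcode[i] <- cl$barcode
    n_sub[i] <- cl$n_sub; n_ins[i] <- cl$n_ins; n_del[i] <- cl$n_del
    delsig[i] <- signature_string(cl$deletion_signature)
    flni[i] <- aln$n_ins == 0L && aln$n_del == 0L &&
      aln$read_length == n
    if (!is.null(tag_cols)) {
      obs <- aln$projected[tag_cols]
      if (!anyNA(obs)) {
        traptag[i] <- match_tags(paste(obs, collapse = ""), whitelist,
                                 max_mismatch_tag)
      }
    }
    if (flni[i] && cl$n_sub > 0L) {
      ev <- sub_events_from_alignment(aln, assignment, design, template)
      if (nrow(ev)) { ev$read <- i; events[[length(events) + 1L]] <- ev }
    }
  }

  out <- data.frame(category = category, barcode = barcode,
                    traptag = traptag, n_sub = as.integer(n_sub),
                    n_ins = as.integer(n_ins), n_del = as.integer(n_del),
                    full_length_noindel = flni,
                    deletion_signature = delsig, stringsAsFactors = FALSE)
  attr(out, "sub_events") <- if (length(events)) do.call(rbind, events)
    else data.frame(read = integer(0), bpos = integer(0),
                    from = character(0), to = character(0))
  attr(out, "template") <- template
  class(out) <- c("decoded_reads", "data.frame")
  out
}

# Substitution events (barcode span) for one aligned read.
sub_events_from_alignment <- function(aln, assignment, design, template) {
  segs <- template$segments
  b0 <- template$barcode_offset0
  b1 <- b0 + template$barcode_length
  e <- aln$edits
  ev <- e[e$op == "sub" & e$tpos > b0 & e$tpos <= b1, , drop = FALSE]
  out <- if (nrow(ev)) {
    data.frame(read = NA_integer_, bpos = ev$tpos - b0,
               from = substring(template$sequence, ev$tpos, ev$tpos),
               to = ev$base, stringsAsFactors = FALSE)
  } else {
    data.frame(read = integer(0), bpos = integer(0), from = character(0),
               to = character(0))
  }
  if (!is.null(assignment)) {
    vrows <- which(segs$role == "variable")
    for (bi in seq_along(vrows)) {
      r <- vrows[bi]
      cols <- (segs$start0[r] + 1L):segs$end0[r]
      obs <- aln$projected[cols]
      if (anyNA(obs)) next
      v <- strsplit(design$vset$sequences[[bi]][assignment[bi]], "")[[1]]
      d <- which(obs != v)
      if (length(d)) {
        out <- rbind(out, data.frame(read = NA_integer_,
                                     bpos = cols[d] - b0,
                                     from = v[d], to = obs[d],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Recovery report: read counts per (barcode, TrapTag)
#'
#' @param decoded a `decoded_reads` object.
#' @return data.frame of counts keyed by assigned barcode and tag, with
#'   attributes `distinct_barcodes` (tuples with at least one read) and
#'   `unassigned` (reads without a barcode assignment).
#' @export
recovery_report <- function(decoded) {
  ok <- !is.na(decoded$barcode)
  if (!any(ok)) {
    out <- data.frame(barcode = character(0), traptag = character(0),
                      count = integer(0))
  } else {
    key <- paste(decoded$barcode[ok],
                 ifelse(is.na(decoded$traptag[ok]), "NA",
                        decoded$traptag[ok]), sep = "\t")
    tab <- table(key)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    out <- data.frame(barcode = vapply(parts, `[`, "", 1L),
                      traptag = vapply(parts, `[`, "", 2L),
                      count = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(-out$count), ]
    rownames(out) <- NULL
  }
  attr(out, "distinct_barcodes") <- length(unique(decoded$barcode[ok]))
  attr(out, "unassigned") <- sum(!ok)
  out
}

#' Deletion profile: ranked deletion-variant signatures
#'
#' Groups deletion-variant reads by their per-region deletion signature and
#' returns ranked counts plus the heatmap matrix (signatures x display
#' regions, cell = deleted nt).
#'
#' @param decoded a `decoded_reads` object.
#' @param top_n number of top signatures to report (default 10).
#' @return an object of class `deletion_profile`: `counts` (signature,
#'   count) and `heatmap` (matrix).
#' @export
deletion_profile <- function(decoded, top_n = 10L) {
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  d <- decoded[decoded$category == "deletion_variant" &
                 !is.na(decoded$deletion_signature), , drop = FALSE]
  template <- attr(decoded, "template")
  regions <- unique(template$segments$region[
    template$segments$name %in% template$layout$name])
  if (!nrow(d)) {
    return(structure(list(
      counts = data.frame(signature = character(0), count = integer(0)),
      heatmap = matrix(0L, 0, length(regions),
                       dimnames = list(NULL, regions))),
      class = "deletion_profile"))
  }
  tab <- sort(table(d$deletion_signature), decreasing = TRUE)
  tab <- head(tab, top_n)
  hm <- matrix(0L, length(tab), length(regions),
               dimnames = list(names(tab), regions))
  for (i in seq_along(tab)) {
    parts <- strsplit(strsplit(names(tab)[i], ";", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    for (p in parts) hm[i, p[1]] <- as.integer(p[2])
  }
  structure(list(counts = data.frame(signature = names(tab),
                                     count = as.integer(tab),
                                     stringsAsFactors = FALSE),
                 heatmap = hm),
            class = "deletion_profile")
}

#' @export
print.deletion_profile <- function(x, ...) {
  cat("Deletion profile:", nrow(x$counts), "signatures\n")
  print(x$counts)
  invisible(x)
}

#' Substitution spectrum over full-length, indel-free reads
#'
#' Per-position and per-type substitution counts over the barcode span,
#' computed over full-length reads containing no insertions or deletions.
#' Constant positions take their from-base from the template; variable
#' positions from the assigned variant.
#'
#' @param decoded a `decoded_reads` object.
#' @return an object of class `substitution_spectrum`: `per_position`
#'   (counts, length = barcode length), `type_matrix` (4x4 from x to),
#'   `denominator` (number of qualifying reads).
#' @export
substitution_spectrum <- function(decoded) {
  template <- attr(decoded, "template")
  L <- template$barcode_length
  ev <- attr(decoded, "sub_events")
  keep <- decoded$full_length_noindel[ev$read]
  ev <- ev[keep, , drop = FALSE]
  per_pos <- tabulate(ev$bpos, nbins = L)
  tm <- matrix(0L, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (nrow(ev)) {
    t2 <- table(factor(ev$from, DNA_BASES), factor(ev$to, DNA_BASES))
    tm <- tm + unclass(t2)
  }
  structure(list(per_position = per_pos, type_matrix = tm,
                 denominator = sum(decoded$full_length_noindel)),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("Substitution spectrum over", length(x$per_position),
      "positions;", sum(x$per_position), "substitutions in",
      x$denominator, "full-length indel-free reads\n")
  invisible(x)
}

#' Mean per-nucleotide substitution rate
#'
#' The per-position substitution rate is the position's count divided by the
#' number of full-length indel-free reads; the estimator returns the mean
#' and standard deviation of those rates over all barcode positions.
#'
#' @param spectrum a `substitution_spectrum`.
#' @return list with `mean` and `sd` (fractions, not percent).
#' @export
mean_substitution_rate <- function(spectrum) {
  if (spectrum$denominator <= 0L) {
    stop("spectrum denominator is zero: no qualifying reads", call. = FALSE)
  }
  rates <- spectrum$per_position / spectrum$denominator
  list(mean = mean(rates), sd = stats::sd(rates))
}

#' Category partition of decoded reads
#'
#' @param decoded a `decoded_reads` object.
#' @return named numeric vector of category percentages (summing to 100 for
#'   non-empty input).
#' @export
category_summary <- function(decoded) {
  cats <- c("perfect", "deletion_variant", "substitution_1nt",
            "unclassified")
  n <- nrow(decoded)
  counts <- vapply(cats, function(cc) sum(decoded$category == cc),
                   numeric(1))
  if (n == 0L) return(setNames(rep(0, length(cats)), cats))
  100 * counts / n
}
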