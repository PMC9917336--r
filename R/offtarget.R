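# Off-target assembly prediction.
#
# During annealing, a block's bottom strand presents a single-stranded
# interface at its right-hand (ligatable) nick: the 10-nt junction overhang
# plus, while strands are free in solution, the adjacent bases of the block -
# in this layout the nick-adjacent variable region. Another block's left
# overhang is recruited to the wrong partner when that interface imitates the
# interface of the block it was designed to follow. Edges are scored by
# counting matching bases between the two top-strand interface windows
# anchored at the nick, requiring the bases nearest the nick to match
# exactly (those must pair for the ligase to seal the nick).

# Top-strand interface window of width `window` ending at block bi's
# bottom-strand nick, for variant vi.
right_interface_window <- function(design, bi, vi, window) {
  spans <- block_spans(design$layout)
  b_end <- spans$bot_end[bi]
  w0 <- max(0L, b_end - window)
  layout <- design$layout
  r <- which(layout$role == "variable")[bi]
  full <- design$template
  substr(full, layout$start0[r] + 1L, layout$end0[r]) <-
    design$vset$sequences[[bi]][vi]
  substr(full, w0 + 1L, b_end)
}

# Matching positions between two equal-length windows, counted with position
# 1 adjacent to the nick (right end).
window_match <- function(wa, wb) {
  a <- rev(charToRaw(wa))
  b <- rev(charToRaw(wb))
  n <- min(length(a), length(b))
  a[seq_len(n)] == b[seq_len(n)]
}

#' Predict off-target chimeric ligation products
#'
#' Builds a junction graph with one node per (position, variant) plus source
#' and sink. Designed edges join consecutive positions. An off-target edge
#' joins block (i, u) to position j (j != i + 1, j >= 2) when block i's
#' right-hand single-stranded interface window imitates the designed
#' upstream interface of position j - that is, when the two windows match in
#' at least `min_junction_match` positions, with the `require_nick_match`
#' positions nearest the ligatable nick matching exactly. All simple
#' source-to-sink paths are enumerated; non-designed paths are returned as
#' predicted amplifiable products (every path carries both terminal primer
#' regions), sorted by total off-target junction score, descending. For
#' products without positional backtracking (strictly increasing block
#' positions) the deleted template span is attributed per layout segment and
#' per display region.
#'
#' @param design a `library_design`.
#' @param min_junction_match minimum matching bases within the interface
#'   window (default 4).
#' @param require_nick_match number of nick-adjacent bases that must match
#'   exactly (default 2).
#' @param window interface window width in nt (default 16).
#' @param max_path_blocks maximum number of blocks per enumerated product
#'   (default: the design's block count, focusing the enumeration on
#'   deletion variants and same-size scrambles; raise it to chase longer
#'   insertion products).
#' @param max_products size-limit guard on the number of enumerated paths.
#' @return list of `offtarget_assembly` objects (possibly empty), each with
#'   `path` (data.frame of block/variant), `junction_scores`,
#'   `product_sequence`, `product_length`, `deleted_regions` (per layout
#'   segment; `NULL` when the path contains positional backtracking),
#'   `deleted_by_region` (display regions), `has_insertion`, `amplifiable`.
#' @export
find_offtarget_assemblies <- function(design, min_junction_match = 4L,
                                      require_nick_match = 2L,
                                      window = 16L, max_path_blocks = NULL,
                                      max_products = 10000L) {
  if (min_junction_match < 1L) {
    stop("min_junction_match must be >= 1", call. = FALSE)
  }
  if (require_nick_match < 0L) {
    stop("require_nick_match must be >= 0", call. = FALSE)
  }
  n_blocks <- length(design$blocks)
  nv <- vapply(design$blocks, length, integer(1))
  if (n_blocks < 2L) return(list())

  # node table: source, sink, then one node per (position, variant)
  nodes <- data.frame(pos = c(0L, n_blocks + 1L,
                              rep(seq_len(n_blocks), nv)),
                      var = c(0L, 0L,
                              unlist(lapply(nv, seq_len))))
  node_id <- function(pos, var) {
    if (pos == 0L) return(1L)
    if (pos == n_blocks + 1L) return(2L)
    2L + sum(nv[seq_len(pos - 1L)]) + var
  }

  windows <- lapply(seq_len(n_blocks), function(bi) {
    vapply(seq_len(nv[bi]),
           function(vi) right_interface_window(design, bi, vi, window),
           character(1))
  })

  edges <- integer(0)
  scores <- numeric(0)
  offtarget <- logical(0)
  add_edge <- function(from, to, score, off) {
    edges <<- c(edges, from, to)
    scores <<- c(scores, score)
    offtarget <<- c(offtarget, off)
  }
  for (u in seq_len(nv[1])) add_edge(1L, node_id(1L, u), 0, FALSE)
  for (u in seq_len(nv[n_blocks])) {
    add_edge(node_id(n_blocks, u), 2L, 0, FALSE)
  }
  for (i in seq_len(n_blocks - 1L)) {
    for (u in seq_len(nv[i])) {
      for (v in seq_len(nv[i + 1L])) {
        add_edge(node_id(i, u), node_id(i + 1L, v), 0, FALSE)
      }
    }
  }
  # off-target edges
  for (i in seq_len(n_blocks - 1L)) {
    for (u in seq_len(nv[i])) {
      wi <- windows[[i]][u]
      for (j in 2:n_blocks) {
        if (j == i + 1L) next
        best <- 0L
        for (w in seq_len(nv[j - 1L])) {
          if (j - 1L == i && w == u) next
          m <- window_match(wi, windows[[j - 1L]][w])
          if (length(m) < require_nick_match) next
          if (require_nick_match > 0L &&
              !all(m[seq_len(require_nick_match)])) next
          best <- max(best, sum(m))
        }
        if (best >= min_junction_match) {
          for (v in seq_len(nv[j])) {
            add_edge(node_id(i, u), node_id(j, v), best, TRUE)
          }
        }
      }
    }
  }

  if (is.null(max_path_blocks)) max_path_blocks <- n_blocks
  g <- igraph::make_graph(edges, n = nrow(nodes), directed = TRUE)
  paths <- igraph::all_simple_paths(g, from = 1L, to = 2L, mode = "out",
                                    cutoff = max_path_blocks + 1L)
  if (length(paths) > max_products) {
    stop("off-target junction graph yields more than max_products paths",
         call. = FALSE)
  }
  eid_lookup <- function(a, b) igraph::get_edge_ids(g, c(a, b))

  spans <- block_spans(design$layout)
  layout <- design$layout
  L <- attr(layout, "total")
  out <- list()
  for (p in paths) {
    v <- as.integer(p)
    inner <- v[-c(1L, length(v))]
    pos <- nodes$pos[inner]
    var <- nodes$var[inner]
    eids <- vapply(seq_len(length(v) - 1L),
                   function(k) eid_lookup(v[k], v[k + 1L]), numeric(1))
    off <- offtarget[eids]
    if (!any(off)) next  # designed product
    jscores <- scores[eids][off]
    tops <- vapply(seq_along(pos), function(k) {
      design$blocks[[pos[k]]][[var[k]]]$top_strand
    }, character(1))
    prod_seq <- paste(tops, collapse = "")
    increasing <- all(diff(pos) > 0L)
    deleted <- NULL
    deleted_by_region <- NULL
    if (increasing) {
      deleted <- setNames(integer(nrow(layout)), layout$name)
      for (k in seq_len(length(pos) - 1L)) {
        i <- pos[k]; j <- pos[k + 1L]
        if (j == i + 1L) next
        # skipped top-strand span [t_i, t_{j-1})
        from <- spans$top_end[i]
        to <- spans$top_start[j]
        ov_start <- pmax(layout$start0, from)
        ov_end <- pmin(layout$end0, to)
        ov <- pmax(0L, ov_end - ov_start)
        deleted <- deleted + setNames(ov, layout$name)
      }
      deleted_by_region <- tapply(deleted, layout$region, sum)
      deleted_by_region <- deleted_by_region[deleted_by_region > 0L]
      deleted <- deleted[deleted > 0L]
    }
    out[[length(out) + 1L]] <- structure(list(
      path = data.frame(block = pos, variant = var),
      junction_scores = as.integer(jscores),
      product_sequence = prod_seq,
      product_length = nchar(prod_seq),
      deleted_regions = if (increasing) as.list(deleted) else NULL,
      deleted_by_region = if (increasing) as.list(deleted_by_region)
                          else NULL,
      has_insertion = !increasing,
      amplifiable = TRUE), class = "offtarget_assembly")
  }
  ord <- order(vapply(out, function(x) sum(x$junction_scores), numeric(1)),
               decreasing = TRUE)
  out[ord]
}

#' @export
print.offtarget_assembly <- function(x, ...) {
  cat("Off-target assembly: blocks",
      paste(sprintf("%d.v%d", x$path$block, x$path$variant), collapse = " -> "),
      "\n  product", x$product_length, "bp; junction scores",
      paste(x$junction_scores, collapse = ","), "\n")
  if (!is.null(x$deleted_regions)) {
    cat("  deleted:",
        paste(sprintf("%s:%d", names(x$deleted_regions),
                      unlist(x$deleted_regions)), collapse = ", "), "\n")
  } else if (x$has_insertion) {
    cat("  contains positional backtracking (insertion-bearing product)\n")
  }
  invisible(x)
}

#' Tabulate off-target assemblies
#'
#' @param assemblies result of [find_offtarget_assemblies()].
#' @param layout the design's `layout_config` (for segment columns).
#' @return data.frame: path, total score, product length, deleted nt per
#'   layout segment.
#' @export
offtarget_report <- function(assemblies, layout) {
  if (!length(assemblies)) {
    return(data.frame(path = character(0), total_score = integer(0),
                      product_length = integer(0), deleted_nt = integer(0)))
  }
  rows <- lapply(assemblies, function(x) {
    del <- if (is.null(x$deleted_regions)) NA_integer_
           else sum(unlist(x$deleted_regions))
    d <- data.frame(
      path = paste(sprintf("%d.v%d", x$path$block, x$path$variant),
                   collapse = "->"),
      total_score = sum(x$junction_scores),
      product_length = x$product_length,
      deleted_nt = del)
    for (seg in layout$name) {
      d[[seg]] <- if (is.null(x$deleted_regions)) NA_integer_
                  else if (!is.null(x$deleted_regions[[seg]]))
                    x$deleted_regions[[seg]] else 0L
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
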