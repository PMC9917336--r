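# Independent oracles and small fixtures used across the test suite.

# Plain dynamic-programming edit distance with template-N wildcard; cost
# only. Written straightforwardly and kept independent of the package's
# aligner.
oracle_edit_cost <- function(read, tmpl) {
  tt <- strsplit(tmpl, "", fixed = TRUE)[[1]]
  rr <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(tt); m <- length(rr)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (tt[i] == "N" || tt[i] == rr[j]) 0L else 1L
      D[i + 1L, j + 1L] <- min(D[i, j] + s, D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  D[n + 1L, m + 1L]
}

# Brute-force count of k-mers with longest homopolymer run <= max_run.
oracle_homopolymer_count <- function(k, max_run) {
  words <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                       stringsAsFactors = FALSE)
  ok <- apply(words, 1L, function(w) max(rle(unlist(w))$lengths) <= max_run)
  sum(ok)
}

# Brute-force maximum feasible subset size under pairwise Hamming and
# shifted-register constraints (tiny pools only).
oracle_max_feasible <- function(pool, min_h, min_sh) {
  n <- length(pool)
  ok_pair <- function(a, b) {
    hamming_distance(a, b) >= min_h &&
      (nchar(a) < 2L || shifted_hamming_min(a, b) >= min_sh)
  }
  best <- 0L
  for (size in n:1) {
    combs <- utils::combn(n, size)
    for (c in seq_len(ncol(combs))) {
      idx <- combs[, c]
      good <- TRUE
      if (size > 1L) {
        for (a in seq_len(size - 1L)) {
          for (b in (a + 1L):size) {
            if (!ok_pair(pool[idx[a]], pool[idx[b]])) { good <- FALSE; break }
          }
          if (!good) break
        }
      }
      if (good) return(size)
    }
  }
  best
}

# Random DNA string helper.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

TOY_FWD <- "ACTGGTCAGTCAGGTCAC"
TOY_REV <- "TGACCTGTCATCCAGTGA"
TOY_TAGP <- "CATCGGATACGGATCGTT"

# Small library design with explicit sequences for assembly tests.
toy_design <- function(n_blocks = 3L, variants = 2L, k = 4L, pad = 2L,
                       overhangs = NULL, vars = NULL, seed = 99L,
                       whitelist_n = 4L) {
  layout <- modbarcode:::std_layout(n_blocks, k, pad)
  cons <- code_constraints(k = k, min_hamming = 1L, min_shifted_hamming = 1L,
                           forbid_duplicates = FALSE)
  if (is.null(vars)) {
    set.seed(seed)
    vars <- replicate(n_blocks, vapply(seq_len(variants),
                                       function(i) rand_dna(k),
                                       character(1)),
                      simplify = FALSE)
  }
  if (is.null(overhangs)) {
    set.seed(seed + 1L)
    overhangs <- vapply(seq_len(max(0L, n_blocks - 1L)),
                        function(i) rand_dna(10L), character(1))
  }
  vset <- variable_region_set(vars, cons, provenance = "toy")
  compile_blocks(layout, vset, overhangs,
                 list(fwd = TOY_FWD, rev = TOY_REV, traptag = TOY_TAGP),
                 traptag_whitelist = make_traptag_whitelist(whitelist_n,
                                                            seed = 3L),
                 seed = seed)
}

# Independent chimera oracle: enumerates all orderings of (position,
# variant) nodes from position 1 to position n (at most n blocks per
# product) and tests each junction directly on the block strands.
oracle_chimera_paths <- function(design, min_match = 4L, nick_match = 2L,
                                 window = 16L) {
  n <- length(design$blocks)
  nv <- vapply(design$blocks, length, integer(1))
  win_of <- function(bi, vi) {
    img <- revcomp(design$blocks[[bi]][[vi]]$bottom_strand)
    substr(img, max(1L, nchar(img) - window + 1L), nchar(img))
  }
  edge_ok <- function(i, u, j) {
    if (j == i + 1L) return(TRUE)
    if (j < 2L) return(FALSE)
    wi <- win_of(i, u)
    for (w in seq_len(nv[j - 1L])) {
      wj <- win_of(j - 1L, w)
      a <- rev(strsplit(wi, "", fixed = TRUE)[[1]])
      b <- rev(strsplit(wj, "", fixed = TRUE)[[1]])
      L <- min(length(a), length(b))
      mt <- a[seq_len(L)] == b[seq_len(L)]
      if (all(mt[seq_len(nick_match)]) && sum(mt) >= min_match) {
        return(TRUE)
      }
    }
    FALSE
  }
  paths <- list()
  recurse <- function(nodes) {
    last <- nodes[[length(nodes)]]
    if (last[1] == n) {
      lab <- paste(vapply(nodes, function(x)
        sprintf("%d.v%d", x[1], x[2]), character(1)), collapse = "->")
      designed <- all(diff(vapply(nodes, `[`, 0L, 1L)) == 1L)
      if (!designed) paths[[length(paths) + 1L]] <<- lab
      return()
    }
    if (length(nodes) >= n) return()
    for (j in 2:n) {
      for (v in seq_len(nv[j])) {
        node <- c(j, v)
        if (any(vapply(nodes, identical, TRUE, node))) next
        if (edge_ok(last[1], last[2], j)) recurse(c(nodes, list(node)))
      }
    }
  }
  for (u in seq_len(nv[1])) recurse(list(c(1L, u)))
  sort(c(unlist(paths), character(0)))
}
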