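test_that("layouts total the published amplicon lengths", {
  l1 <- gen1_layout()
  expect_identical(attr(l1, "total"), 102L)
  expect_identical(attr(l1, "n_blocks"), 4L)
  l2 <- gen2_layout()
  expect_identical(attr(l2, "total"), 128L)
  expect_identical(attr(l2, "n_blocks"), 3L)
  expect_error(modbarcode:::std_layout(4, 6, 3, total = 100), "totals")
})

test_that("block compilation emits the expected oligo counts", {
  d1 <- gen1_design()
  expect_identical(oligo_count(d1), 32L)
  d2 <- gen2_design()
  expect_identical(oligo_count(d2), 48L)
  t1 <- toy_design(n_blocks = 1L, variants = 1L)
  expect_identical(oligo_count(t1), 2L)
  bs <- t1$blocks[[1]][[1]]
  expect_identical(bs$left_overhang, "")
  expect_identical(bs$right_overhang, "")
  sheet <- oligo_sheet(d1)
  expect_identical(nrow(sheet), 32L)
  # nick-flanking strands flagged for 5' phosphorylation
  expect_identical(sum(sheet$five_prime_phosphate), 24L)
})

test_that("annealing a block's strands leaves exactly the declared overhangs", {
  d <- gen1_design()
  spans <- modbarcode:::block_spans(d$layout)
  for (bi in 1:4) {
    for (vi in 1:4) {
      bs <- d$blocks[[bi]][[vi]]
      top <- bs$top_strand
      bot_img <- revcomp(bs$bottom_strand)
      # duplex region = intersection of the two strand spans
      ds <- max(spans$top_start[bi], spans$bot_start[bi])
      de <- min(spans$top_end[bi], spans$bot_end[bi])
      top_dup <- substr(top, ds - spans$top_start[bi] + 1L,
                        de - spans$top_start[bi])
      bot_dup <- substr(bot_img, ds - spans$bot_start[bi] + 1L,
                        de - spans$bot_start[bi])
      expect_identical(top_dup, bot_dup)
      if (bi > 1L) {
        expect_identical(substr(top, 1L, 10L), bs$left_overhang)
      }
      if (bi < 4L) {
        expect_identical(substr(bot_img, nchar(bot_img) - 9L,
                                nchar(bot_img)), bs$right_overhang)
      }
      # variable region at its declared coordinates
      expect_identical(
        substr(top, bs$variable_start0 - bs$top_start0 + 1L,
               bs$variable_start0 - bs$top_start0 + 6L),
        bs$variable_region)
    }
  }
})

test_that("library enumeration is a complete odometer-ordered product", {
  d1 <- gen1_design()
  lib1 <- enumerate_library(d1)
  expect_identical(nrow(lib1), 256L)
  expect_identical(unique(nchar(lib1$sequence)), 102L)
  expect_identical(anyDuplicated(lib1$sequence), 0L)
  expect_identical(lib1$id[1], "bc_0_0_0_0")
  expect_identical(lib1$id[2], "bc_0_0_0_1")  # last position fastest
  expect_identical(lib1$id[256], "bc_3_3_3_3")
  d2 <- gen2_design()
  expect_identical(nrow(enumerate_library(d2)), 512L)
  t23 <- toy_design(n_blocks = 2L, variants = 3L)
  t23$blocks[[1]] <- t23$blocks[[1]][1:2]
  t23$vset$sequences[[1]] <- t23$vset$sequences[[1]][1:2]
  expect_identical(nrow(enumerate_library(t23)), 6L)
  # all members identical outside variable regions
  lay <- d1$layout
  con <- lay[lay$role != "variable", , drop = FALSE]
  for (i in seq_len(nrow(con))) {
    seg <- substr(lib1$sequence, con$start0[i] + 1L, con$end0[i])
    expect_identical(length(unique(seg)), 1L)
  }
})

test_that("in-silico annealing and ligation yields full-length duplexes", {
  d1 <- gen1_design()
  a <- assemble_target(d1, c(2, 3, 1, 4))
  expect_identical(a$length, 102L)
  expect_true(a$ligated)
  expect_identical(a$sequence,
                   enumerate_library(d1)$sequence[
                     match("bc_1_2_0_3", enumerate_library(d1)$id)])
  d2 <- gen2_design()
  expect_identical(assemble_target(d2, c(8, 1, 5))$length, 128L)
  t1 <- toy_design(n_blocks = 1L, variants = 1L)
  a1 <- assemble_target(t1, 1L)
  expect_identical(a1$sequence, t1$blocks[[1]][[1]]$top_strand)
  # a corrupted junction is reported by name
  bad <- d1
  bad$blocks[[2]][[1]]$top_strand <-
    paste0("TTTTTTTTTT", substr(bad$blocks[[2]][[1]]$top_strand, 11, 19))
  expect_error(assemble_target(bad, c(1, 1, 1, 1)), "junction 1")
  # a missing phosphate downgrades to a nick-not-ligatable warning
  warn <- d1
  warn$blocks[[2]][[1]]$five_prime_phosphate["top"] <- FALSE
  expect_warning(res <- assemble_target(warn, c(1, 1, 1, 1)),
                 "phosphate")
  expect_false(res$ligated)
})

test_that("overhang PCR arithmetic matches the printed primer sets", {
  ps <- fixture_primer_sets_gen1()
  prm <- fixture_primers("gen1")
  # the generic four-set constructor reproduces the printed table
  built <- overhang_pcr_sets(prm$fwd, prm$rev, prm$traptag)
  expect_identical(built$fwd, ps$fwd)
  expect_identical(built$rev, ps$rev)

  d <- gen1_design()
  bc <- enumerate_library(d)$sequence[10]
  s1 <- pcr_extend(bc, ps$fwd[1], ps$rev[1])
  expect_identical(s1$length, 135L)
  expect_identical(s1$fwd_extension, 33L)
  cur <- s1$sequence
  lens <- c(s1$length)
  for (s in 2:4) {
    r <- pcr_extend(cur, ps$fwd[s], ps$rev[s])
    cur <- r$sequence
    lens <- c(lens, r$length)
  }
  expect_identical(lens, c(135L, 161L, 195L, 262L))
  # primers fully contained with no extensions: product equals the span
  sub <- substr(bc, 1, 60)
  res <- pcr_extend(sub, substr(bc, 1, 18), revcomp(substr(bc, 43, 60)))
  expect_identical(res$sequence, sub)
  # ambiguous priming is an error
  tmpl <- paste0(strrep("ACGT", 10), strrep("ACGT", 10))
  expect_error(pcr_extend(tmpl, "ACGTACGTACGT", "TTTTTTTTTTTT"),
               "priming error")
})

test_that("library prep records stage lengths and wildcard substitutions", {
  d <- gen1_design()
  bc <- enumerate_library(d)$sequence[1]
  tag <- d$traptag_whitelist[3]
  prep <- simulate_library_prep(bc, tag, "ACGTACGTAC", d)
  expect_identical(prep$stage_lengths, c(135L, 161L, 195L, 262L))
  expect_identical(nchar(prep$amplicon), 262L)
  # the tag appears top-strand at the recorded span
  expect_identical(substr(prep$amplicon, prep$segments$traptag[1] + 1L,
                          prep$segments$traptag[2]), tag)
  expect_identical(substr(prep$amplicon, prep$segments$barcode[1] + 1L,
                          prep$segments$barcode[2]), bc)
  expect_error(simulate_library_prep(bc, "ACGT", "ACGTACGTAC", d),
               "8 nt")
  # two tags differ only at the UMI positions
  p2 <- simulate_library_prep(bc, d$traptag_whitelist[4], "ACGTACGTAC", d)
  a <- strsplit(prep$amplicon, "")[[1]]
  b <- strsplit(p2$amplicon, "")[[1]]
  diffs <- which(a != b)
  expect_true(all(diffs > prep$segments$traptag[1] &
                    diffs <= prep$segments$traptag[2]))
})

test_that("length conservation holds on random toy designs", {
  set.seed(31)
  for (rep in 1:5) {
    nb <- sample(2:4, 1)
    td <- toy_design(n_blocks = nb, variants = 2L, seed = 100 + rep)
    lay <- td$layout
    a <- assemble_target(td, rep(1L, nb))
    expect_identical(a$length, sum(lay$length))
    tops <- vapply(seq_len(nb),
                   function(i) nchar(td$blocks[[i]][[1]]$top_strand),
                   integer(1))
    expect_identical(sum(tops), sum(lay$length))
  }
})
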