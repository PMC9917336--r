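test_that("demultiplexing assigns exact, near and ambiguous tags correctly", {
  d <- gen1_design()
  tmpl <- make_generic_template(d, full = TRUE)
  bc <- enumerate_library(d)$sequence[1]
  tag <- d$traptag_whitelist[10]
  amp <- simulate_library_prep(bc, tag, "ACGTACGTAC", d)$amplicon
  expect_identical(demultiplex(amp, d$traptag_whitelist, tmpl), tag)
  # one mismatch in the tag: nearest-unique assignment
  amp1 <- amp
  p <- tmpl$segments$start0[match("traptag", tmpl$segments$name)] + 1L
  orig <- substr(amp1, p, p)
  substr(amp1, p, p) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  got <- demultiplex(amp1, d$traptag_whitelist, tmpl)
  expect_true(is.na(got) || got == tag)  # NA only if a tie arises
  # a tag equidistant from two whitelist entries is unassigned
  wl <- c("AAAAAAAA", "AAAAAATT")
  amp2 <- amp
  substr(amp2, p, p + 7L) <- "AAAAAAAT"
  expect_identical(demultiplex(amp2, wl, tmpl), NA_character_)
})

test_that("variable-region decoding corrects within the code distance", {
  d2 <- gen2_design()
  tmpl <- make_generic_template(d2, full = TRUE)
  bc <- enumerate_library(d2)$sequence[100]
  amp <- simulate_library_prep(bc, d2$traptag_whitelist[1], "ACGTACGTAC",
                               d2)$amplicon
  aln <- align_read(amp, tmpl)
  truth <- assign_barcode(aln, d2, tmpl)
  expect_false(is.null(truth))
  # up to 3 substitutions inside one variable region still assign
  vseg <- tmpl$segments[tmpl$segments$name == "variable_1", ]
  amp3 <- amp
  v <- d2$vset$sequences[[1]][truth[1]]
  for (q in 1:3) {
    p <- vseg$start0 + q
    substr(amp3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(amp3, p, p))[1]
  }
  aln3 <- align_read(amp3, tmpl)
  expect_identical(assign_barcode(aln3, d2, tmpl), truth)
  # a region equidistant between two variants gives no assignment
  v1 <- d2$vset$sequences[[1]][1]
  v2 <- d2$vset$sequences[[1]][2]
  diffs <- which(strsplit(v1, "")[[1]] != strsplit(v2, "")[[1]])
  mid <- v1
  for (q in diffs[seq_len(length(diffs) %/% 2)]) {
    substr(mid, q, q) <- substr(v2, q, q)
  }
  if (hamming_distance(mid, v1) == hamming_distance(mid, v2)) {
    ampm <- amp
    substr(ampm, vseg$start0 + 1L, vseg$end0) <- mid
    expect_null(assign_barcode(align_read(ampm, tmpl), d2, tmpl))
  }
})

test_that("classification follows the category precedence rules", {
  d <- gen1_design()
  tmpl <- make_generic_template(d, full = TRUE)
  bc <- enumerate_library(d)$sequence[5]
  amp <- simulate_library_prep(bc, d$traptag_whitelist[2], "ACGTACGTAC",
                               d)$amplicon
  aln <- align_read(amp, tmpl)
  cl <- classify_read(aln, assign_barcode(aln, d, tmpl), d, tmpl)
  expect_identical(cl$category, "perfect")
  # one substitution inside the barcode
  amp1 <- amp
  p <- tmpl$barcode_offset0 + 20L
  substr(amp1, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(amp1, p, p))[1]
  aln1 <- align_read(amp1, tmpl)
  cl1 <- classify_read(aln1, assign_barcode(aln1, d, tmpl), d, tmpl)
  expect_identical(cl1$category, "substitution_1nt")
  expect_identical(cl1$n_sub, 1L)
  # deletion (with a co-occurring substitution) stays a deletion variant
  amp2 <- paste0(substr(amp1, 1, p + 9L), substr(amp1, p + 15L, 262L))
  aln2 <- align_read(amp2, tmpl)
  cl2 <- classify_read(aln2, assign_barcode(aln2, d, tmpl), d, tmpl)
  expect_identical(cl2$category, "deletion_variant")
  expect_identical(cl2$n_del, 5L)
  # insertions always land in unclassified
  amp3 <- paste0(substr(amp, 1, 100), "ACGTA", substr(amp, 101, 262))
  aln3 <- align_read(amp3, tmpl)
  cl3 <- classify_read(aln3, assign_barcode(aln3, d, tmpl), d, tmpl)
  expect_identical(cl3$category, "unclassified")
})

test_that("a read of the predicted chimera classifies with the published
           deletion pattern", {
  d <- gen1_design()
  tmpl <- make_generic_template(d, full = TRUE)
  off <- find_offtarget_assemblies(d)
  amp <- simulate_library_prep(off[[1]]$product_sequence,
                               d$traptag_whitelist[1], "ACGTACGTAC",
                               d)$amplicon
  aln <- align_read(amp, tmpl)
  cl <- classify_read(aln, assign_barcode(aln, d, tmpl), d, tmpl)
  expect_identical(cl$category, "deletion_variant")
  expect_setequal(names(cl$deletion_signature),
                  c("constant_2", "constant_3", "variable_2", "variable_3"))
})

test_that("zero-error decoding is the identity on (barcode, tag)", {
  d <- gen1_design()
  pool <- library_pool(d, seed = 6)
  reads <- simulate_reads(pool, 3000, error_model(), seed = 8)
  dec <- decode_reads(reads, d)
  truth <- parse_read_truth(reads$id)
  expect_true(all(dec$category == "perfect"))
  expect_identical(dec$barcode, truth$member)
  expect_identical(dec$traptag, truth$traptag)
  rec <- recovery_report(dec)
  expect_identical(attr(rec, "unassigned"), 0L)
  expect_identical(sum(rec$count), 3000L)
})

test_that("batch decoding matches the single-read path on errored reads", {
  d <- gen1_design()
  pool <- library_pool(d, seed = 6)
  reads <- simulate_reads(pool, 400,
                          error_model(sub_rate = 2e-3, ins_rate = 5e-4,
                                      del_rate = 5e-4), seed = 13)
  dec <- decode_reads(reads, d)
  tmpl <- attr(dec, "template")
  for (i in sample(nrow(reads), 25)) {
    aln <- align_read(reads$sequence[i], tmpl)
    cl <- classify_read(aln, assign_barcode(aln, d, tmpl), d, tmpl)
    expect_identical(dec$category[i], cl$category)
    expect_identical(dec$n_sub[i], cl$n_sub)
  }
  # category partition covers every read
  expect_equal(sum(category_summary(dec)), 100)
})

test_that("deletion profiles rank spiked chimeras by their fractions", {
  d <- gen1_design()
  pool0 <- library_pool(d, seed = 9)
  off <- find_offtarget_assemblies(d)
  chim1 <- simulate_library_prep(off[[1]]$product_sequence,
                                 d$traptag_whitelist[1], "ACGTACGTAC",
                                 d)$amplicon
  # a second, distinct deletion product: drop 7 nt from a barcode
  bc <- enumerate_library(d)$sequence[40]
  short <- paste0(substr(bc, 1, 50), substr(bc, 58, 102))
  chim2 <- simulate_library_prep(short, d$traptag_whitelist[2],
                                 "ACGTACGTAC", d,
                                 min_anchor = 12L)$amplicon
  pool <- pool_spec(pool0$amplicons, pool0$traptags, pool0$abundances,
                    pool0$member_ids,
                    spike_ins = data.frame(sequence = c(chim1, chim2),
                                           fraction = c(0.02, 0.01)))
  reads <- simulate_reads(pool, 8000, error_model(sub_rate = 5e-4),
                          seed = 10)
  dec <- decode_reads(reads, d)
  prof <- deletion_profile(dec, top_n = 10)
  expect_true(nrow(prof$counts) >= 2L)
  expect_identical(prof$counts$count, sort(prof$counts$count,
                                           decreasing = TRUE))
  top_sig <- prof$counts$signature[1]
  expect_true(grepl("constant_2", top_sig) && grepl("variable_3", top_sig))
  # heatmap rows mirror the signatures
  expect_identical(rownames(prof$heatmap), prof$counts$signature)
  expect_identical(sum(prof$heatmap[1, ]), 38L)
  # no deletion reads -> empty profile
  clean <- decode_reads(simulate_reads(pool0, 50, error_model(), seed = 1),
                        d)
  expect_identical(nrow(deletion_profile(clean)$counts), 0L)
})

test_that("substitution spectra count events with correct attribution", {
  d <- gen1_design()
  pool <- library_pool(d, seed = 2)
  # error-free reads: all-zero spectrum
  clean <- decode_reads(simulate_reads(pool, 100, error_model(), seed = 1),
                        d)
  sp0 <- substitution_spectrum(clean)
  expect_true(all(sp0$per_position == 0L))
  expect_identical(sp0$denominator, 100L)
  r0 <- mean_substitution_rate(sp0)
  expect_identical(r0$mean, 0)
  expect_identical(r0$sd, 0)
  # a single hand-placed C->A substitution among 1000 reads
  tmpl <- attr(clean, "template")
  b0 <- tmpl$barcode_offset0
  bc <- enumerate_library(d)$sequence[1]
  cpos <- regexpr("C", substr(bc, 15, 40))[1] + 14L  # constant C position
  amp <- pool$amplicons[1]
  mut <- amp
  substr(mut, b0 + cpos, b0 + cpos) <- "A"
  reads <- c(rep(amp, 999), mut)
  dec <- decode_reads(reads, d)
  sp <- substitution_spectrum(dec)
  expect_identical(sum(sp$per_position), 1L)
  expect_identical(sp$per_position[cpos], 1L)
  expect_identical(sp$type_matrix["C", "A"], 1L)
  r <- mean_substitution_rate(sp)
  expect_equal(r$mean, (1 / 1000) / 102)
  # reads with indels are excluded from the denominator
  del <- paste0(substr(amp, 1, 99), substr(amp, 101, 262))
  dec2 <- decode_reads(c(rep(amp, 9), del), d)
  expect_identical(substitution_spectrum(dec2)$denominator, 9L)
  err <- tryCatch(mean_substitution_rate(
    substitution_spectrum(decode_reads(character(0), d))),
    error = identity)
  expect_true(inherits(err, "error"))
})

test_that("an Illumina-biased simulation shows the expected from/to trends", {
  d <- gen1_design()
  pool <- library_pool(d, seed = 3)
  reads <- simulate_reads(pool, 30000,
                          error_model(sub_rate = 2e-3,
                                      sub_bias = illumina_sub_bias()),
                          seed = 19)
  dec <- decode_reads(reads, d)
  sp <- substitution_spectrum(dec)
  from_tot <- rowSums(sp$type_matrix)
  to_tot <- colSums(sp$type_matrix)
  # with a GC-rich barcode and the biased model, C and G dominate the
  # from-base totals while A and T dominate the to-base totals
  expect_true(sum(from_tot[c("C", "G")]) > sum(from_tot[c("A", "T")]))
  expect_true(sum(to_tot[c("A", "T")]) > sum(to_tot[c("C", "G")]))
})

test_that("the rate estimator is unbiased across injected rates", {
  d <- gen1_design()
  pool0 <- library_pool(d, seed = 2)
  one <- pool_spec(pool0$amplicons[1], pool0$traptags[1], 1,
                   pool0$member_ids[1])
  for (rate in c(1e-4, 1e-3)) {
    est <- vapply(1:4, function(s) {
      reads <- simulate_reads(one, 20000, error_model(sub_rate = rate),
                              seed = 1000 + s)
      mean_substitution_rate(
        substitution_spectrum(decode_reads(reads, d)))$mean
    }, numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_true(abs(mean(est) - rate) <= 3 * se)
  }
})
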