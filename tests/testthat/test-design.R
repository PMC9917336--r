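test_that("code constraints enforce their invariants", {
  expect_error(code_constraints(k = 6, min_hamming = 7),
               "min_shifted_hamming <= min_hamming <= k")
  expect_error(code_constraints(k = 6, min_hamming = 3,
                                min_shifted_hamming = 4),
               "min_shifted_hamming")
  expect_error(code_constraints(k = 6, max_homopolymer_run = 1,
                                min_hamming = 3),
               "max_homopolymer_run")
  cc <- code_constraints(k = 12, min_hamming = 7, min_shifted_hamming = 5)
  expect_s3_class(cc, "code_constraints")
})

test_that("selection returns a feasible set on a tiny pool (brute force)", {
  cons <- code_constraints(k = 4, min_hamming = 3, min_shifted_hamming = 1,
                           max_homopolymer_run = 4)
  vset <- select_variable_regions(c("AAAA", "TTTT", "AAAT"), 1, 2, cons,
                                  seed = 5)
  got <- sort(unlist(vset$sequences))
  # brute force over the 3 pairs: {AAAA,TTTT} (d=4) and {AAAT,TTTT} (d=3)
  # are the feasible pairs
  expect_true(identical(got, c("AAAA", "TTTT")) ||
                identical(got, c("AAAT", "TTTT")))
  rep <- validate_variable_set(vset)
  expect_true(all(rep$status == "pass"))
})

test_that("selection refuses infeasible requests with best partial size", {
  cons <- code_constraints(k = 4, min_hamming = 3, min_shifted_hamming = 1,
                           max_homopolymer_run = 4)
  err <- tryCatch(select_variable_regions(c("AAAA"), 1, 2, cons, seed = 1),
                  error = identity)
  expect_s3_class(err, "modbarcode_search_failure")
  err2 <- tryCatch(
    select_variable_regions(c("AAAA", "AAAT", "AATA", "ATAA"), 1, 4, cons,
                            seed = 1, restarts = 5),
    error = identity)
  expect_s3_class(err2, "modbarcode_search_failure")
  expect_true(err2$best_size >= 1L)
})

test_that("selection reaches the brute-force maximum on small pools", {
  set.seed(21)
  for (rep in 1:5) {
    pool <- unique(replicate(10, rand_dna(5)))
    pool <- filter_homopolymers(pool, 3)
    cons <- code_constraints(k = 5, min_hamming = 3, min_shifted_hamming = 2)
    mx <- oracle_max_feasible(pool, 3, 2)
    if (mx < 2) next
    vset <- select_variable_regions(pool, 1, mx, cons, seed = rep)
    expect_length(unlist(vset$sequences), mx)
    expect_true(all(validate_variable_set(vset)$status == "pass"))
  }
})

test_that("selection output always validates and is seed-deterministic", {
  pool <- filter_homopolymers(enumerate_kmers(6), 3)
  cons <- code_constraints(k = 6, min_hamming = 3, min_shifted_hamming = 2)
  v1 <- select_variable_regions(pool, 4, 4, cons, seed = 42)
  v2 <- select_variable_regions(pool, 4, 4, cons, seed = 42)
  expect_identical(v1$sequences, v2$sequences)
  expect_true(all(validate_variable_set(v1)$status == "pass"))
})

test_that("a 24-sequence 12-mer set passes the strict code constraints", {
  set.seed(7)
  pool <- unique(replicate(3000, rand_dna(12)))
  pool <- filter_homopolymers(pool, 3)
  cons <- code_constraints(k = 12, min_hamming = 7, min_shifted_hamming = 5)
  vset <- select_variable_regions(pool, 3, 8, cons, seed = 1)
  expect_length(unlist(vset$sequences), 24L)
  rep <- validate_variable_set(vset)
  expect_true(all(rep$status == "pass"))
  h <- rep$value[rep$constraint == "min_hamming_global"]
  expect_true(h >= 7)
})

test_that("published variable-region sets validate as printed", {
  g2 <- fixture_variable_regions("gen2")
  rep2 <- validate_variable_set(g2)
  expect_true(all(rep2$status == "pass"))
  expect_true(rep2$value[rep2$constraint == "min_hamming_within_block"] >= 7)
  expect_true(rep2$value[rep2$constraint == "min_hamming_global"] >= 7)
  expect_true(rep2$value[rep2$constraint ==
                           "min_shifted_hamming_global"] >= 5)

  g1 <- fixture_variable_regions("gen1")
  rep1 <- validate_variable_set(g1)
  dup <- rep1[rep1$constraint == "duplicates", ]
  # duplicates allowed for the first generation: reported but passing;
  # the duplicated sequence is GCGGGC shared by blocks 1 and 3
  expect_identical(dup$status, "pass")
  expect_identical(dup$worst_pair, "b1.v2|b3.v4")
  expect_identical(g1$sequences[[1]][2], "GCGGGC")
  expect_identical(g1$sequences[[3]][4], "GCGGGC")
})

test_that("duplicate sequences fail validation when duplicates forbidden", {
  cons <- code_constraints(k = 4, min_hamming = 1, min_shifted_hamming = 1,
                           forbid_duplicates = TRUE)
  vset <- variable_region_set(list(c("ACGT", "ACGT")), cons)
  rep <- validate_variable_set(vset)
  expect_identical(rep$status[rep$constraint == "duplicates"], "fail")
  expect_equal(rep$value[rep$constraint == "min_hamming_global"], 0)
})

test_that("overhang design meets all stated constraints", {
  cons <- code_constraints(k = 6, min_hamming = 3, min_shifted_hamming = 1,
                           unique_terminal_nt = 2)
  oh <- design_overhangs(3, 10, cons, seed = 2)
  expect_length(oh, 3L)
  expect_true(all(nchar(oh) == 10L))
  expect_true(all(longest_run(oh) <= 3L))
  gc <- gc_fraction(oh)
  expect_true(all(gc >= 0.4 & gc <= 0.6))
  min_h <- ceiling(3 * 10 / 6)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_true(hamming_distance(oh[i], oh[j]) >= min_h)
    expect_false(oh[i] == oh[j])
    expect_false(oh[i] == revcomp(oh[j]))
    expect_true(cross_hybridization_score(oh[i], oh[j]) < 6L)
  }
  # distinct nick-adjacent terminal dinucleotides
  terms <- substr(oh, 9, 10)
  expect_identical(anyDuplicated(terms), 0L)
  # single overhang trivially satisfies pairwise constraints
  expect_length(design_overhangs(1, 10, cons, seed = 2), 1L)
})

test_that("overhang design fails by pigeonhole when terminals run out", {
  cons <- code_constraints(k = 6, min_hamming = 1, min_shifted_hamming = 1,
                           unique_terminal_nt = 2)
  err <- tryCatch(design_overhangs(17, 10, cons, seed = 1), error = identity)
  expect_s3_class(err, "modbarcode_search_failure")
})

test_that("primer specificity scan reports on-target and off-target sites", {
  d <- gen1_design()
  lib <- enumerate_library(d)
  fwd <- d$primers$fwd
  hits <- primer_library_specificity(fwd, lib$sequence[1:20],
                                     intended_strand = "+",
                                     intended_start = 1L)
  expect_identical(nrow(hits), 20L)
  expect_true(all(hits$on_target))
  expect_true(all(hits$mismatches == 0L))
  # no shared anchor: no hits
  none <- primer_library_specificity("ACGTACGTACGT",
                                     strrep("T", 40))
  expect_identical(nrow(none), 0L)
  # primer equal to the reverse complement of an internal segment:
  # one hit on the opposite strand
  inner <- "GATTACCAGGATCCGATTAC"
  lib1 <- paste0(rand_dna(10), inner, rand_dna(10))
  hits2 <- primer_library_specificity(revcomp(inner), lib1)
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$strand, "-")
  expect_identical(hits2$position, 11L)
})
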