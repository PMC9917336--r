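# Shipped fixtures: the printed primer and variable-region tables, plus
# deterministic reconstructions of the parts the publication record omits
# (constant pads, junction overhangs, TrapTag whitelist).

FIXTURE_SEED <- 20230129L  # fixed fixture seed; all shipped designs derive
                           # their generated constants from it

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "modbarcode")
  if (p == "") stop("missing extdata file: ", file, call. = FALSE)
  p
}

#' Shipped barcode primer table
#'
#' @param generation `"gen1"` or `"gen2"`.
#' @return list with elements `fwd`, `rev`, `traptag`.
#' @export
fixture_primers <- function(generation = c("gen1", "gen2")) {
  generation <- match.arg(generation)
  tab <- read.delim(extdata_path("barcode_primers.tsv"),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$generation == generation, ]
  setNames(as.list(tab$sequence), tab$role)
}

#' Shipped variable-region sets
#'
#' The printed per-block variant sequences: first generation, four blocks of
#' four 6-nt variants (duplicates permitted; GCGGGC is shared by blocks 1 and
#' 3); second generation, three blocks of eight 12-nt variants selected under
#' the explicit minimum Hamming distance of 7 and shifted-register minimum
#' of 5.
#'
#' @param generation `"gen1"` or `"gen2"`.
#' @return a `variable_region_set`.
#' @export
fixture_variable_regions <- function(generation = c("gen1", "gen2")) {
  generation <- match.arg(generation)
  f <- sprintf("variable_regions_%s.tsv", generation)
  tab <- read.delim(extdata_path(f), stringsAsFactors = FALSE)
  blocks <- lapply(split(tab, tab$block),
                   function(d) d$sequence[order(d$variant)])
  cons <- if (generation == "gen1") {
    code_constraints(k = 6L, min_hamming = 2L, min_shifted_hamming = 1L,
                     forbid_duplicates = FALSE)
  } else {
    code_constraints(k = 12L, min_hamming = 7L, min_shifted_hamming = 5L,
                     forbid_duplicates = TRUE, unique_terminal_nt = 2L)
  }
  variable_region_set(unname(blocks), cons,
                      provenance = sprintf("published %s table", generation))
}

#' Shipped overhang-PCR primer sets (first generation)
#'
#' The four printed nested primer pairs used to amplify the barcode, append
#' the TrapTag UMI and attach the sequencing adapters and index.
#'
#' @return data.frame with columns `set`, `fwd`, `rev`.
#' @export
fixture_primer_sets_gen1 <- function() {
  read.delim(extdata_path("overhang_pcr_primer_sets_gen1.tsv"),
             stringsAsFactors = FALSE)
}

# Junction overhangs for the fixtures. Overhang sequences were not published;
# they are designed deterministically here. The first-generation set
# reproduces the published design's flaw: the nick-adjacent terminal
# dinucleotide of junction 3 is forced equal to junction 1's, which (together
# with the duplicate GCGGGC variable region in blocks 1 and 3) enables the
# documented off-target block1->block4 ligation. The second generation
# enforces unique terminal dinucleotides.
fixture_overhangs <- function(generation) {
  if (generation == "gen1") {
    cons <- code_constraints(k = 6L, min_hamming = 3L,
                             min_shifted_hamming = 1L,
                             unique_terminal_nt = 0L)
    oh <- design_overhangs(3L, length = 10L, constraints = cons,
                           seed = FIXTURE_SEED)
    substr(oh[3], 9L, 10L) <- substr(oh[1], 9L, 10L)
    oh
  } else {
    cons <- code_constraints(k = 12L, min_hamming = 7L,
                             min_shifted_hamming = 5L,
                             unique_terminal_nt = 2L)
    design_overhangs(2L, length = 10L, constraints = cons,
                     seed = FIXTURE_SEED)
  }
}

#' Shipped first-generation library design (4 blocks x 4 variants, 102 bp)
#'
#' Printed primers and variable regions combined with deterministic
#' reconstructions of the unpublished constants (pads, overhangs, TrapTag
#' whitelist). Faithful to the published design, including the junction-1 /
#' junction-3 terminal-dinucleotide collision that drives its dominant
#' off-target deletion variant.
#'
#' @param n_tags TrapTag whitelist size.
#' @return a `library_design`.
#' @export
gen1_design <- function(n_tags = 96L) {
  primers <- fixture_primers("gen1")
  compile_blocks(gen1_layout(),
                 fixture_variable_regions("gen1"),
                 fixture_overhangs("gen1"),
                 primers,
                 traptag_whitelist = make_traptag_whitelist(n_tags,
                                                            seed = FIXTURE_SEED),
                 primer_sets = overhang_pcr_sets(primers$fwd, primers$rev,
                                                 primers$traptag),
                 seed = FIXTURE_SEED)
}

#' Shipped second-generation library design (3 blocks x 8 variants, 128 bp)
#'
#' As [gen1_design()] but with the second-generation tables and the improved
#' design constraints: no duplicate variable regions and unique nick-adjacent
#' terminal dinucleotides across junction overhangs.
#'
#' @param n_tags TrapTag whitelist size.
#' @return a `library_design`.
#' @export
gen2_design <- function(n_tags = 96L) {
  primers <- fixture_primers("gen2")
  compile_blocks(gen2_layout(),
                 fixture_variable_regions("gen2"),
                 fixture_overhangs("gen2"),
                 primers,
                 traptag_whitelist = make_traptag_whitelist(n_tags,
                                                            seed = FIXTURE_SEED),
                 primer_sets = overhang_pcr_sets(primers$fwd, primers$rev,
                                                 primers$traptag),
                 seed = FIXTURE_SEED)
}
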