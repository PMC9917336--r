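---
title: "Modular combinatorial DNA barcodes: design, in-silico assembly, simulation and decoding"
author: "modbarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular combinatorial DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modbarcode)
```

## The system

A modular DNA barcode is a short (~100-200 bp) double-stranded identifier
assembled from interchangeable duplex *blocks* joined in fixed order by
10-nt single-stranded sticky-end *overhangs*. Every block variant of a
given position shares its overhang and constant domains, so any variant can
ligate into any assembly; the identity of a barcode is the tuple of block
variants, read out from the block-internal *variable regions*. With $B$
blocks of $V$ variants each, $2BV$ synthetic oligos yield $V^B$ distinct
barcodes: the shipped first-generation design (4 blocks x 4 variants,
102 bp) gives 256 barcodes from 32 oligos, and the second generation
(3 blocks x 8 variants, 128 bp) gives 512 from 48.

Detection is by PCR amplification with a primer pair common to all library
members, attachment of an 8-nt unique molecular identifier (the *TrapTag*,
encoding the recovery site/time of a sample) and sequencing adapters by
four nested overhang-PCR stages, and amplicon sequencing. The package
covers the full dry-lab loop: code design, in-silico assembly, prediction
of off-target (deletion-variant) assemblies, read simulation, and decoding.

## Code design

Variable regions form an error-tolerant code. Candidates are enumerated
(`enumerate_kmers()`), filtered against homopolymer runs of four or more
(`filter_homopolymers()`; of the $4^6 = 4096$ 6-mers, 3936 survive), and a
set is selected so that every pair keeps

* Hamming distance $\ge d_{\min}$ (7 for the 12-nt second-generation code,
  correcting up to 3 substitutions per region), and
* *shifted-register* Hamming distance $\ge d_{\text{shift}}$ (5), the
  minimum mismatch count over the two one-position offsets of the pair,
  which protects identifiability when a single indel shifts the reading
  register.

Selection (`select_variable_regions()`) is greedy accretion over a seeded
random candidate order with restarts (default 100). The field's usual
alternative, clique search, is exact but does not scale to $4^{12}$
candidates; greedy accretion with restarts finds 24-sequence sets under
the strict constraints reliably, and on pools small enough for brute force
it attains the maximum feasible set size (property-tested). Tie-breaks are
lexicographic; all randomness flows from one explicit seed.

`validate_variable_set()` re-measures a set from scratch (duplicates,
homopolymer runs, within-block and global pairwise minima, shifted-register
minimum). On the printed second-generation set the within-block and global
minima are 7 and the shifted minimum is 5. On the printed first-generation
set the measured global minimum is **2** (the block-3 pair GCGGAA/GCGGGC),
not the nominal 3 recorded alongside it; the fixture therefore records
`min_hamming = 2`, and the validator always reports both within-block and
global minima rather than assuming a nominal value.

Junction overhangs (`design_overhangs()`) are found by seeded random search
under: the homopolymer limit; GC fraction within 0.4-0.6 (a plain
composition proxy for comparable duplex stability, since the package does
not model thermodynamics); pairwise Hamming distance at least
$\lceil d_{\min} \cdot L_{oh} / k \rceil$ (the variable-region rule rescaled
to overhang length); no overhang equal to, or the reverse complement of,
another; a heuristic cross-hybridization screen; and distinct nick-adjacent
terminal bases (below). `cross_hybridization_score()` is the longest
contiguous Watson-Crick complementary stretch between one sequence and the
reverse of the other - a deliberate, fast stand-in for equilibrium
hybridization prediction, with a rejection threshold of 6 complementary
bases and a hook for plugging in an external thermodynamic scorer.

## Assembly geometry and the off-target mechanism

Coordinates are 0-based half-open on the top strand. At junction $i$ the
top strand is nicked at the overhang's start and the bottom strand at its
end, so each block presents a 10-nt 5' overhang on its bottom strand at its
right side and on its top strand at its left side. Ligation requires a 5'
phosphate on both nick-flanking strands; `compile_blocks()` flags the top
strands of blocks $2..B$ and bottom strands of blocks $1..B-1$ (24 of the
32 first-generation oligos). The layout places each variable region
immediately adjacent to its block's right-hand nick, and groups each
junction overhang with the following block's constant pad into a display
"constant region" for deletion reporting.

During annealing, a free bottom strand presents more than its overhang: the
nick-adjacent window of the block is single-stranded until its partner
arrives. `find_offtarget_assemblies()` models chimera formation on exactly
this interface: block $(i,u)$ can recruit the left overhang of a
non-designed partner at position $j$ when the 16-nt top-strand window
ending at its bottom-strand nick imitates the corresponding window of some
variant of block $j-1$, matching in at least `min_junction_match` (4)
positions with the `require_nick_match` (2) positions nearest the nick
matching exactly - the ligase cannot seal an unpaired nick, and one sealed
strand suffices for PCR propagation. The defaults mirror the observed
failure mode: two identical nick-adjacent terminal nucleotides plus a
shared 6-nt variable region give a window score of 8.

Candidate products are simple source-to-sink paths in the resulting
junction graph (igraph), capped by default at the design's block count;
longer insertion-bearing scrambles can be chased by raising
`max_path_blocks`, but deletion variants are the species of interest.
Designed paths are dropped; the rest are reported with per-segment deleted
nucleotide attribution (from the skipped top-strand spans) and sorted by
junction score. On the first-generation fixture the top prediction is the
block1-to-block4 chimera carried by the duplicated GCGGGC variable region,
deleting constant regions 2-3 and variable regions 2-3 (38 nt); on the
second-generation fixture - no duplicate variable regions, unique terminal
dinucleotides - the prediction is empty. This motivates the
`unique_terminal_nt` code constraint.

The shipped fixtures reproduce the printed primers, variable regions and
overhang-PCR primer sets verbatim; the constant pads, junction overhangs
and TrapTag whitelist are not part of the publication record and are
generated deterministically from a fixed fixture seed (the whitelist is a
synthetic stand-in: 96 8-mers at pairwise distance >= 3). The
first-generation fixture deliberately forces junction 3's terminal
dinucleotide equal to junction 1's, reproducing the design flaw that the
second generation corrects.

## Library preparation arithmetic

`pcr_extend()` models one overhang-PCR stage: the primer's 3'-terminal 12
bases must match the template uniquely and exactly (template wildcards
never template a primer), the annealed span extends 5'-ward while bases
match, and the product is the full forward primer, the inter-primer span,
and the reverse complement of the full reverse primer. Applied in order,
the four shipped primer sets take a 102-bp barcode through 135, 161, 195
and 262 bp, instantiating the TrapTag (8 nt) and sample index (10 nt)
wildcards on the way. Tags and indices are specified in top-strand
orientation as they appear on the final amplicon; the reverse-primer
wildcards therefore receive their reverse complements.

## Read simulation

`simulate_reads()` models joined, adapter-trimmed single-end amplicon
reads: each read is a copy of a pool member's full amplicon drawn
proportionally to abundance, with independent per-base substitution,
insertion and deletion events (indels first, at most one indel event per
position; substitution targets drawn from a row-stochastic 4x4 matrix,
uniform by default, with an Illumina-like preset elevating C-to-A, C-to-T
and G-to-T). Abundances emulate the wide per-member spread of a pool mixed
from imprecisely quantified stocks: log-uniform over three decades
(10^3-10^6) by default. Quality strings are a cosmetic constant Q37 - the
decoder is alignment-based, not quality-aware. Read ids carry the ground
truth (member, tag, applied error counts) so every downstream claim is
checkable. What the generator does *not* emulate: PCR jackpot errors and
cycle-correlated substitutions (the real data's T108G hotspot is of that
kind), sequencer-specific learned error profiles, chimera formation during
amplification (off-target products enter only as explicit spike-ins), and
paired-end joining artifacts. Passing tests therefore demonstrate
correctness of the decoding machinery under the stated error model, not
performance on any particular instrument's data.

## Decoding

Reads are aligned globally to the full-amplicon template carrying `N` at
every variable, TrapTag and index position (`make_generic_template()`).
The aligner (C++, Gotoh three-state recursion) uses unit edit costs with
`N` matching free, plus an infinitesimal gap-opening surcharge so that
among minimum-edit alignments the one with fewest gap runs wins - this is
also what makes a lone substitution beat an equal-cost indel pair.
Remaining ties place gap runs at their *rightmost* equivalent position: a
chimeric deletion's left edge abuts a variable region, so leftmost
placement would let the run slide through zero-cost wildcard columns and
misattribute the deleted segments, while rightward sliding is blocked by
the orthogonal overhang sequences, pinning the run at the ligatable nick
where it arose. Reads whose length equals the template's and whose
non-wildcard mismatch count is at most 2 take a vectorized
substitutions-only fast path (provably minimum-cost there, since any
indel-bearing alignment costs at least 2 and ties prefer substitutions).

Downstream of alignment: the TrapTag is read off the tag window and
assigned to the unique whitelist tag within one mismatch (ties and
distances beyond the threshold yield no assignment); each variable region
is assigned to the variant with the unique minimum Hamming distance, at
most `floor(min_hamming / 2)` (1 for the first generation's distance-2
code, 3 for the second generation's distance-7 code) - a deletion
overlapping a variable region blocks assignment. Classification follows a
strict precedence over the barcode span: any insertion makes a read
*unclassified*; otherwise any deletion makes it a *deletion variant*
(regardless of co-occurring substitutions); otherwise zero substitutions
with a full assignment is *perfect*, exactly one substitution is a *1-nt
substitution variant*, and the rest are unclassified. The four categories
partition every read. Edits outside the barcode span (adapters, tag,
index) do not affect the category; whether substitution-only reads inside
variable regions should count against "perfect" is genuinely ambiguous in
the source record, and the rule here - they do, measured against the
assigned variant - is one consistent reading, stated so results are
interpretable.

The substitution spectrum is computed over full-length reads containing no
indels anywhere: per-position counts (from-base taken from the template at
constant positions and from the assigned variant inside variable regions)
and a 4x4 from-by-to matrix. The mean per-nucleotide substitution rate is
the mean over barcode positions of count/denominator, reported with its
positional standard deviation - the estimator used on the real data, which
recovers an injected rate of 5e-4 as 0.05% in simulation.

## Problem sizes and study conditions

The package's own checks run at these sizes, chosen to match the study's
stated conditions while staying desk-scale:

* estimator recovery: 200,000 reads per seed at substitution rate 5e-4,
  3 seeds in the test suite (10 in the acceptance script), agreement
  within 3 standard errors across seeds;
* multiplex recovery: the full 256-member pool, log-uniform abundances
  over (10^3, 10^6). At exactly 100,000 reads the rarest member's expected
  coverage is ~2.7 reads, so complete recovery is a coin flip by design
  (Poisson miss probability ~7% for the rarest member); the package test
  therefore uses 200,000 reads (minimum expected coverage ~5.4, overall
  miss probability ~1%), a size fixed from that calculation;
* alignment oracle equivalence: exhaustive comparison against a plain
  dynamic-programming edit distance on reads up to 30 nt, plus an
  independent aligner route (Biostrings) on random pairs;
* off-target enumeration: exhaustive ordering oracle on designs up to
  4 blocks x 2 variants.

## Known limitations

* The off-target model scores single-stranded interface windows by base
  identity; it does not rank products by thermodynamic stability or
  concentration, and cannot see mechanisms that require strand
  displacement through annealed duplex.
* The decoder assumes joined, adapter-bearing amplicon copies; paired-end
  merging, quality-aware calling and UMI-family consensus are out of
  scope.
* Deletion attribution is exact only up to alignment equivalence: a
  deletion whose flanks are repeated in the template is reported at its
  rightmost equivalent placement by convention.
* Real-data category fractions (e.g. the published 80/3/5 and 26/1/3
  percentage splits) depend on instrument- and run-specific artifacts the
  simulator does not model, and are not reproduced here.
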