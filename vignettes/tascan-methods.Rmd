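---
title: "tascan: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tascan: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tascan)
```

## The problem

Chromosomal type I toxin–antitoxin (TA) loci encode a small hydrophobic
toxin and an sRNA antitoxin that represses toxin translation by antisense
base pairing. Pan-genome surveys of such loci ask, per assembly: is the
locus present, intact, interrupted, or reduced to an orphan antitoxin;
how many copies exist (including plasmid-borne ones); which regulatory
elements are conserved; can the antitoxin still silence its cognate
toxin; and does copy number co-vary with strain metadata. tascan
implements that whole chain as testable code, with a synthetic pan-genome
generator standing in for assembly downloads.

## Coordinates

All intervals are **1-based inclusive**, the Bioconductor
(IRanges/Biostrings) convention, both internally and in the outfmt-6
style hit table (where minus-strand hits have `sstart > send`, as in
BLAST). This is a deliberate deviation from a 0-based half-open design:
in R the 1-based convention removes a permanent conversion layer against
every library the package touches.

## The aligner

`seed_extend_search()` follows the classical BLASTn architecture:

1. **Seeding.** Exact `word_size`-mer matches (default 11) on both
   strands, found by hashing; residues outside A/C/G/T never seed and
   mismatch everything.
2. **Diagonal clustering.** Seeds within 40 diagonals and 200 nt of each
   other along the subject form a candidate region. A locus split by an
   insertion produces clusters on distant diagonals, which is what later
   lets the classifier see the interruption.
3. **Extension.** An ungapped X-drop extension (X = 20 raw points)
   delimits the high-scoring region, then a banded affine-gap
   Smith–Waterman (band half-width 40) with traceback produces the final
   alignment. Overlapping hits on the same subject and strand keep only
   the higher-scoring one.
4. **Statistics.** Raw scores are normalized with the Karlin–Altschul
   parameters: `bits = (λS − ln K)/ln 2`, `E = m·n·2^(−bits)` with the
   raw `m·n` search space (no finite-size correction — a documented,
   deliberate divergence from NCBI's edge-effect adjustment; at the
   scales involved it changes E-values by a constant factor that the
   permissive E ≤ 10 cutoff absorbs). λ is the unique positive root of
   `Σ pᵢpⱼ e^{λ s(i,j)} = 1` (solved by `uniroot` to 1e−12); `K` is a
   user-set constant, 0.41 by default for the +2/−3 scheme.

Defaults mirror the `blastn` task: reward +2, penalty −3, gap open 5, gap
extend 2, word size 11, E-value cutoff 10, at most 10,000 subjects.

Parity is claimed against the package's own exhaustive oracle, not
against the NCBI binary: `smith_waterman()` is a full
dynamic-programming local aligner (ties broken by smallest end in the
subject, then the query), and the test suite checks both that the search
reproduces its scores on hundreds of planted-segment pairs and that the
oracle itself matches `Biostrings::pairwiseAlignment()` — two
independent implementations guarding each other.

## Locus calling

Hits of one query on the same subject and strand within `max_gap` =
2,000 nt form one **coverage profile** (tandem loci stay distinct because
the simulator — and real tandem systems — space copies further apart).
Two robustness rules matter at genome scale and were added after watching
11-nt chance matches (raw score 22, E ≈ 4, i.e. *below* the permissive
E ≤ 10 cutoff) corrupt profiles:

* alignments shorter than 20 nt cluster only among themselves, so a
  chance word match can neither bridge two loci into one cluster nor
  inject a bogus coverage segment into a real one;
* query segments are merged only when they overlap by ≥ 30 nt: the
  abutting halves of an interrupted locus typically overlap by a few
  chance-extension nucleotides at the breakpoint and must not fuse.

`filter_spurious()` then drops (i) profiles confined to the query's 3′
terminator region spanning < 60 nt — the analogue of the short
antitoxin-3′-end matches a manual survey discards — and (ii)
opposite-strand profiles nested inside an already-counted cluster, which
arise from near-palindromic antitoxin/target complementarity (the
query's own antitoxin 3′ half is the reverse complement of its UTR
target, so every planted locus also produces a short opposite-strand
self-match).

Classification (`classify_locus()`):

| category | rule | copy units |
|---|---|---|
| full | one alignment (or one collinear segment) covering ≥ 95% of the query | 1.0 |
| interrupted | ≥ 2 segments jointly ≥ 95% with a subject insertion ≥ 100 nt or query deletion ≥ 50 nt | 1.0 |
| antitoxin_only | coverage confined to the antitoxin gene ± 10 nt plus ≤ 30 nt of the toxin UTR, ≥ 80% of the antitoxin covered, no ORF/pairing-region coverage | 0.5 |
| toxin_only | the symmetric case | 0.5 |
| partial | anything else | 0 (reported separately) |

The 95% full-coverage threshold, the 100/50-nt interruption rule, the
80% orphan-coverage floor and the 10-nt boundary slack operationalize
judgements a manual curation makes implicitly; all are exposed as
arguments. The ≤ 30 nt UTR allowance reflects the observed 27–29-nt UTR
remnant of antitoxin-only loci (simulator default 28, the midpoint);
crucially the UTR remnant does **not** reach the pairing region, which
sits deep in the UTR — the orphan antitoxin has nothing left to silence.

Locus typing uses bit-score cutoffs: a full locus takes the type of the
typing query scoring > 650 (highest score wins; ties break O > P > Q, the
order of the thresholds vector); antitoxin-only loci are tested against
the type-O antitoxin query at 280, then type-P at 250. Threshold names
are bare type letters (`full`, `O`, `P`) rather than query sequence
names, since the cutoffs attach to types, not to any particular query.

Duplicate strain names keep one representative per distinct copy-number
vector (first assembly id lexicographically) — so three same-named
assemblies with copies 0.5/0.5/2 keep exactly one 0.5 and one 2.

## Conservation

`map_element()` walks alignment columns and returns the subject residues
aligned to a query interval (in query orientation), so element
observations are comparable across strands. Elements observed with
indels count as non-matching (the reference tables report exact
hexamers, so a conservative identity test is the right default).
Denominators count loci whose hit fully covers the element; partially
covered loci are excluded and their count reported. Percentages are per
locus, not per assembly (a flaggable choice; multi-copy assemblies
contribute once per copy).

`build_consensus()` reports per-column counts, the modal consensus
(nucleotide ties become IUPAC ambiguity codes, protein ties `X`) and
information content `Rᵢ = log2(|alphabet|) − Hᵢ` with the entropy over
non-gap symbols. Columns with > 50% gaps are masked. The small-sample
correction `(|alphabet|−1)/(2 ln 2 · n)` is off by default — the output
is the count matrix itself, so any logo renderer can apply its own
correction. `translate_orf()` uses an internally constructed standard
genetic code (tests cross-check it against Biostrings), trims trailing
partial codons, flags internal stops as truncated, and truncated ORFs
never enter the protein variant tables.

## Pairing rule

`best_duplex()` slides the reverse-complemented antitoxin along the
toxin region at every offset — gapless, because the sufficiency rule is
phrased in nucleotide counts, not thermodynamics — and reports the
longest contiguous complementary run plus the longest window with at
most one internal mismatch ("internal" meaning not at either end: a
terminal mismatch just shortens the window). `is_repressive()` applies
the experimentally derived thresholds: ≥ 15 nt contiguous, or ≥ 17 nt
with one internal mismatch. Only Watson–Crick pairs count by default;
G:U wobble is available behind a flag but off, since the sufficiency
rule was established without it.

## Monte Carlo statistics

`mc_anova()` compares the classic one-way F to its distribution under
label shuffles preserving group sizes (the survey design: heavily
unbalanced groups with unequal variances, where the F reference
distribution is unreliable). P-values use the add-one rule
`(1 + #{null ≥ obs})/(1 + B)` and are never zero. The name "Monte Carlo
Tukey" does not by itself pin down a statistic; `mc_tukey()` interprets
it as the standard Tukey logic under permutation: observed
`qᵢⱼ = |x̄ᵢ − x̄ⱼ| / √(MSW·(1/nᵢ + 1/nⱼ)/2)` against the null of the
**maximum** q over pairs, giving family-wise control.
`exhaustive_permutation_p()` enumerates all size-preserving assignments
(≤ 10⁶) and returns the exact `#{stat ≥ obs}/total`; since the identity
assignment is included the exact p is also never zero, and the Monte
Carlo estimates converge to it (verified on the 1,680-assignment 3×3
case). Assemblies with unknown group labels are excluded before testing,
as with incomplete BioSample metadata.

Defaults are 10⁴ iterations. The type-I
calibration test uses 499 shuffles per replicate instead: under the
add-one rule the rejection event `p ≤ 0.05` then has probability exactly
25/500 = 0.05 under the null (no discreteness bias), and 500 replicates
fit comfortably in the test-time budget.

## The synthetic world

`simulate_pangenome()` emulates a pan-genome at desk scale: 20-kb
chromosomes and 6-kb plasmids (real enteric genomes are ~5 Mb; length
only scales search time, not the logic under test), background GC 0.5 (a
free choice — the real intergenic composition is not specified
anywhere), planted loci spaced > 2 kb so distinct copies never share a
hit cluster, per-assembly RNG streams derived as `seed + index` so
outputs are reproducible and order-independent. The default category mix
mirrors the observed zor/orz-like spectrum (3% absent, 25% one full, 42%
two full, 27% antitoxin-only, plus rare 3-copy, 1.5-copy, interrupted
and plasmid-borne shapes). Mutation noise is i.i.d. substitution only
(no indels), and annotated elements are protected unless a flag lifts
that — protection keeps alignment recovery interpretable and lets
conservation tests distinguish "element conserved" from "aligner found
it". An optional metadata effect adds full copies to one pathotype group
to create a recoverable signal. `shapes` can fix the per-assembly
category allocation deterministically (used by the acceptance fixture so
every category is guaranteed present at n = 50).

The built-in `example_template()` is a **synthetic stand-in**, not a real
MG1655/EDL933 sequence (the real query sequences are not redistributed
here): a 520-nt locus with antitoxin sRNA (1–160), intergenic toxin
promoter + LexA box, 180-nt toxin 5′ UTR containing the EAP whose central
36 nt are perfectly antisense to the antitoxin 3′ half, RSS, RBS, and a
90-nt ORF encoding a 29-aa toxin. Its architecture — not its residues —
is what the pipeline exercises.

What a green round-trip test establishes: the detection, classification,
copy-number, conservation, pairing and statistics machinery is
self-consistent against planted truth under substitution noise. What it
does not establish: recovery of any published survey percentage, which
depends on thousands of real assemblies; robustness to indel-rich
divergence, rearrangements, or contamination; or NCBI-BLAST numerical
parity.

## Numerical and degenerate-input choices

* Equal-scoring local alignments: smallest end in subject, then query.
* Equal-scoring HSPs in a cluster: smallest subject start wins (the
  sort order of the hit table).
* `karlin_lambda` requires a negative expected score and fails loudly
  otherwise; `f_statistic` fails loudly on zero within-group variance.
* Lowercase input is uppercased; non-ACGT residues mismatch everything,
  never seed, and translate to `X` within codons (via `N`).
* Variant labels: substitutions joined with `+` (`N2S`, `T3S+A20S`);
  the unchanged protein is `reference`.
* Empty inputs (no observations, no sequences, empty query, empty
  genomes directory) raise errors naming the offending input.

## Limitations

The aligner is a desk-scale reimplementation: no two-hit seeding, no
finite-size E-value correction, no translated searches, and it is not
tuned for megabase subjects beyond what the tests exercise. The pairing
scan is gapless by design. The Tukey procedure is one defensible
interpretation of an under-specified method. The simulator plants loci
on a uniform background without gene content, recombination or
phylogeny.
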