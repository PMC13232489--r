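---
title: "Designing endogenous-tagging reagents and surveying tagged alleles with celtag"
author: "celtag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing endogenous-tagging reagents and surveying tagged alleles with celtag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celtag)
```

# Scope and model

`celtag` automates the design of CRISPR knock-in reagents for endogenous
protein tagging in *C. elegans* and the statistics used to survey the
community's tagged-allele inventory. This vignette is the package's own
account of the underlying procedures: the assumptions they make, the
parameters that matter, the numerical conventions, and what the synthetic
test bed does and does not demonstrate.

## Coordinates

All internal coordinates are 0-based and half-open on the plus strand;
insertion points are *inter-base* (the integer k denotes the boundary
between plus-strand bases k−1 and k). User-facing output is 1-based
inclusive, and GFF3 input (1-based) is converted at the parser boundary.
This single convention eliminates the usual off-by-one ambiguities between
"position of a cut" and "position of a base". CDS segments are taken to
include the stop codon, so a CDS of 3(L+1) nt encodes L residues; the
C-terminal "before the stop" boundary is then simply the boundary after
residue L. Alongside the inter-base point, every insertion spec reports the
1-based position of the nucleotide immediately 5′ of the boundary in
transcript orientation, the convention used when communicating insertion
coordinates to bench scientists.

When a codon boundary coincides with an exon–intron junction, the insertion
point is placed at the exon side adjacent in transcript orientation (just
after the last exonic base of the upstream codon) and flagged. Insertions
must be exonic to end up in the mature mRNA; placement inside an intron
would be spliced out.

## Mature-protein boundaries

"N-terminal tagging" rarely means "immediately after the initiator Met": a
tag inserted upstream of a cleaved signal peptide is removed with it. The
mature start is therefore the maximum over all annotated N-terminal
processing events — residue 2 when the initiator Met is removed, one past a
signal or transit peptide, one past every N-terminal propeptide reachable
by chaining, and the annotated chain start. Symmetrically, the mature end is
the minimum of the protein length, the chain end, and one before any
C-terminal propeptide. Terminal lipidation sites push the boundary so that
exactly five native residues remain between the insertion point and the
lipidated residue (first mature residue = site + 6 at the N-terminus, last
retained residue = site − 6 at the C-terminus). The "five residues between"
arithmetic is a fixed, documented convention: the source annotations state
the distance but not the endpoint handling, and one convention has to be
chosen and applied uniformly.

Sorting-motif scans (PTS1, PTS2, KDEL, di-lysine, CAAX) are warning-only
and never move coordinates; the patterns are the canonical textbook
regexes, fixed here because "simple motif searches" admits many variants:
PTS1 `[SAC][KRH][LM]$`, PTS2 `[RK][LVIQ]..[LVIHQ][SGAK]` within residues
1–40, KDEL `[KHRQ][DE]EL$`, di-lysine K at −3 with K at −4 or −5, CAAX
`C[aliphatic][aliphatic]X$`. A protein with no processing annotations at
all gets its N-terminal boundary before residue 1 and a
`NO_PROCESSING_INFO` flag, making the degenerate default visible rather
than silent.

## Guide selection

Around each insertion point the pipeline extracts ±50 bp (truncated and
flagged at contig ends) plus one base of context on each side, and
enumerates every placement of a 20-nt protospacer followed by an NGG PAM on
either strand; minus-strand sites appear as CCN + 20-mer on the plus strand
and are reported in protospacer sense. Filters follow fixed rules: GC
content of the protospacer (PAM excluded) must lie in [25, 80] percent with
*inclusive* bounds; any single-base run of 7 or more rejects the guide; a
GGG PAM, or any PAM whose next non-guide base is G, is rejected (such
NGG+G/GGG contexts behave poorly); a TTTT run demotes the guide to "in
vitro transcription only" because it terminates RNA-polymerase-III-driven
in vivo expression but is harmless to in vitro synthesis. Homopolymer and
poly-T checks apply to the protospacer in its own sense — that is the
sequence the sgRNA actually contains. Windows containing N disqualify
overlapping guides (conservative).

The blunt cut sits between protospacer positions 17 and 18, 3 bp 5′ of the
PAM. Guides are ranked by off-target count, then by cut-to-insertion
distance, then — purely to make the output deterministic — plus strand
before minus and smaller genomic start. The best in-vivo-class guide is
selected; an in-vitro-only guide is additionally reported iff its cut is
strictly closer to the insertion point.

Off-target counting is an internal, exactly specified stand-in for external
seed-and-extend tools: the genome is indexed for every NGG-adjacent 20-mer
on both strands, and a guide's count is the number of indexed sites within
Hamming (ungapped) distance ≤ 3 of its protospacer, excluding the on-target
location. Three mismatches with an NGG-only PAM is a standard screening
default; it is a configurable parameter, not a claim about any particular
external tool's settings. Bulged (gapped) off-targets and activity scores
are out of scope. The scan is implemented over 2-bit-packed 20-mers with a
popcount distance, so genome-scale counting stays interactive; the packed
path is verified against a naive position-by-position scan in the tests.

## Primer design

Primers 2 and 3 anchor the two homology arms at the junction, each covering
the 30–35 nt immediately adjacent and pointing away from it (P2 is the
left arm's reverse primer, P3 the right arm's forward primer, in transcript
orientation). Four to five silent mutations — counted as mutated
*nucleotides*, target 4, allow 5 — are placed over the guide's PAM GG bases
and 8 PAM-proximal (seed) protospacer bases, preferring codon replacements
that maximize changed bases inside that footprint; footprint bases outside
the CDS are mutated freely by transversion. Two guards apply: no mutation
within 3 nt of an exonic splice boundary or 6 nt on the intron side
(splicing must not be disturbed), and each anchored primer must retain 15
unmodified 3′-terminal bases (a mismatched primer 3′ end kills extension).
Because the anchored primers point away from the junction, the 15-base rule
binds exactly when mutations sit *far* from the junction — more than
35 − 15 = 20 nt — and in that case the design splits: the inner B primer
stays anchored with whatever mutations fit its allowance, and an auxiliary
A primer carries the mutation block with a 20-nt overlap to B, the standard
overlap-extension geometry. When the footprint offers fewer than four
mutable bases (Met/Trp codons have no synonyms) the plan is emitted with an
`INSUFFICIENT_SILENT_MUTATIONS` warning rather than failing. A plan is
considered to immunize the repaired allele when it disrupts a PAM G or
changes ≥3 seed bases; the tests verify the guide no longer matches the
edited junction at zero mismatches under those conditions.

Outer primers 1 and 4 (18–27 nt, GC 30–70 %) are placed so each homology
arm amplicon falls in 500–1000 bp, scored by melting-temperature distance
to their anchored partner (must be within 3 °C), tie-broken toward the
500-bp target then leftmost, and checked for genome-wide uniqueness by
exact full-length occurrence counting on both strands (a primer is
"specific" iff it occurs exactly once). If no candidate qualifies, the
allowable arm grows in 500-nt steps to at most 10 kb before the
best-scoring candidate is returned with a warning. Genotyping primers are
chosen the same way within a 500-nt margin outside the arms, so their
amplicon strictly contains both arm amplicons and supports a nested
two-step PCR.

Melting temperatures use the unified nearest-neighbor thermodynamic
parameters with fixed conditions: 50 mM monovalent salt, 250 nM total
oligo, and the entropic salt correction 0.368·(N−1)·ln[Na⁺]. The absolute
values depend on these conventions (they match a widely used reference
implementation to within 0.01 °C in the tests); what the design actually
relies on is Tm *matching*, which is insensitive to the shared constants.
The 3 °C tolerance, the 60 °C genotyping target, the 18–27-nt length
bounds and the 500-nt expansion step are documented defaults where the
procedure needed a number.

## Survey statistics

Inventory curation keeps one representative allele per (gene, tag set,
position set), choosing the earliest publication year and breaking ties by
allele designation; deduplication is idempotent. Literature and repository
records merge on allele designation where present, falling back to the
(gene, tags, positions) key; designation conflicts resolve in favor of the
literature with a warning. Summary distributions are percentages with one
decimal, rounded half *away from zero* — the convention that reproduces
every anchored printed value; an allele tagged at more than one position
counts once under "multiple".

Enrichment uses, for a category with t tagged genes of n against a
background of T tagged among N, the table [[t, n−t], [T−t, (N−n)−(T−t)]].
The odds ratio is the sample (cross-product) ratio; log₂(OR) is reported
with ±7 substituted for ±∞ (fully tagged or fully untagged categories) so
extreme categories stay plottable; finite values are clamped to the same
interval for scale consistency, which at survey sizes never binds. The
two-sided Fisher p sums hypergeometric probabilities no larger than the
observed table's (with the customary 1 + 10⁻⁷ tolerance), and q values are
Benjamini–Hochberg with a 0.05 significance flag. Zero cells get no
continuity correction — capping handles them. Two stated backgrounds are
supported by passing the appropriate (T, N): genes with at least one
category annotation for GO-style enrichment, all protein-coding genes for
disease-style enrichment.

Accrual is modeled two ways: ordinary least squares on cumulative unique
tagged genes per year (a gene counts once, in its earliest year), fitted
over the steady-state years; and an exponential-saturation discovery curve
G(n) = G_max(1 − e^{−n/τ}) over cumulative newly found genes versus papers
screened, fitted by Levenberg–Marquardt least squares with starts G_max =
1.05·max(G) and τ at the 63.2 % quantile. Its closed-form quantile
papers_for_fraction(f) = −τ·ln(1−f) answers "how many papers must be read
for f coverage".

# The synthetic test bed

The fixture generator builds AT-rich (36 % GC) genomes of compact genes —
1–5 exons, introns of 48–200 nt with GT..AG ends, 80–300-residue proteins,
both strands, 1.5–2.5-kb intergenic spacing — and plants maturation
features (initiator-Met removal 30 %, signal peptides 25 %, transit
peptides 5 %, N/C propeptides 10 % each, chains 15 %, terminal lipidation
5 % each). Crucially, it computes the expected boundary residues and
genomic insertion coordinates *during generation*, from its own layout
bookkeeping, before the pipeline ever parses the files; the tests then
require exact agreement for 1,000 genes. Inventory fixtures compose the
survey's study conditions exactly (1,554 genes, 2,812 alleles;
63.1/19.7/8.3/8.9 % genes with 1/2/3/4+ alleles; 62.9/33.7/2.9/0.5 %
C/N/internal/multiple placements; a yearly accrual ramp reaching a steady
203 new genes per year from 2020 with a jitter of 5; a discovery curve
with G_max = 1713 and τ = 1052.7, the values implied by ~90 % coverage at
~2,424 papers, with Gaussian noise at 2 % of G_max), using
largest-remainder allocation so the planted proportions are exact.

What passing on this bed shows: the coordinate arithmetic, filters, counts
and statistics implement their stated contracts exactly, at genome scale,
on both strands, across feature combinations. What it does not show:
performance on real *C. elegans* sequence (repeats, operons, isoform
complexity, biased codon usage), the biological validity of any particular
guide or primer, or agreement with external off-target/primer tools whose
exact parameters are unspecified. Problem sizes in the suite — 1,000-gene
sweeps, 100-kb off-target oracles, 500-window enumeration checks — were
chosen as the smallest scales at which strand, junction and boundary edge
cases all occur many times.

# Numerical choices and degenerate inputs

* Ties in guide ranking, outer-primer scoring and deduplication all have
  documented deterministic tie-breaks; identical inputs give byte-identical
  outputs.
* Windows shorter than 23 nt after truncation, genes with no NGG candidate,
  categories with zero tagged genes, empty inventories and failed curve
  fits all produce flagged results, never errors; per-gene failures in a
  batch are logged and the batch continues.
* CDS defects (length not divisible by 3, missing ATG or stop, inconsistent
  phase) are per-gene warnings carried on the transcript model — how such
  genes were handled upstream is unknowable from the annotations, so the
  package warns and proceeds.
* `roundHalfAway` adds a half-ulp guard before truncating so that decimal
  halves represented just below their true value still round away from
  zero.

# Limitations

Only the single canonical transcript per gene is designed against; isoform
enumeration, non-NGG nucleases, gapped off-target search, activity scoring,
repair-template assembly and hairpin/dimer thermodynamics are out of scope.
The off-target default (3 mismatches, NGG-only) is a screening convention,
not a validated sensitivity claim. Survey semantic clustering of categories
(term-similarity reduction) is likewise out of scope: enrichment operates
on whatever category table it is given.
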