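---
title: "Methods: mitogenome accounting, codon usage, control-region dissection and the tree stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepmito)
```

## The problem

Descriptive mitogenomics of insects rests on a small set of computations
over an annotated circular genome: sizes and composition by gene class,
signed gaps between adjacent genes, codon-usage statistics over the 13
protein-coding genes (PCGs), the structure of the A+T-rich control
region, and a concatenated-gene phylogeny. Published papers report these
as tables whose numbers are rarely recomputable because the arithmetic
conventions are left implicit. This package fixes the conventions,
implements each computation, and tests everything against a synthetic
generator whose planted structure is known exactly.

The worked system is the pair of Apaturinae mitogenomes *Hestina
persimilis* (15,252 bp) and *Hestinalis nama* (15,208 bp), whose
annotation tables ship in `extdata` as TSV transcriptions of the
GenBank records MT110153/MT110154.

## Coordinates, strands and validation

All coordinates are 1-based inclusive on the forward (majority / J)
strand, the convention of both GenBank and published annotation tables.
Reverse-strand ("R") features are stored in the same frame; only
`feature_sequence()` reverse-complements. Wrap-spanning features are
rejected: none occur in real lepidopteran annotations, and silently
splitting them would corrupt the junction arithmetic.

Declared columns (size, intergenic nucleotides) are treated as
assertions to check, never as inputs: `validate_annotation()` recomputes
sizes from coordinates and flags disagreements, anticodon positions
outside their gene span, tRNAs without anticodons, and same-strand PCG
overlaps. Overlaps of atp8/atp6, atp6/cox3 and nad4L/nad4 are
whitelisted: these pairs genuinely share sequence in metazoan
mitogenomes (atp8/atp6 through the conserved ATGATAA heptamer), so
flagging them would bury real errors in noise. On the packaged tables
the validator finds exactly three problems — the *H. nama* nad2 row
declares 1013 bp where its coordinates give 1014 (the PCG total printed
alongside is only consistent with 1014, confirming a typo), and one
anticodon position per table lies outside its gene.

Unknown gene names are errors, not warnings, with the synonym table
(cox1/COI, rrnL/lrRNA, trnL1/trnL(CUN), ...) shipped as data: a silently
misjoined gene would corrupt the supermatrix stage downstream.

## The junction ledger

For adjacent features the signed intergenic length is
`ign = start(downstream) − end(upstream) − 1`; the wrap junction closes
the circle with `start(first) + L − end(last) − 1`. This gives the
telescoping identity Σ sizes + Σ ign = genome length on any valid
circular annotation, which the test suite property-checks on random
layouts. Summary statistics exclude the control region's two flanking
junctions: the control region is itself the largest non-coding segment
and is accounted separately, and this is the only reading under which
the published spacer counts (12 spacers / 150 bp and 11 / 118 bp for
the two genomes) are reproduced from the printed coordinates. Junction
motif searches are exact matches on the forward strand, as such motifs
are conventionally quoted; reverse-complement search is an explicit
flag.

## Codon usage

The genetic code is NCBI table 5 (invertebrate mitochondrial: ATA=Met,
TGA=Trp, AGA/AGG=Ser), with leucine split into Leu1 (CUN) / Leu2 (UUR)
and serine into Ser1 (AGN) / Ser2 (UCN), the standard presentation for
mitochondrial RSCU plots. `extract_codons()` splits the sense strand
into triplets; a 1–2 nt trailing remainder is a truncated stop (T/TA,
completed to UAA by polyadenylation — cox2 and nad4 end this way in both
genomes), and a final TAA/TAG is classified as the stop.

Counting conventions are explicit because published codon totals are
convention-dependent and often not recomputable from printed gene
lengths (the sum of floor(size/3) over the *H. persimilis* PCGs is
3740; no single start/stop convention maps this onto a printed total of
3703, so this package reports totals under its own documented default
rather than asserting any published value). Defaults: start codons are
counted, classified stops are not, and a non-ATN initiation codon (the
cox1 CGA) is counted in the total but withheld from its synonymous
family — an initiation codon read as arginine would distort the Arg
family's RSCU. Both toggles are exposed. Within every family with
nonzero total, Σ RSCU equals the family size (mean 1) to machine
precision, and per-family codons-per-thousand sums to 1000; both are
tested invariants.

## Control-region dissection

The scanner reads the control region from its rrnS-proximal boundary on
the forward strand and reports four elements, each possibly absent:

| element | definition | default parameters |
|---|---|---|
| origin motif | first exact ATAGA | motif configurable |
| poly-T | longest perfect T-run starting within a window after the motif | window 10 bp, min run 5 |
| microsatellite | maximal perfect (AT)n runs, left-greedy | motif AT, min 5 copies |
| tandem repeat | self-comparison arrays (below) | unit 10–50 bp, ≥1.9 copies, ≥85% identity |
| poly-A | longest perfect A-run ending within a window of the downstream boundary | window 10 bp, min run 5 |

Poly-runs are perfect: a single interruption terminates the run,
matching how these blocks appear in comparative alignments. The
adjacency window expresses that the poly-T follows the motif closely
without demanding exact abutment; 10 bp is a configuration default, not
a biological claim.

The tandem detector is deliberately simple and fully specified: for
each unit length p, an array over span [a, b] has copies
(b − a + 1)/p and adjacent-copy identity = matches between the span and
its p-shifted self, divided by (span − p). Valid arrays need ≥ 1.9
copies and ≥ 85% identity; overlapping candidates resolve greedily to
the largest span (ties: smaller unit, then smaller start), and the
flanks are rescanned, so reported arrays never overlap. The test suite
checks the scanner against an exhaustive enumeration oracle on short
sequences. Thresholds were chosen once so that 23–25 bp units at two
copies — the size class reported in these control regions — are found
while AT-rich background produces no long-unit calls; at unit lengths
below ~10 bp an 85% identity bar is statistically easy to clear in
80–90% AT sequence, which is why the dissector (not the raw scanner)
uses min unit 10 and additionally drops calls whose consensus unit has
period ≤ 2 or whose span lies mostly (> 50%) inside an already-reported
poly-run or microsatellite: each stretch of the control region is
assigned to one element class.

## The synthetic generator

`simulate_mitogenome()` emits an annotated genome from a template. The
default template is the full 37-gene *H. persimilis* layout
(coordinates, strands, start/stop codons) with per-region AT targets
matching that genome's published composition (PCG 79.7%, tRNA 81.4%,
rrnL 84.3%, rrnS 85.1%, control region 91.2%, spacers 80.9%) and a
control-region plan of ATAGA + 19 bp poly-T + (AT)₁₀ + a 23 bp unit × 2
+ 9 bp poly-A — the element sizes reported for this species. These
defaults are the study conditions, not tuning knobs.

Generation choices favour exact bookkeeping over realism: non-coding
regions are i.i.d. draws at the region's AT target; PCG interiors are
drawn codon-wise from a sense-codon profile (so no in-frame stops
arise), whose per-base AT weight is solved numerically so the
conditional expectation over sense codons hits the region target;
overlapping features share sequence, with bases written by an upstream
feature preserved (this is how real overlapping genes work — atp6's ATG
is the middle of atp8's final codons). The ATGATAA overlap is
pre-planted when the template's atp8/atp6 junction overlaps by 7;
ATACTAA is planted at a recorded offset in the trnS2–nad1 spacer.
Ground truth (junction values, codon counts tallied by the generator's
own independent pass over the final sequence, control-region element
positions) is recorded for every run, and the whole pipeline is tested
by plant-and-recover over seeded replicates.

What the generator does not emulate: indels, secondary-structure
constraints in tRNA/rRNA, strand-asymmetric composition (A vs T are
symmetric in the draws), and site-rate heterogeneity. Passing tests
therefore demonstrate that the accounting, scanning and tree stages
recover known structure exactly; they do not validate annotation
quality or alignment choices on real data.

`evolve_panel()` draws root sequences at a chosen AT bias and evolves
them along a guide tree under a two-rate (transition/transversion,
kappa) site-independent process using closed-form transition
probabilities per branch; the tests check observed divergence against
an eigen-decomposition matrix exponential of the same rate matrix. No
indels are introduced, so per-gene outputs are aligned by construction.

## Distances, trees and monophyly

Distances use pairwise deletion by default (complete deletion by flag):
sites with gaps or N in either sequence of a pair are excluded. K2P is
the closed form d = −½ ln((1 − 2P − Q)√(1 − 2Q)); when the log argument
is non-positive the pair is saturated and set to a configurable cap with
a flag rather than NaN, so downstream tree building still runs on a
marked matrix. Neighbour joining is the standard Saitou–Nei
agglomeration (via ape), with negative branch lengths clamped to zero
with a message. Monophyly queries root the tree at a named outgroup and
ask whether an edge separates exactly the query set.

The tree stage is a verification stage: it writes the standard inputs
for external ML/Bayesian inference (relaxed PHYLIP, NEXUS, RAxML-style
partition files by gene and by gene × codon position) but does not
reimplement those engines, and the full 54-taxon analysis behind the
published tree is out of scope — topology claims are exercised on
synthetic panels. The planted-clade design is a 6-leaf tree with a long
internal branch separating (Hestinalis, Apatura) from (Hestina spp.,
Euripus), mirroring the headline taxonomic configuration at the level
of planted topology; with 13 genes × 200 bp and kappa 2, NJ on K2P
distances recovers it in ≥ 95 of 100 seeded replicates.

## Problem sizes and numerical choices

Report rounding is one decimal for percentages (the precision of
published composition tables); internal computation is unrounded.
Simulations in the packaged analyses and checks use one full 15,252 bp
genome per seed, 50–100 seeded 376 bp control regions, 100 six-taxon
panels of 2,600 bp, and oracle comparisons on sequences ≤ 200 bp —
sizes chosen so the whole suite runs in a few minutes on one CPU while
leaving each statistical check well-powered. Degenerate inputs are
errors with named offenders (empty regions, genes under 6 nt, pairs
with zero comparable sites, asymmetric distance matrices); content
problems in annotations are validator reports, never errors.

## Known limitations

- GenBank parsing covers the single-record, non-join subset this
  pipeline emits; joined or wrap-spanning locations are rejected.
- The tandem detector reports perfect/near-perfect arrays under fixed
  thresholds; it is not a substitute for alignment-scored repeat
  finders on diverged repeats.
- Composition statistics of the two real genomes require their full
  sequences, which are not shipped; the packaged tables carry the
  annotation only, and sequence-level statistics are demonstrated on
  synthetic genomes.
- Bootstrap resampling and model-based inference are intentionally
  absent; the NJ stage verifies topology logic only.
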