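---
title: "Methods: characterizing a circular baculovirus genome with baculokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a circular baculovirus genome with baculokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

baculokit re-implements, as tested reusable code, the computational steps of
a nucleopolyhedrovirus (NPV) genome characterization: ORF annotation on a
circular genome under explicit selection rules, detection of homologous
repeat (*hr*) regions from a degenerate 48-bp imperfect inverted-repeat
consensus, pileup-based intra-isolate SNP/indel frequency analysis, a
core-gene inventory with pairwise-identity summaries, and a concatenated
core-gene distance phylogeny with bootstrap. Raw sequencing reads for this
kind of study are typically not deposited, so a synthetic-data generator
reproduces the statistical structure of the assembly (genome size and
composition, repeat architecture, variant frequency spectrum, read depth)
with full ground truth, and the pipeline is validated by planted-truth
recovery.

## Circular coordinates

All coordinates are 1-based inclusive (GenBank convention). A feature with
`start > end` wraps the origin; GFF3 output splits such features into two
part-lines sharing one `ID`. The code never assumes a particular rotation
of the circle: ORF enumeration, repeat scanning and clustering all continue
across the origin, and a rotation test asserts that rotating the genome
permutes coordinates while preserving every (strand, size, protein) triple.

## ORF annotation

`find_orfs()` decomposes each strand of the circle into codon cycles (one
cycle when the genome length is not divisible by 3, three otherwise) and,
for every stop codon, reports the longest start-to-stop ORF — the most
upstream in-frame ATG after the previous stop. Defaults: minimum 50 codons
excluding the stop; start codon set {ATG}; stop codons {TAA, TAG, TGA}
(translation table 1). Two choices deserve note:

* On circles whose length is not divisible by 3, a reading frame is a
  single cycle of length L codons, so a stop-free stretch could formally
  yield an ORF longer than the genome, overlapping itself. Such candidates
  are excluded: an ORF's span `3*(n_codons+1)` never exceeds the genome
  length. The exhaustive per-position oracle in the test suite applies the
  same cap.
* Codons containing N never match a start or stop, and any candidate whose
  span contains N is flagged rather than silently scored. Ambiguity codes
  other than N are rejected at genome construction; they do not occur in
  finished NPV assemblies.

`resolve_overlaps()` applies the selection rule: a candidate is annotated
iff it has homology evidence, or it lacks homology but is predicted
protein-coding by *both* ab initio gene finders and overlaps every larger
accepted ORF by fewer than 75 nt (shared genomic positions on the circle,
strand-agnostic; a 74-nt overlap passes, 75 fails). Candidates are
processed in decreasing size order so "larger accepted ORF" is well
defined; ties on size break by earlier footprint start, making the result
independent of input order. Homology evidence is an input table (the
BLASTp-style search itself is out of scope) with a configurable E-value
cutoff, default 1e-5.

## hr regions

The repeat-unit model is the printed mixed-case 48-bp consensus: uppercase
positions (19 of 48) are invariant across aligned repeat units, lowercase
positions vary. `scan_degenerate()` slides a fixed-length window over both
strands with a total mismatch budget of 12 (25% of 48) and, in the default
strict mode, requires the invariant positions to match exactly. The budget
tolerates the "imperfect" in imperfect inverted repeat while keeping the
chance of a strict match in 120 kb of random sequence negligible (the 19
invariant positions alone contribute a factor of 4^-19 per window).

One property of this particular consensus forced a design decision: its 19
invariant positions are exactly self-reverse-complementary, and its full
reverse complement differs from it at only 10 positions — fewer than the
mismatch budget. Every genuine repeat copy is therefore hit on *both*
strands. Overlapping windows are resolved across strands by keeping the
lower-mismatch window (ties: lower position, then plus strand), so each
physical repeat unit is reported once.

The scanner uses fixed-length windows; repeat units containing indels
relative to the consensus would require an aligner and are not modeled — a
known limitation. Units are implicitly aligned by consensus coordinates,
which replaces a multiple-alignment step for this fixed-length case.

`cluster_matches()` groups hits by single-linkage along the circle with a
1-kb start-to-start gap threshold. No threshold is standard in the
literature; 1 kb is far above intra-region neighbor distances (tens to
hundreds of nt) and far below inter-region distances (many kb), and the
generator enforces at least 1.5 kb between planted feature blocks so the
desk-scale experiments cannot sit on the boundary. `build_consensus()`
renders the recovered units column by column: all-identical columns give
an uppercase letter (shaded black), a >50% majority residue gives
lowercase (black), a >50% purine or pyrimidine class without a majority
residue gives gray (lettered with the lowercase majority residue when one
exists, otherwise the IUPAC class letter r/y), and anything else is
unshaded `n`.

## Polymorphisms

The canonical input is a per-position pileup TSV (position, ref, depth,
A/C/G/T counts, semicolon-coded insertion and deletion observations); the
study's read data are not public, so the exchange format is deliberately
minimal. `call_polymorphisms()` emits one call per alternate allele at
columns with depth ≥ 20, allele count ≥ 2 and frequency ≥ 1% — thresholds
chosen to reach the sub-6% frequencies that dominate an NPV intra-isolate
spectrum; the proprietary thresholds of the original assembly software are
unknown, so exact reproduction of a published variant count from raw reads
is not claimed. The frequency denominator is the column depth for SNPs and
indels alike. `classify_effect()` translates ref and alt codons on the
ORF's strand and frame: synonymous / nonsynonymous / nonsense for SNPs
(loss of an annotated stop is reported as nonsynonymous), frameshift for
indels of length not divisible by 3 inside an ORF, nonsynonymous for
in-frame indels (the effect enumeration has no separate in-frame-indel
class), intergenic outside all accepted ORFs; a call under two overlapping
ORFs is reported once per ORF.

## Homology and the core-gene inventory

Pairwise identity is computed from an optimal global affine-gap alignment
(Needleman–Wunsch–Gotoh, BLOSUM62 with gap open 11 / extend 1 for
proteins; +2/−3 with open 5 / extend 2 for nucleotides — community
defaults, since the original tools' parameters are unstated). The default
identity denominator excludes terminal gap columns, so a partial sequence
is compared over its overlap with a full-length gene; this is the only
sensible convention when comparing a complete gene against partial
database entries. Exhaustive enumeration of all alignments on short inputs
serves as the score oracle in the tests.

`inventory_core_genes()` takes the best-identity ORF for each of the 38
baculovirus core genes and counts a gene as present at ≥ 15% identity — a
floor low enough for the most divergent core genes (observed down to ~32%
in real comparisons) while an order of magnitude above the ~5–10% identity
of unrelated proteins under global alignment. The packaged reference set
is *synthetic* (deterministic random proteins labelled with the standard
core-gene symbols, generated by `data-raw/make_core_refs.R`): real
reference proteomes cannot be redistributed here, so accession-dependent
identity values are out of scope, and the inventory is validated
structurally — every reference mutated at 30% of sites must still be
found, 38/38. Users substitute a real group II alphabaculovirus proteome
via the `reference_set` argument for accession-based work.

## Phylogeny

Per-gene amino-acid alignments (produced upstream by any aligner) are
concatenated with strict taxon-set checking — a missing taxon is an error,
never silent gap-filling — and a partition table records each gene's
column range. Distances use the p-distance under pairwise deletion
(columns gapped in either member of a pair are dropped for that pair
only), optionally corrected: Poisson `-ln(1-p)` or gamma
`a((1-p)^(-1/a)-1)`. The gamma shape is a user parameter (default 1.0):
how the original analysis estimated its shape from the alignments is not
reproducible from the text, so estimation is explicitly not attempted.
Saturated pairs (p ≥ 1 under a corrected model) are errors, not silent
clamps.

Minimum-evolution tree inference is realized as neighbor joining, its
standard greedy heuristic; full ME search and maximum likelihood are out
of scope, and the validation surface is topology recovery, not score
parity with any particular program. Negative NJ branch lengths are clamped
to zero with a warning. On additive matrices NJ is exact; the tests verify
this against an exhaustive least-squares topology search up to 8 taxa.
`bootstrap_support()` resamples superalignment columns with replacement
(default 500 replicates), rebuilds the tree per replicate, and labels each
internal edge of the point estimate with the percentage of replicates
containing the same bipartition; replicates with saturated distances are
dropped and counted, and more than 10% dropped is an error.

## The synthetic generator

`simulate_genome()` draws an i.i.d. background at the target G+C (defaults
mirror the study conditions: 119,054 bp at 40%), then packs feature blocks
— 25 ORFs of 60–400 codons on random strands, five hr regions with copy
counts {1,2,3,4,4} — in shuffled order with ≥ 1.5 kb spacing. ORF interior
codons are drawn from the 61 non-stop codons with a composition tilt
(solved numerically) so that rejecting the AT-rich stop codons does not
inflate G+C; realized G+C stays within 0.5 percentage points of target.
Planted repeat units mutate only the variable (lowercase) consensus
positions, at 8% per base — what the mixed-case consensus asserts about
real units; copies mutated at invariant positions are a strict-mode
detection limitation, demonstrated in the tests.

The variant plan mirrors the study's spectrum: 878 variants, of which ten
sit at ≥ 8% — five at the published positions and frequencies (1320:
17.44%, 7468: 14.63%, 66442: 11.08%, 66453: 10.10%, 114338: 12.5%) and
five more between 10.4 and 13% — plus a bulk of 860 SNPs and 8 short
indels uniform in 3.0–5.5%, so "most variants below 6%" holds. The bulk
range keeps every planted frequency more than three binomial standard
errors (at 941× depth) from both the 8% class boundary and the 1% calling
floor; with ~860 bulk draws a rare crossing of the 8% line remains
possible at some seeds, which is the honest behavior of a frequency
spectrum read at finite depth. `simulate_pileup()` draws per-position
depth Poisson around the mean (default 941×), allele counts binomially at
the planted frequency, and uniform sequencing errors at 0.001 per base
spread over the non-reference bases.

`evolve_alignment()` places substitution events along each branch as a
Poisson process at the branch-length rate, replacing the residue with one
of the 19 alternatives uniformly. This keeps the simulator self-consistent
with the p/Poisson/gamma distance formulas used downstream, at a known
cost: with a finite 20-letter alphabet the expected leaf-pair difference
over a path of length t is `(19/20)(1 - exp(-20t/19))`, slightly below the
idealized `1 - exp(-t)`, so the Poisson correction under-estimates large
distances (about 3.6% at t = 1, negligible below t ≈ 0.5). The tests
therefore check the estimator against this closed form, and recovery
experiments use branch lengths in the regime where the bias is far below
binomial noise. An empirically-derived amino-acid substitution matrix was
deliberately not used: it would break the closed-form correspondence
between simulator and estimator that makes the tests exact.

## Problem sizes and determinism

The desk-scale experiments run at the study's native scale where that is
cheap (119-kb genome, 941× depth, 878 variants, 38 genes, 5,000
concatenated columns, 500 bootstrap replicates in the analysis scripts)
and at reduced bootstrap counts (100) inside the test suite. Every
generator is a pure function of its configuration and seed; re-running any
stage with the same inputs is bit-identical, and report writers fix float
formatting (2 decimals for percents, 6 for branch lengths) so outputs are
diffable.

## Known limitations

* Repeat units with internal indels are invisible to the fixed-window
  scanner.
* The synthetic core-gene references validate machinery, not biology;
  accession-dependent identity statistics require a real reference
  proteome.
* The gamma shape is supplied, not estimated.
* The generator's i.i.d. background has no dinucleotide structure, no
  transcriptional organization, and no real codon usage; passing
  planted-truth recovery demonstrates correctness of the detection
  machinery under the stated statistical model, not performance on real
  genomes with repeat families or compositional heterogeneity.
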