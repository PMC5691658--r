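# baculokit

Toolkit and analysis workflow for characterizing circular baculovirus
(nucleopolyhedrovirus, NPV) genomes. Given an assembled genome, evidence
tables and read pileups, it reproduces the standard computational
characterization of a new NPV isolate:

- **ORF annotation** — six-frame enumeration on circular topology
  (continuing across the origin), keeping ORFs of ≥ 50 codons that either
  have homology evidence or are predicted by both ab initio gene finders
  and overlap no larger accepted ORF by ≥ 75 bp;
- ***hr* regions** — detection of homologous repeat regions as clusters of
  a degenerate 48-bp imperfect inverted repeat, scanned under a 12-mismatch
  budget with invariant (uppercase) consensus positions required to match,
  plus Fig-style mixed-case/shaded consensus rendering;
- **polymorphisms** — SNP/indel calling from per-position pileups
  (depth ≥ 20, ≥ 2 reads, frequency ≥ 1%), coding-effect classification
  (synonymous / nonsynonymous / nonsense / frameshift / intergenic) and
  the intra-isolate frequency spectrum;
- **core genes** — inventory of the 38 baculovirus core genes by global
  affine alignment (BLOSUM62, terminal gaps excluded from the identity
  denominator) with min/median/max identity summaries;
- **phylogeny** — concatenation of per-gene amino-acid alignments,
  p / Poisson / gamma distances under pairwise deletion
  (`d = -ln(1-p)`, `d = a((1-p)^(-1/a) - 1)`), neighbor-joining trees and
  column-resampling bootstrap supports.

Because raw reads for such studies are generally not deposited, the package
ships a synthetic-data generator (`simulate_genome()`, `simulate_pileup()`,
`evolve_alignment()`) that reproduces the statistical structure of a real
NPV assembly — ~119 kb circular at 40% G+C, five *hr* regions with one to
four repeat copies, 878 variants with ten at ≥ 8% observed at 941× depth —
with complete ground truth, so every stage is validated by planted-truth
recovery.

## Worked example

```r
library(baculokit)

sim <- simulate_genome(genome_sim_config(seed = 42L))   # default study conditions
g <- sim$genome
gc_content(g)
#> [1] 40.16
regions <- cluster_matches(scan_degenerate(g), g)
regions$copy_count
#> [1] 1 4 3 4 2
pileup <- simulate_pileup(g, sim$truth, depth = 941, seed = 42L)
calls <- call_polymorphisms(pileup)
s <- summarize_frequencies(calls, thresholds = c(6, 8))
c(total = s$total, ge8 = unname(s$n_ge[["8%"]]))
#> total   ge8
#>   878    10
head(s$top$frequency, 5)
#> [1] 16.88 15.65 14.94 14.00 11.44
```

The genome realizes the configured 40% G+C; the scan recovers the five
planted *hr* regions with copy counts {1,2,3,4,4}; all 878 planted variants
are called with exactly ten at ≥ 8%, the highest near the planted 17.44%.

The same pipeline runs as a narrated workflow in `analysis/`
(`01_simulate_fixture.R` … `06_phylogeny.R`, executed in order from the
repository root with `Rscript`); small result tables land in `results/`,
large intermediates in `scratch/`.

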