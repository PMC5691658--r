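#!/usr/bin/env Rscript
# Stage 1: build the default synthetic study genome (seed 42).
#
# The generator plants, on a 119,054-bp circular sequence at 40% G+C:
# 25 ORFs (60-400 codons, both strands), five hr regions carrying 1-4
# copies of the 48-bp repeat consensus, and a plan of 878 variants (ten at
# >= 8%, the rest a low-frequency bulk). Large artifacts (genome FASTA,
# truth JSON) go to scratch/; small summaries to results/.
# Run from the repository root: Rscript analysis/01_simulate_fixture.R

suppressPackageStartupMessages(library(baculokit))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- genome_sim_config(seed = 42L)
sim <- simulate_genome(cfg)
g <- sim$genome

write_fasta(list(g), "scratch/fixture_genome.fasta")
save_truth(sim$truth, "scratch/fixture_truth.json")

stats <- c(sprintf("id\t%s", g$id),
           sprintf("length_bp\t%d", g$length),
           sprintf("gc_pct\t%.2f", gc_content(g)),
           sprintf("planted_orfs\t%d", nrow(sim$truth$orfs)),
           sprintf("planted_hr_units\t%d", nrow(sim$truth$hr_units)),
           sprintf("planted_variants\t%d", nrow(sim$truth$variants)))
writeLines(stats, "results/01_genome_stats.tsv")

message(sprintf("simulated %s: %d bp, G+C %.2f%%", g$id, g$length, gc_content(g)))
message(sprintf("planted: %d ORFs, %d repeat units in %d hr regions, %d variants",
                nrow(sim$truth$orfs), nrow(sim$truth$hr_units),
                length(sim$truth$hr_copy_counts), nrow(sim$truth$variants)))
message("genome and ground truth written to scratch/, summary to results/01_genome_stats.tsv")
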