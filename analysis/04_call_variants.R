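#!/usr/bin/env Rscript
# Stage 4: intra-isolate polymorphism calling and frequency spectrum.
#
# Simulates a 941x pileup carrying the planted variant plan, calls SNPs and
# indels (depth >= 20, >= 2 supporting reads, frequency >= 1%), classifies
# coding effects against the stage-02 annotation, and summarizes the
# frequency spectrum. Requires stages 01-02.

suppressPackageStartupMessages(library(baculokit))

g <- read_genome_fasta("scratch/fixture_genome.fasta")[[1]]
truth <- load_truth("scratch/fixture_truth.json")
ann <- read.delim("results/02_orfs.tsv", stringsAsFactors = FALSE)

pileup <- simulate_pileup(g, truth, depth = 941, seed = 42L)
write_pileup(pileup, "scratch/fixture_pileup.tsv")
message(sprintf("simulated pileup: %d positions, mean depth %.0fx",
                nrow(pileup), mean(pileup$depth)))

calls <- call_polymorphisms(pileup)
calls <- classify_effect(calls, ann, g)
s <- summarize_frequencies(calls, thresholds = c(6, 8))
message(sprintf("%d variants called (%d planted); %d at >= 8%%, %d at <= 6%%",
                s$total, nrow(truth$variants), s$n_ge[["8%"]], s$n_le[["6%"]]))
message(sprintf("effect classes: %s",
                paste(sprintf("%s %d", names(table(calls$effect)), table(calls$effect)),
                      collapse = ", ")))

write_calls_tsv(calls, "scratch/fixture_polymorphisms.tsv")
top <- s$top[, c("position", "kind", "alt_count", "depth", "frequency", "effect")]
write.table(top, "results/04_top_variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(c(sprintf("total_calls\t%d", s$total),
             sprintf("ge_8pct\t%d", s$n_ge[["8%"]]),
             sprintf("le_6pct\t%d", s$n_le[["6%"]]),
             sprintf("top_frequency_pct\t%.2f", s$top$frequency[1])),
           "results/04_frequency_summary.tsv")
message("frequency summary in results/04_*, full calls in scratch/")
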