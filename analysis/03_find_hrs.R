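#!/usr/bin/env Rscript
# Stage 3: homologous repeat (hr) region detection.
#
# Scans both strands for the 48-bp degenerate consensus (total mismatch
# budget 12, invariant positions exact), clusters hits within 1 kb into
# regions, and renders the recovered repeat-unit consensus with the
# case/shading convention (uppercase = invariant column, lowercase =
# majority, gray = base-class majority). Requires stage 01.

suppressPackageStartupMessages(library(baculokit))

g <- read_genome_fasta("scratch/fixture_genome.fasta")[[1]]
truth <- load_truth("scratch/fixture_truth.json")

matches <- scan_degenerate(g)
regions <- cluster_matches(matches, g)
message(sprintf("%d repeat units in %d hr regions (copy counts: %s)",
                nrow(matches), nrow(regions),
                paste(regions$copy_count, collapse = ", ")))
message(sprintf("planted: %d units in %d regions (copy counts: %s)",
                nrow(truth$hr_units), length(truth$hr_copy_counts),
                paste(sort(truth$hr_copy_counts), collapse = ", ")))

write.table(as.data.frame(regions), "results/03_hr_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gff3(hrs_as_features(regions, g), g, "results/03_hrs.gff3")
write_bed(hrs_as_features(regions, g), g, "results/03_hr_units.bed")

cons <- build_consensus(matches$matched_seq)
writeLines(c(sprintf("recovered_consensus\t%s", cons$consensus),
             sprintf("seed_consensus\t%s", hr_consensus()),
             sprintf("mean_unit_ir_score\t%.3f", mean(matches$ir_score))),
           "results/03_hr_consensus.txt")
message(sprintf("recovered consensus: %s", cons$consensus))
message("hr tables written to results/03_*")
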