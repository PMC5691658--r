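# Generates inst/extdata/core_gene_refs_synthetic.faa: 38 synthetic
# reference proteins labelled with the standard baculovirus core-gene
# symbols. The sequences are deterministic random amino-acid strings --
# stand-ins for a real group II alphabaculovirus proteome, sufficient for
# structural (planted-truth) validation of the inventory machinery.
# Run from the repository root: Rscript data-raw/make_core_refs.R

core_genes <- c(
  "lef-1", "lef-2", "lef-4", "lef-5", "lef-8", "lef-9", "p47",
  "dnapol", "helicase", "alk-exo", "vlf-1", "gp41", "vp39", "vp91",
  "vp1054", "p6.9", "38k", "p33_ac92", "ac53", "ac66", "pif-6_ac68",
  "ac78", "ac81", "ac93", "p40_ac101", "p48_ac103", "odv-ec43_ac109",
  "pif-8_ac110", "pif-3_ac115", "pif-1_ac119", "ac142", "odv-e18_ac143",
  "odv-ec27_ac144", "pif-5_odv-e56", "p74_pif-0", "pif-2_ac22",
  "pif-4_ac96", "p6.9b_38k2")
stopifnot(length(core_genes) == 38L)

aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
set.seed(20170307)
lens <- sample(120:900, 38L)
seqs <- vapply(lens, function(n) paste(sample(aa, n, replace = TRUE), collapse = ""),
               character(1))

lines <- character(0)
for (i in seq_len(38L)) {
  lines <- c(lines, sprintf(">%s synthetic reference", core_genes[i]),
             substring(seqs[i], seq(1, lens[i], 70), pmin(seq(1, lens[i], 70) + 69, lens[i])))
}
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(lines, "inst/extdata/core_gene_refs_synthetic.faa")
cat("wrote", length(core_genes), "references, total", sum(lens), "aa\n")
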