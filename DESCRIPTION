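Package: baculokit
Title: Baculovirus Genome Characterization Toolkit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for characterizing circular baculovirus
    (nucleopolyhedrovirus) genomes: six-frame ORF enumeration on circular
    topology with evidence-based acceptance rules, detection of homologous
    repeat (hr) regions from a degenerate 48-bp imperfect inverted-repeat
    consensus, pileup-based intra-isolate SNP/indel frequency analysis,
    core-gene inventory with pairwise-identity summaries, and concatenated
    core-gene distance phylogenetics (neighbor joining with bootstrap).
    Includes a synthetic-data generator that plants ORFs, repeat regions and
    low-frequency variants with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
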