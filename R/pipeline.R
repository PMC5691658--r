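#' Pipeline configuration with module defaults
#'
#' Any parameter left NULL takes the corresponding module default. Inputs
#' other than the genome are optional; stages without inputs are skipped.
#'
#' @param genome a [circular_genome()] (or FASTA path).
#' @param evidence ORF evidence data.frame (or TSV path), optional.
#' @param pileup pileup data.frame (or TSV path), optional.
#' @param proteins named protein vector for the core-gene inventory;
#'   `"auto"` translates the accepted ORFs.
#' @param core_refs reference set for [inventory_core_genes()], optional.
#' @param alignments list of [gene_alignment()] objects, optional.
#' @param min_codons,max_overlap ORF stage parameters.
#' @param consensus,max_mismatch,strict,max_gap hr stage parameters.
#' @param min_depth,min_alt,min_freq variant stage parameters.
#' @param identity_floor core-gene stage parameter.
#' @param model,gamma_shape,n_boot,seed phylogeny stage parameters.
#' @return config list.
#' @export
pipeline_config <- function(genome, evidence = NULL, pileup = NULL,
                            proteins = "auto", core_refs = NULL, alignments = NULL,
                            min_codons = 50L, max_overlap = 75L,
                            consensus = degenerate_consensus(), max_mismatch = 12L,
                            strict = TRUE, max_gap = 1000L,
                            min_depth = 20L, min_alt = 2L, min_freq = 1.0,
                            identity_floor = 15,
                            model = "poisson", gamma_shape = 1.0,
                            n_boot = 500L, seed = 1L) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)[[1L]]
  if (is.character(evidence)) evidence <- read_evidence_tsv(evidence)
  if (is.character(pileup)) pileup <- read_pileup(pileup)
  as.list(environment())
}

#' Run the end-to-end genome characterization
#'
#' Stages: genome statistics (length, G+C); ORF enumeration and acceptance;
#' hr-region detection and consensus rendering; polymorphism calling and
#' frequency summary; core-gene inventory with identity summary; and, when
#' alignments are supplied, the concatenated NJ tree with bootstrap
#' supports. Per-stage counts are reported on stderr.
#'
#' @param cfg list from [pipeline_config()].
#' @return report list with one element per executed stage, plus the config
#'   (for provenance).
#' @export
run_characterization <- function(cfg) {
  report <- list(config = cfg[setdiff(names(cfg), c("genome", "evidence", "pileup",
                                                    "proteins", "core_refs", "alignments"))])
  g <- cfg$genome
  report$genome_stats <- list(id = g$id, length = g$length, gc_pct = gc_content(g))
  message(sprintf("[genome] %s: %d bp, G+C %.2f%%",
                  g$id, g$length, report$genome_stats$gc_pct))

  cands <- find_orfs(g, min_codons = cfg$min_codons)
  ev <- cfg$evidence
  if (is.null(ev)) {
    # without evidence every candidate is unsupported; annotate candidates only
    ev <- data.frame(orf_id = character(0), has_homology = logical(0),
                     best_subject = character(0), best_identity = numeric(0),
                     fgenes_pred = logical(0), zcurve_pred = logical(0))
  }
  ann <- resolve_overlaps(cands, ev, g, max_overlap = cfg$max_overlap,
                          min_codons = cfg$min_codons)
  report$orfs <- ann
  message(sprintf("[orfs] %d candidates, %d accepted (%s)",
                  nrow(cands), sum(ann$accepted),
                  paste(sprintf("%s: %d", names(table(ann$rejection_reason)),
                                table(ann$rejection_reason)), collapse = ", ")))

  matches <- scan_degenerate(g, cfg$consensus, cfg$max_mismatch, cfg$strict)
  regions <- cluster_matches(matches, g, max_gap = cfg$max_gap,
                             unit_length = cfg$consensus$length)
  report$hr <- list(matches = matches, regions = regions)
  if (nrow(matches) >= 2L)
    report$hr$consensus <- build_consensus(matches$matched_seq)
  message(sprintf("[hr] %d repeat units in %d regions (copies: %s)",
                  nrow(matches), nrow(regions),
                  paste(regions$copy_count, collapse = ",")))

  if (!is.null(cfg$pileup)) {
    calls <- call_polymorphisms(cfg$pileup, cfg$min_depth, cfg$min_alt, cfg$min_freq)
    calls <- classify_effect(calls, ann, g)
    report$polymorphisms <- list(calls = calls,
                                 summary = summarize_frequencies(calls))
    message(sprintf("[variants] %d calls, %d at >=8%%",
                    report$polymorphisms$summary$total,
                    report$polymorphisms$summary$n_ge[["8%"]]))
  }

  if (!is.null(cfg$core_refs)) {
    prots <- cfg$proteins
    if (identical(prots, "auto")) {
      acc <- ann[ann$accepted, , drop = FALSE]
      prots <- setNames(vapply(seq_len(nrow(acc)), function(i)
        orf_protein(g, acc[i, ]), character(1)), acc$orf_id)
    }
    hits <- inventory_core_genes(prots, cfg$core_refs, floor = cfg$identity_floor)
    report$core_genes <- list(hits = hits, n_found = sum(hits$found))
    if (any(hits$found)) report$core_genes$identity <- identity_summary(hits)
    report$orfs <- classify_conservation(report$orfs, hits, cfg$evidence)
    message(sprintf("[core] %d/%d core genes found", sum(hits$found), nrow(hits)))
  }

  if (!is.null(cfg$alignments)) {
    super <- concatenate_alignments(cfg$alignments)
    tree <- bootstrap_support(super, model = cfg$model, gamma_shape = cfg$gamma_shape,
                              n_reps = cfg$n_boot, seed = cfg$seed)
    report$phylogeny <- list(superalignment_length = super$length,
                             partitions = super$partitions,
                             tree = tree, newick = tree_newick(tree))
    message(sprintf("[phylo] %d taxa, %d columns, %d bootstrap replicates",
                    length(super$taxa), super$length, cfg$n_boot))
  }
  report
}

#' Write the report bundle to a directory
#'
#' Fixed formatting (2 decimals for percents, 6 for branch lengths) keeps
#' re-runs byte-identical under an identical config and seed.
#'
#' @param report list from [run_characterization()].
#' @param dir output directory (created if missing).
#' @param genome the genome (for GFF3 headers).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir, genome) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- report$genome_stats
  writeLines(c(sprintf("id\t%s", gs$id), sprintf("length\t%d", gs$length),
               sprintf("gc_pct\t%.2f", gs$gc_pct)),
             file.path(dir, "genome_stats.tsv"))
  if (!is.null(report$orfs)) {
    write.table(report$orfs, file.path(dir, "orfs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gff3(orfs_as_features(report$orfs, genome), genome,
               file.path(dir, "orfs.gff3"))
  }
  if (!is.null(report$hr)) {
    regions <- report$hr$regions
    write.table(as.data.frame(regions), file.path(dir, "hr_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_gff3(hrs_as_features(regions, genome), genome, file.path(dir, "hrs.gff3"))
    if (!is.null(report$hr$consensus))
      writeLines(report$hr$consensus$consensus, file.path(dir, "hr_consensus.txt"))
  }
  if (!is.null(report$polymorphisms))
    write_calls_tsv(report$polymorphisms$calls, file.path(dir, "polymorphisms.tsv"))
  if (!is.null(report$core_genes))
    write.table(report$core_genes$hits, file.path(dir, "core_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$phylogeny)) {
    writeLines(report$phylogeny$newick, file.path(dir, "tree.nwk"))
    write.table(report$phylogeny$partitions, file.path(dir, "partitions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
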