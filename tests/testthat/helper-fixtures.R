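# Shared fixture constructors.

# a genome carrying one planted plus-strand ORF of n_codons (excl. stop)
make_orf_genome <- function(n_codons, pad_left = 30L, pad_right = 30L,
                            topology = "circular") {
  interior <- paste(rep("GCC", n_codons - 1L), collapse = "")
  circular_genome(paste0(strrep("C", pad_left), "ATG", interior, "TAA",
                         strrep("C", pad_right)), topology = topology)
}

evidence_row <- function(orf_id, hom = FALSE, fg = FALSE, zc = FALSE) {
  data.frame(orf_id = orf_id, has_homology = hom,
             best_subject = if (hom) "subject" else "", best_identity = NA_real_,
             fgenes_pred = fg, zcurve_pred = zc, stringsAsFactors = FALSE)
}

# two plus-strand ORF candidates with a controlled overlap; "small" smaller
overlap_pair <- function(overlap_nt) {
  L <- 3000L
  big_span <- 3L * 101L   # 100 codons
  small_span <- 3L * 61L  # 60 codons
  s1 <- 101L; e1 <- s1 + big_span - 1L
  s2 <- e1 - overlap_nt + 1L; e2 <- s2 + small_span - 1L
  cand <- data.frame(
    orf_id = c("big", "small"),
    start = c(s1, s2), end = c(e1, e2), strand = "+", frame = 0L,
    n_codons = c(100L, 60L), wraps = FALSE,
    istart = c(s1, s2), iend = c(e1, e2), has_n = FALSE,
    stringsAsFactors = FALSE)
  list(cand = cand, genome = random_genome(L))
}
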