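pileup_row <- function(position, ref, depth, A = 0L, C = 0L, G = 0L, T = 0L,
                       ins = "", del = "") {
  data.frame(position = position, ref = ref, depth = depth,
             A = A, C = C, G = G, T = T, ins = ins, del = del,
             stringsAsFactors = FALSE)
}

test_that("pileup TSV round-trips, including indel fields", {
  g <- random_genome(500)
  truth <- list(variants = data.frame(
    position = c(100L, 200L, 300L),
    kind = c("SNP", "insertion", "deletion"),
    ref = c("A", "A", "A"), alt = c("G", "TTG", "-"),
    len = c(1L, 3L, 2L), freq = c(20, 15, 10), stringsAsFactors = FALSE))
  pu <- simulate_pileup(g, truth, depth = 200, seed = 3L)
  tmp <- tempfile(fileext = ".tsv")
  write_pileup(pu, tmp)
  back <- read_pileup(tmp)
  expect_equal(back, pu)
})

test_that("read_pileup validates and tolerates empty input", {
  tmp <- tempfile(fileext = ".tsv")
  file.create(tmp)
  expect_equal(nrow(read_pileup(tmp)), 0L)
  write_pileup(pileup_row(7L, "A", 10L, A = 9L, G = 5L), tmp)
  expect_error(read_pileup(tmp), "position\\(s\\): 7")
})

test_that("calling respects depth, count and frequency thresholds", {
  # all-reference column: no call
  pu <- pileup_row(1L, "A", 200L, A = 200L)
  expect_equal(nrow(call_polymorphisms(pu)), 0L)

  # 25/200 is one SNP at 12.50%
  pu <- pileup_row(10L, "A", 200L, A = 175L, G = 25L)
  calls <- call_polymorphisms(pu)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$frequency, 12.50)
  expect_equal(calls$alt, "G")

  # below min_alt, below min_freq, below min_depth: all silent
  expect_equal(nrow(call_polymorphisms(pileup_row(1L, "A", 200L, A = 199L, G = 1L))), 0L)
  expect_equal(nrow(call_polymorphisms(pileup_row(1L, "A", 400L, A = 397L, G = 3L))), 0L)
  expect_equal(nrow(call_polymorphisms(pileup_row(1L, "A", 19L, A = 9L, G = 10L))), 0L)

  # multi-allelic column: one call per alternate allele
  pu <- pileup_row(5L, "A", 200L, A = 150L, C = 20L, G = 30L)
  calls <- call_polymorphisms(pu)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("C", "G"))

  # indels share the depth denominator
  pu <- pileup_row(8L, "T", 200L, T = 180L, ins = "GG:10", del = "2:10")
  calls <- call_polymorphisms(pu)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$kind, c("insertion", "deletion"))
  expect_equal(calls$frequency, c(5, 5))
})

test_that("no call is ever emitted below a configured threshold", {
  set.seed(88)
  for (i in 1:8) {
    md <- sample(10:50, 1); ma <- sample(2:5, 1); mf <- runif(1, 0.5, 4)
    g <- random_genome(300)
    truth <- list(variants = data.frame(
      position = sample(300, 20), kind = "SNP", ref = "A",
      alt = sample(c("A", "C", "G", "T"), 20, TRUE), len = 1L,
      freq = runif(20, 0.1, 30), stringsAsFactors = FALSE))
    pu <- simulate_pileup(g, truth, depth = sample(30:300, 1), seed = i)
    calls <- call_polymorphisms(pu, min_depth = md, min_alt = ma, min_freq = mf)
    if (nrow(calls) == 0L) next
    expect_true(all(calls$depth >= md))
    expect_true(all(calls$alt_count >= ma))
    expect_true(all(100 * calls$alt_count / calls$depth >= mf))
  }
})

test_that("calls are invariant under pileup row order", {
  g <- random_genome(400)
  truth <- list(variants = data.frame(
    position = c(50L, 150L, 250L), kind = "SNP", ref = "A",
    alt = c("G", "T", "C"), len = 1L, freq = c(10, 20, 30),
    stringsAsFactors = FALSE))
  pu <- simulate_pileup(g, truth, depth = 300, seed = 5L)
  shuffled <- pu[sample.int(nrow(pu)), , drop = FALSE]
  tmp <- tempfile(); write_pileup(shuffled, tmp)
  expect_equal(call_polymorphisms(read_pileup(tmp)), call_polymorphisms(pu))
})

# --- coding-effect classification on a constructed genome ------------------
# plus-strand ORF at 101..253 (50 codons + stop), minus-strand ORF elsewhere
effect_fixture <- function() {
  # TTAA-repeat background: stop codons in all six frames, no ATG anywhere,
  # so the only ORFs are the two planted ones
  bg <- rep(c("T", "T", "A", "A"), length.out = 600)
  # CTA (Leu) interior: its antisense reading is a wall of TAG stops, so no
  # spurious ORF opens on the complementary strand
  plus_orf <- paste0("ATG", strrep("CTA", 49L), "TAA")        # M + 49x Leu
  bg[101:253] <- strsplit(plus_orf, "")[[1]]
  minus_orf <- reverse_complement(paste0("ATG", strrep("AAA", 49L), "TGA"))
  bg[301:453] <- strsplit(minus_orf, "")[[1]]
  g <- circular_genome(paste(bg, collapse = ""))
  cand <- find_orfs(g, min_codons = 50L)
  ev <- data.frame(orf_id = cand$orf_id, has_homology = TRUE,
                   best_subject = "s", best_identity = 50,
                   fgenes_pred = TRUE, zcurve_pred = TRUE)
  ann <- resolve_overlaps(cand, ev, g)
  list(genome = g, ann = ann)
}

call_at <- function(position, ref, alt, kind = "SNP") {
  data.frame(position = position, ref = ref, alt = alt, kind = kind,
             alt_count = 50L, depth = 400L, frequency = 12.5,
             stringsAsFactors = FALSE)
}

test_that("synonymous, nonsynonymous and nonsense SNPs classify correctly", {
  fx <- effect_fixture()
  # third position of a CTA (Leu) codon: CTA->CTG is synonymous
  pos3 <- 101L + 3L + 2L                 # codon 2, third base
  out <- classify_effect(call_at(pos3, "A", "G"), fx$ann, fx$genome)
  expect_equal(out$effect, "synonymous")

  # ATG->ACG (Met->Thr), nonsynonymous at codon 1, base 2
  out <- classify_effect(call_at(102L, "T", "C"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")

  # CTA->GTA is Leu->Val, nonsynonymous
  out <- classify_effect(call_at(104L, "C", "G"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")

  # CTA->CGA is Leu->Arg, nonsynonymous
  out <- classify_effect(call_at(105L, "T", "G"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")

  # intergenic position
  out <- classify_effect(call_at(50L, "C", "T"), fx$ann, fx$genome)
  expect_equal(out$effect, "intergenic")
  expect_equal(out$orf_id, "")
})

test_that("minus-strand codons are read on the coding strand", {
  fx <- effect_fixture()
  # minus ORF occupies genomic 301..453; transcription right-to-left.
  # Codon 2 (AAA, Lys) sits at genomic 448..450 read as complement
  # of 450,449,448. Genomic bases there are TTT; a genomic T->C at 450
  # makes the codon GAA (Glu): nonsynonymous.
  out <- classify_effect(call_at(450L, "T", "C"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")
  # genomic T->G at 448 reads as codon AAC (Asn): nonsynonymous
  out <- classify_effect(call_at(448L, "T", "G"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")
  # AAA -> TAA (stop) via genomic T->A at position 450: nonsense
  out <- classify_effect(call_at(450L, "T", "A"), fx$ann, fx$genome)
  expect_equal(out$effect, "nonsense")
})

test_that("indels inside ORFs are frameshift unless in frame", {
  fx <- effect_fixture()
  out <- classify_effect(call_at(110L, "-", "GG", kind = "insertion"),
                         fx$ann, fx$genome)
  expect_equal(out$effect, "frameshift")
  out <- classify_effect(call_at(110L, "-", "GGG", kind = "insertion"),
                         fx$ann, fx$genome)
  expect_equal(out$effect, "nonsynonymous")
  out <- classify_effect(call_at(110L, "NN", "-", kind = "deletion"),
                         fx$ann, fx$genome)
  expect_equal(out$effect, "frameshift")
  out <- classify_effect(call_at(50L, "NN", "-", kind = "deletion"),
                         fx$ann, fx$genome)
  expect_equal(out$effect, "intergenic")
})

test_that("a SNP inside two overlapping ORFs is reported once per ORF", {
  set.seed(61)
  g <- random_genome(600)
  ann <- data.frame(
    orf_id = c("ORFa", "ORFb"),
    start = c(101L, 352L), end = c(253L, 200L),
    strand = c("+", "-"), frame = 0L, n_codons = 50L, wraps = FALSE,
    istart = c(101L, 200L), iend = c(253L, 352L), has_n = FALSE,
    accepted = TRUE, rejection_reason = "none",
    conservation_class = NA_character_, product = "",
    stringsAsFactors = FALSE)
  out <- classify_effect(call_at(210L, "A", "G"), ann, g)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$orf_id, c("ORFa", "ORFb"))
  expect_true(all(out$effect %in% c("synonymous", "nonsynonymous", "nonsense")))
})

test_that("frequency summaries count the threshold classes", {
  s <- summarize_frequencies(call_at(1L, "A", "G")[0, ])
  expect_equal(s$total, 0L)
  expect_equal(unname(s$n_ge), c(0L, 0L))

  freqs <- c(17.44, 14.63, 12.5, 11.08, 10.10, 5.0, 4.0)
  calls <- do.call(rbind, lapply(seq_along(freqs), function(i)
    call_at(i, "A", "G")))
  calls$frequency <- freqs
  s <- summarize_frequencies(calls, thresholds = c(6, 8), top_k = 5L)
  expect_equal(s$total, 7L)
  expect_equal(unname(s$n_ge["8%"]), 5L)
  expect_equal(unname(s$n_le["6%"]), 2L)
  expect_equal(s$top$frequency, c(17.44, 14.63, 12.5, 11.08, 10.10))
})
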