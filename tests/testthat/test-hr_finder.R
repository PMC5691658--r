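test_that("ir_score matches hand counts and a brute-force scan", {
  expect_equal(ir_score("ACGT"), 1.0)
  expect_equal(ir_score("AAAA"), 0.0)
  expect_equal(ir_score("ACT"), 1.0)    # center of odd length excluded
  expect_error(ir_score("ACXU"), "non-DNA")

  # brute-force oracle: explicit position loop
  brute_ir <- function(s) {
    ch <- strsplit(s, "")[[1]]; L <- length(ch)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    hits <- 0L; n <- 0L
    for (i in seq_len(L)) {
      j <- L + 1L - i
      if (i == j) next
      n <- n + 1L
      if (!is.na(comp[ch[i]]) && comp[ch[i]] == ch[j]) hits <- hits + 1L
    }
    hits / n
  }
  cons <- toupper(hr_consensus())
  expect_equal(ir_score(cons), brute_ir(cons))
  expect_gt(ir_score(cons), 0.5)   # the consensus is a (degraded) inverted repeat
  set.seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(6:20, 1), TRUE), collapse = "")
    expect_equal(ir_score(s), brute_ir(s))
  }
})

test_that("the consensus matches itself once, at position 1, with zero mismatches", {
  g <- circular_genome(hr_consensus())
  m <- scan_degenerate(g)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 1L)
  expect_equal(m$mismatch_total, 0L)
  expect_equal(m$mismatch_strict, 0L)
  expect_equal(m$strand, "+")
})

test_that("a copy mutated at variable positions is detected with the right count", {
  set.seed(21)
  cons <- strsplit(toupper(hr_consensus()), "")[[1]]
  strict <- degenerate_consensus()$strict_positions
  lower_idx <- setdiff(seq_len(48L), strict)
  mut <- sample(lower_idx, 3L)
  unit <- cons
  for (i in mut) unit[i] <- sample(setdiff(c("A", "C", "G", "T"), unit[i]), 1L)
  bg <- sample(c("A", "C", "G", "T"), 3000, TRUE)
  bg[1001:1048] <- unit
  g <- circular_genome(paste(bg, collapse = ""))
  m <- scan_degenerate(g, max_mismatch = 8L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 1001L)
  expect_equal(m$mismatch_total, 3L)
  expect_equal(m$mismatch_strict, 0L)
})

test_that("strict mode rejects copies mutated at invariant positions", {
  cons <- strsplit(toupper(hr_consensus()), "")[[1]]
  strict <- degenerate_consensus()$strict_positions
  unit <- cons
  unit[strict[1]] <- setdiff(c("A", "C", "G", "T"), unit[strict[1]])[1]
  bg <- rep("C", 500)  # C-monomer background cannot shadow the consensus
  bg[201:248] <- unit
  g <- circular_genome(paste(bg, collapse = ""))
  expect_equal(nrow(scan_degenerate(g, max_mismatch = 12L, strict = TRUE)), 0L)
  relaxed <- scan_degenerate(g, max_mismatch = 12L, strict = FALSE)
  expect_equal(nrow(relaxed), 1L)
  expect_equal(relaxed$mismatch_strict, 1L)
})

test_that("scanning the reverse-complemented genome mirrors matches", {
  set.seed(77)
  bg <- sample(c("A", "C", "G", "T"), 2000, TRUE)
  bg[301:348] <- strsplit(toupper(hr_consensus()), "")[[1]]
  g <- circular_genome(paste(bg, collapse = ""))
  m <- scan_degenerate(g)
  g_rc <- circular_genome(reverse_complement(g$sequence))
  m_rc <- scan_degenerate(g_rc)
  expect_equal(nrow(m), nrow(m_rc))
  # position of window start mirrors to L - (pos + 47) + 1; strand flips
  expect_setequal(g$length - (m$position + 47L) + 1L, m_rc$position)
  expect_setequal(m$mismatch_total, m_rc$mismatch_total)
  expect_true(all(m$strand == "+"))
  expect_true(all(m_rc$strand == "-"))
})

test_that("max_mismatch must leave the scan non-vacuous", {
  g <- random_genome(500)
  expect_error(scan_degenerate(g, max_mismatch = 48L), "vacuous")
})

test_that("clustering joins nearby matches and splits distant ones", {
  g <- random_genome(20000)
  two_near <- data.frame(position = c(1000L, 1100L), strand = "+",
                         matched_seq = "x", mismatch_total = 0L,
                         mismatch_strict = 0L, ir_score = 1, has_n = FALSE)
  r <- cluster_matches(two_near, g)
  expect_equal(nrow(r), 1L)
  expect_equal(r$copy_count, 2L)
  expect_equal(r$span_start, 1000)
  expect_equal(r$span_end, 1100 + 47)

  two_far <- transform(two_near, position = c(1000L, 6000L))
  r <- cluster_matches(two_far, g)
  expect_equal(nrow(r), 2L)
  expect_equal(r$copy_count, c(1L, 1L))
})

test_that("clustering joins across the origin of a circular genome", {
  g <- random_genome(10000)
  m <- data.frame(position = c(50L, 9900L), strand = "+", matched_seq = "x",
                  mismatch_total = 0L, mismatch_strict = 0L, ir_score = 1,
                  has_n = FALSE)
  r <- cluster_matches(m, g, max_gap = 1000L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$copy_count, 2L)
  expect_equal(r$span_start, 9900)   # wrapped span starts before the origin
  expect_equal(r$span_end, 50 + 47)
})

test_that("a repeat-free random 120-kb genome yields no strict matches", {
  set.seed(4242)
  g <- random_genome(120000)
  m <- scan_degenerate(g)
  expect_equal(nrow(m), 0L)
})

test_that("consensus rendering follows the case and shading conventions", {
  cons <- toupper(hr_consensus())
  r <- build_consensus(c(cons, cons))
  expect_equal(r$consensus, cons)                 # identical columns: uppercase
  expect_true(all(r$shading == "black"))
  r <- build_consensus(c(cons, cons, cons))
  expect_equal(r$consensus, cons)                 # any n >= 2

  r <- build_consensus(c("A", "A", "A", "G"))
  expect_equal(r$consensus, "a")                  # majority: lowercase, black
  expect_equal(r$shading, "black")

  r <- build_consensus(c("A", "G", "A", "G"))
  expect_equal(r$shading, "gray")                 # purine class only
  expect_equal(r$consensus, "r")

  r <- build_consensus(c("A", "C", "G", "T"))
  expect_equal(r$shading, "none")
  expect_equal(r$consensus, "n")

  expect_error(build_consensus(c("AA", "AAA")), "unequal")
  expect_error(build_consensus("AA"), "at least 2")
})
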