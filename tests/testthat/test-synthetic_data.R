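small_cfg <- function(seed = 7L, ...) {
  genome_sim_config(length = 30000L, n_orfs = 6L, orf_codon_range = c(55L, 150L),
                    hr_plan = default_hr_plan(copies = c(1L, 3L)),
                    snp_plan = NULL, seed = seed, ...)
}

test_that("generators are pure functions of config and seed", {
  s1 <- simulate_genome(small_cfg())
  s2 <- simulate_genome(small_cfg())
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(small_cfg(seed = 8L))
  expect_false(identical(s1$genome$sequence, s3$genome$sequence))

  p1 <- simulate_pileup(s1$genome, s1$truth, depth = 50, seed = 3L)
  p2 <- simulate_pileup(s1$genome, s1$truth, depth = 50, seed = 3L)
  expect_identical(p1, p2)
})

test_that("realized G+C stays close to the target despite planted features", {
  sim <- simulate_genome(genome_sim_config(length = 120000L, gc = 0.40, seed = 11L))
  expect_lt(abs(gc_content(sim$genome) - 40), 0.5)
})

test_that("a featureless config yields a genome with no planted truth", {
  cfg <- genome_sim_config(length = 20000L, n_orfs = 0L, hr_plan = NULL,
                           snp_plan = NULL, seed = 5L)
  sim <- simulate_genome(cfg)
  expect_null(sim$truth$orfs)
  expect_null(sim$truth$hr_units)
  expect_null(sim$truth$variants)
  # chance ORFs may exist; none of them are in the truth
  expect_equal(nrow(scan_degenerate(sim$genome)), 0L)
})

test_that("infeasible packing errors instead of overlapping features", {
  cfg <- genome_sim_config(length = 5000L, n_orfs = 40L,
                           orf_codon_range = c(100L, 200L), seed = 1L)
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("planted ORFs are recovered by the ORF caller", {
  sim <- simulate_genome(small_cfg(seed = 17L))
  cand <- find_orfs(sim$genome, min_codons = 50L)
  for (i in seq_len(nrow(sim$truth$orfs))) {
    o <- sim$truth$orfs[i, ]
    # the candidate for the planted stop: same strand, same stop-codon end,
    # size at least the planted size (an upstream in-frame ATG in background
    # sequence legitimately extends the ORF)
    hit <- cand[cand$strand == o$strand & cand$end == o$end, , drop = FALSE]
    expect_equal(nrow(hit), 1L, info = o$planted_id)
    expect_gte(hit$n_codons, o$n_codons)
    if (hit$n_codons == o$n_codons) {
      expect_equal(hit$start, o$start)
      expect_equal(orf_protein(sim$genome, hit), o$protein)
    }
  }
})

test_that("planted hr copy counts are recovered exactly", {
  cfg <- genome_sim_config(length = 60000L, n_orfs = 0L, snp_plan = NULL,
                           hr_plan = default_hr_plan(copies = c(1L, 2L, 3L, 4L, 4L)),
                           seed = 23L)
  sim <- simulate_genome(cfg)
  m <- scan_degenerate(sim$genome)
  expect_equal(nrow(m), nrow(sim$truth$hr_units))
  expect_setequal(m$position, sim$truth$hr_units$position)
  reg <- cluster_matches(m, sim$genome)
  expect_equal(sort(reg$copy_count), sort(sim$truth$hr_copy_counts))
  # mismatch counts equal the planted mutation counts
  key <- match(m$position, sim$truth$hr_units$position)
  expect_equal(m$mismatch_total, sim$truth$hr_units$n_mut[key])
})

test_that("ground truth serializes and reloads", {
  sim <- simulate_genome(small_cfg(seed = 29L))
  tmp <- tempfile(fileext = ".json")
  save_truth(sim$truth, tmp)
  back <- load_truth(tmp)
  expect_equal(back$orfs$istart, sim$truth$orfs$istart)
  expect_equal(back$hr_units$position, sim$truth$hr_units$position)
  expect_equal(back$seed, sim$truth$seed)
})

test_that("pileups with zero depth produce no downstream calls", {
  g <- random_genome(500)
  pu <- simulate_pileup(g, NULL, depth = 0, seed = 1L)
  expect_true(all(pu$depth == 0L))
  expect_equal(nrow(call_polymorphisms(pu)), 0L)
})

test_that("planted variant frequencies are recovered within binomial error", {
  set.seed(67)
  g <- random_genome(2000)
  freqs <- c(17.44, 12.5, 6, 3)
  truth <- list(variants = data.frame(
    position = c(200L, 600L, 1000L, 1400L), kind = "SNP",
    ref = substring(g$sequence, c(200L, 600L, 1000L, 1400L),
                    c(200L, 600L, 1000L, 1400L)),
    alt = "N", len = 1L, freq = freqs, stringsAsFactors = FALSE))
  # choose alts different from ref
  truth$variants$alt <- vapply(truth$variants$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  for (s in 1:5) {
    pu <- simulate_pileup(g, truth, depth = 941, seed = s)
    calls <- call_polymorphisms(pu)
    for (i in seq_along(freqs)) {
      got <- calls$frequency[calls$position == truth$variants$position[i]]
      expect_length(got, 1L)
      f <- freqs[i] / 100
      se_pct <- 100 * sqrt(f * (1 - f) / 941)
      expect_lt(abs(got - freqs[i]), 3 * se_pct)
    }
  }
})

test_that("a zero-length tree evolves identical rows", {
  tr <- deep_split_tree()
  tr$edge.length[] <- 0
  al <- evolve_alignment(tr, 200L, seed = 2L)
  expect_equal(length(unique(unname(al$rows))), 1L)
  expect_equal(p_distance(al$rows[[1]], al$rows[[2]]), 0)
})

test_that("pairwise distance estimates match the simulator's closed form", {
  # two leaves at path length t; with 20 states and uniform replacement the
  # expected p-distance is (19/20)(1 - exp(-20 t / 19)); the estimator
  # -log(1-p) therefore recovers -log(1 - that) rather than t itself at
  # large t (finite-alphabet saturation)
  two_leaf <- ape::read.tree(text = "(X:0.25,Y:0.25);")
  n_sites <- 10000L
  for (s in 1:3) {
    al <- evolve_alignment(two_leaf, n_sites, seed = s)
    p_hat <- p_distance(al$rows[["X"]], al$rows[["Y"]])
    t_true <- 0.5
    p_exp <- (19 / 20) * (1 - exp(-20 * t_true / 19))
    se <- sqrt(p_exp * (1 - p_exp) / n_sites)
    expect_lt(abs(p_hat - p_exp), 3 * se)
    # at this distance the poisson correction is within one SE of the truth
    d_hat <- model_distance(p_hat, "poisson")
    expect_lt(abs(d_hat - t_true), 3 * se / (1 - p_exp) + 0.01)
  }
})

test_that("NJ on simulated alignments recovers the generating topology", {
  tr <- deep_split_tree()
  alns <- simulate_core_gene_alignments(tr, n_genes = 10L, total_sites = 3000L,
                                        seed = 31L)
  sup <- concatenate_alignments(alns)
  est <- nj_tree(distance_matrix(sup, model = "poisson"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
})
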