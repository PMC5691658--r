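#' Default hr-region plan: five regions with one-to-four repeat copies
#'
#' Copy counts \{1, 2, 3, 4, 4\} mirror the five hr regions of the study
#' genome. `mut_prob` is the per-base substitution probability applied to
#' the variable (lowercase) consensus positions of each planted copy; the
#' invariant (uppercase) positions are left intact, which is what the
#' mixed-case consensus asserts about real repeat units.
#'
#' @param copies integer vector of per-region copy counts.
#' @param mut_prob per-variable-base mutation probability.
#' @return data.frame with columns `copies`, `mut_prob`.
#' @export
default_hr_plan <- function(copies = c(1L, 2L, 3L, 4L, 4L), mut_prob = 0.08) {
  data.frame(copies = copies, mut_prob = mut_prob)
}

#' Default variant plan: 878 polymorphisms, ten at >= 8%
#'
#' The five highest-frequency SNPs are planted at the genome positions and
#' frequencies reported for the study isolate (1320: 17.44%, 7468: 14.63%,
#' 66442: 11.08%, 66453: 10.10%, 114338: 12.5%); five further variants sit
#' between 10.4% and 13%, making exactly ten at >= 8%. The remaining 860
#' SNPs and 8 small indels form the low-frequency bulk, uniform in
#' 3.0-5.5%, so that the spectrum reads "most polymorphisms below 6%".
#' Bulk frequencies keep at least two binomial standard errors (at the
#' default 941x depth) away from both the 8% class boundary and the 1%
#' calling floor, so planted-truth recovery is not a coin flip.
#'
#' @return list describing the plan; consumed by [simulate_genome()].
#' @export
default_snp_plan <- function() {
  list(
    fixed = data.frame(
      position = c(1320L, 7468L, 66442L, 66453L, 114338L),
      freq = c(17.44, 14.63, 11.08, 10.10, 12.5)),
    extra_high = c(13.0, 12.0, 11.5, 10.8, 10.4),
    n_bulk_snps = 860L,
    bulk_range = c(3.0, 5.5),
    n_ins = 4L, n_del = 4L,
    indel_range = c(4.0, 6.0),
    max_indel_len = 4L
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study genome: 119,054 bp at 40% G+C, five hr
#' regions with one-to-four copies of the 48-bp consensus, 878 variants
#' with ten at >= 8%, and 941x mean read depth.
#'
#' @param length genome length in nt.
#' @param gc target G+C fraction.
#' @param n_orfs number of planted ORFs.
#' @param orf_codon_range min/max planted ORF size in codons (excl. stop).
#' @param hr_plan data.frame from [default_hr_plan()] (NULL = no hrs).
#' @param snp_plan list from [default_snp_plan()] (NULL = no variants).
#' @param depth mean read depth for [simulate_pileup()].
#' @param error_rate per-base sequencing error rate.
#' @param seed RNG seed (all generators are pure functions of config+seed).
#' @return config list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(length = 119054L, gc = 0.40, n_orfs = 25L,
                              orf_codon_range = c(60L, 400L),
                              hr_plan = default_hr_plan(),
                              snp_plan = default_snp_plan(),
                              depth = 941, error_rate = 0.001, seed = 42L) {
  stopifnot(gc > 0, gc < 1, length >= 1000L)
  structure(list(length = as.integer(length), gc = gc, n_orfs = as.integer(n_orfs),
                 orf_codon_range = as.integer(orf_codon_range), hr_plan = hr_plan,
                 snp_plan = snp_plan, depth = depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

# base sampling probabilities (A,C,G,T) at a given GC fraction
base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# Interior ORF codons are drawn from the 61 non-stop codons. Rejecting the
# (AT-rich) stop codons inflates G+C slightly, so the sampling composition
# is tilted down via uniroot so the expected G+C of an accepted codon
# equals the target.
nonstop_codon_probs <- function(gc_target) {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  codons <- setdiff(codons, STOP_CODONS)
  gc_count <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), numeric(1))
  expected_gc <- function(g) {
    p <- base_probs(g)
    w <- vapply(strsplit(codons, ""), function(x)
      prod(p[match(x, DNA_BASES)]), numeric(1))
    w <- w / sum(w)
    sum(w * gc_count) / 3
  }
  g <- uniroot(function(g) expected_gc(g) - gc_target,
               interval = c(max(gc_target - 0.05, 1e-3), gc_target + 0.01))$root
  p <- base_probs(g)
  w <- vapply(strsplit(codons, ""), function(x) prod(p[match(x, DNA_BASES)]), numeric(1))
  setNames(w / sum(w), codons)
}

#' Simulate a circular genome with planted ORFs, hr regions and a variant plan
#'
#' Background sequence is drawn i.i.d. at the target G+C. ORFs are planted
#' as ATG + stop-free interior codons + stop on random strands; repeat
#' units are planted by mutating the variable positions of the 48-bp
#' consensus per the hr plan. Feature blocks are packed left to right in a
#' shuffled order with at least 1500 nt between blocks (so distinct hr
#' regions never fall within the 1000-nt clustering gap of one another);
#' infeasible packing is an error. The variant plan assigns positions,
#' alternate alleles and frequencies but does not alter the reference
#' sequence; variants materialize in [simulate_pileup()].
#'
#' @param cfg a [genome_sim_config()].
#' @return list: `genome` (a [circular_genome()]) and `truth` (list with
#'   `orfs`, `hr_units`, `hr_copy_counts`, `variants`, `seed`).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$length
  g <- sample(DNA_BASES, L, replace = TRUE, prob = base_probs(cfg$gc))

  # plan blocks -------------------------------------------------------------
  blocks <- list()
  if (cfg$n_orfs > 0L) {
    n_cod <- sample(seq(cfg$orf_codon_range[1], cfg$orf_codon_range[2]),
                    cfg$n_orfs, replace = TRUE)
    for (i in seq_len(cfg$n_orfs))
      blocks[[length(blocks) + 1L]] <-
        list(type = "orf", id = sprintf("P%02d", i), n_codons = n_cod[i],
             span = 3L * (n_cod[i] + 1L), strand = sample(c("+", "-"), 1L))
  }
  if (!is.null(cfg$hr_plan)) {
    for (i in seq_len(nrow(cfg$hr_plan))) {
      nc <- cfg$hr_plan$copies[i]
      gaps <- if (nc > 1L) sample(30:150, nc - 1L, replace = TRUE) else integer(0)
      blocks[[length(blocks) + 1L]] <-
        list(type = "hr", id = sprintf("HR%d", i), copies = nc, gaps = gaps,
             mut_prob = cfg$hr_plan$mut_prob[i],
             span = 48L * nc + sum(gaps))
    }
  }
  min_gap <- 1500L
  total_span <- sum(vapply(blocks, `[[`, numeric(1), "span"))
  n_b <- length(blocks)
  slack <- L - total_span - (n_b + 1L) * min_gap
  if (slack < 0L) stopf("simulate_genome: infeasible packing (need %d nt more)", -slack)
  blocks <- blocks[sample.int(n_b)]
  gaps <- min_gap + tabulate(sample.int(n_b + 1L, slack, replace = TRUE), n_b + 1L)

  # write blocks ------------------------------------------------------------
  cons_ch <- strsplit(toupper(hr_consensus()), "")[[1]]
  lower_idx <- setdiff(seq_len(48L), degenerate_consensus()$strict_positions)
  codon_p <- nonstop_codon_probs(cfg$gc)
  codon_names <- names(codon_p)
  orf_rows <- list(); hr_rows <- list()
  cursor <- 1L
  for (bi in seq_len(n_b)) {
    cursor <- cursor + gaps[bi]
    b <- blocks[[bi]]
    if (b$type == "orf") {
      interior <- sample(codon_names, b$n_codons - 1L, replace = TRUE, prob = codon_p)
      orf_seq <- paste0("ATG", paste(interior, collapse = ""),
                        sample(STOP_CODONS, 1L))
      s <- cursor; e <- cursor + b$span - 1L
      placed <- if (b$strand == "+") orf_seq else reverse_complement(orf_seq)
      g[s:e] <- strsplit(placed, "")[[1]]
      prot <- paste(c("M", unname(Biostrings::GENETIC_CODE[interior])), collapse = "")
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        planted_id = b$id, istart = s, iend = e, strand = b$strand,
        n_codons = b$n_codons,
        start = if (b$strand == "+") s else e,
        end = if (b$strand == "+") e else s,
        protein = prot, stringsAsFactors = FALSE)
    } else {
      pos <- cursor
      for (ci in seq_len(b$copies)) {
        unit <- cons_ch
        mut <- lower_idx[runif(length(lower_idx)) < b$mut_prob]
        for (mi in mut)
          unit[mi] <- sample(setdiff(DNA_BASES, unit[mi]), 1L)
        g[pos:(pos + 47L)] <- unit
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          region = b$id, copy = ci, position = pos, n_mut = length(mut),
          stringsAsFactors = FALSE)
        pos <- pos + 48L + if (ci < b$copies) b$gaps[ci] else 0L
      }
    }
    cursor <- cursor + b$span
  }

  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else NULL
  hr_units <- if (length(hr_rows)) do.call(rbind, hr_rows) else NULL

  # variant plan ------------------------------------------------------------
  variants <- NULL
  if (!is.null(cfg$snp_plan)) {
    sp <- cfg$snp_plan
    fixed <- sp$fixed
    if (any(fixed$position > L)) stopf("fixed variant position beyond genome end")
    used <- fixed$position
    n_rand <- length(sp$extra_high) + sp$n_bulk_snps + sp$n_ins + sp$n_del
    rand_pos <- sample(setdiff(seq_len(L), used), n_rand)
    freqs <- c(fixed$freq, sp$extra_high,
               round(runif(sp$n_bulk_snps, sp$bulk_range[1], sp$bulk_range[2]), 2),
               round(runif(sp$n_ins + sp$n_del, sp$indel_range[1], sp$indel_range[2]), 2))
    pos_all <- c(fixed$position, rand_pos)
    n_snp <- nrow(fixed) + length(sp$extra_high) + sp$n_bulk_snps
    kind <- c(rep("SNP", n_snp), rep("insertion", sp$n_ins), rep("deletion", sp$n_del))
    ref <- g[pos_all]
    alt <- character(length(pos_all)); len <- integer(length(pos_all))
    for (i in seq_along(pos_all)) {
      if (kind[i] == "SNP") {
        alt[i] <- sample(setdiff(DNA_BASES, ref[i]), 1L); len[i] <- 1L
      } else if (kind[i] == "insertion") {
        len[i] <- sample(seq_len(sp$max_indel_len), 1L)
        alt[i] <- paste(sample(DNA_BASES, len[i], replace = TRUE), collapse = "")
      } else {
        len[i] <- sample(seq_len(sp$max_indel_len), 1L)
        alt[i] <- "-"
      }
    }
    variants <- data.frame(position = pos_all, kind = kind, ref = ref, alt = alt,
                           len = len, freq = freqs, stringsAsFactors = FALSE)
    variants <- variants[order(variants$position), , drop = FALSE]
    rownames(variants) <- NULL
  }

  genome <- circular_genome(paste(g, collapse = ""), id = sprintf("synthetic_seed%d", cfg$seed))
  truth <- list(orfs = orfs, hr_units = hr_units,
                hr_copy_counts = if (is.null(cfg$hr_plan)) integer(0) else cfg$hr_plan$copies,
                variants = variants, seed = cfg$seed)
  list(genome = genome, truth = truth)
}

#' Simulate a read pileup over a genome carrying planted variants
#'
#' Per position, depth is Poisson around the mean; alternate-allele reads
#' are binomial at the planted frequency; uniform sequencing errors are
#' spread over the three non-reference bases. Insertion/deletion reads are
#' recorded in the `ins`/`del` columns (`SEQ:count` / `LEN:count`); the
#' denominator for every allele is the column depth.
#'
#' @param genome reference [circular_genome()].
#' @param truth truth list from [simulate_genome()] (its `variants` table
#'   drives the alternate alleles; NULL plants nothing).
#' @param depth mean coverage (default 941).
#' @param error_rate per-base error rate (default 0.001).
#' @param seed RNG seed.
#' @return pileup data.frame (see [read_pileup()] for the format).
#' @export
simulate_pileup <- function(genome, truth = NULL, depth = 941,
                            error_rate = 0.001, seed = 1L) {
  set.seed(seed)
  L <- genome$length
  ref <- strsplit(genome$sequence, "")[[1]]
  ref_idx <- match(ref, DNA_BASES)
  dep <- rpois(L, depth)

  snp_alt <- integer(L); del_cnt <- integer(L)
  ins_str <- character(L); del_str <- character(L)
  alt_base_idx <- integer(0); alt_pos <- integer(0)
  if (!is.null(truth) && !is.null(truth$variants) && nrow(truth$variants) > 0L) {
    v <- truth$variants
    for (i in seq_len(nrow(v))) {
      p <- v$position[i]
      n_alt <- rbinom(1L, dep[p], v$freq[i] / 100)
      if (v$kind[i] == "SNP") {
        snp_alt[p] <- n_alt
        alt_pos <- c(alt_pos, p)
        alt_base_idx <- c(alt_base_idx, match(v$alt[i], DNA_BASES))
      } else if (v$kind[i] == "insertion") {
        if (n_alt > 0L) ins_str[p] <- sprintf("%s:%d", v$alt[i], n_alt)
      } else {
        del_cnt[p] <- n_alt
        if (n_alt > 0L) del_str[p] <- sprintf("%d:%d", v$len[i], n_alt)
      }
    }
  }

  avail <- pmax(dep - snp_alt, 0L)
  err_n <- rbinom(L, avail, error_rate)
  e1 <- rbinom(L, err_n, 1 / 3)
  e2 <- rbinom(L, err_n - e1, 1 / 2)
  e3 <- err_n - e1 - e2
  # the three non-reference base columns, in sorted order
  oth1 <- ifelse(ref_idx == 1L, 2L, 1L)
  oth2 <- ifelse(ref_idx <= 2L, 3L, 2L)
  oth3 <- ifelse(ref_idx == 4L, 3L, 4L)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, DNA_BASES))
  idx <- seq_len(L)
  counts[cbind(idx, oth1)] <- e1
  counts[cbind(idx, oth2)] <- counts[cbind(idx, oth2)] + e2
  counts[cbind(idx, oth3)] <- counts[cbind(idx, oth3)] + e3
  if (length(alt_pos))
    counts[cbind(alt_pos, alt_base_idx)] <- counts[cbind(alt_pos, alt_base_idx)] + snp_alt[alt_pos]
  ref_count <- pmax(dep - rowSums(counts) - del_cnt, 0L)
  counts[cbind(idx, ref_idx)] <- counts[cbind(idx, ref_idx)] + ref_count

  data.frame(position = idx, ref = ref, depth = dep,
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
             ins = ins_str, del = del_str, stringsAsFactors = FALSE)
}

#' Evolve a gap-free amino-acid alignment along a tree
#'
#' The root sequence is uniform over the 20 amino acids; substitution
#' events are placed along each branch as a Poisson process at the
#' branch-length rate (expected events per site), each event replacing the
#' residue with one of the 19 alternatives, uniformly. With a finite
#' 20-letter alphabet the expected leaf-pair difference over a path of
#' length t is (19/20)(1 - exp(-20 t / 19)), slightly below the idealized
#' 1 - exp(-t) of the Poisson correction; the discrepancy matters only at
#' large distances (see the methods vignette).
#'
#' @param tree `phylo` with branch lengths.
#' @param n_sites alignment columns.
#' @param seed RNG seed.
#' @param gene gene label for the returned alignment.
#' @return a [gene_alignment()] with one gap-free row per tip.
#' @export
evolve_alignment <- function(tree, n_sites, seed = 1L, gene = "gene") {
  set.seed(seed)
  if (is.null(tree$edge.length)) stopf("evolve_alignment: tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(NA_integer_, n_tip + tree$Nnode, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE)
  for (ei in seq_len(nrow(tree$edge))) {
    par <- tree$edge[ei, 1L]; child <- tree$edge[ei, 2L]
    s <- states[par, ]
    k <- rpois(n_sites, tree$edge.length[ei])
    for (site in which(k > 0L)) {
      cur <- s[site]
      for (j in seq_len(k[site])) {
        r <- sample.int(19L, 1L)
        cur <- r + (r >= cur)
      }
      s[site] <- cur
    }
    states[child, ] <- s
  }
  rows <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                function(x) paste(AA20[x], collapse = ""))
  gene_alignment(setNames(rows, tree$tip.label), gene = gene)
}

#' Simulate a set of core-gene alignments on one tree
#'
#' Splits `total_sites` as evenly as possible over `n_genes` genes and
#' evolves each independently on the same tree (seeds derived from `seed`).
#'
#' @param tree `phylo` with branch lengths.
#' @param n_genes number of genes (default 38, the core-gene count).
#' @param total_sites total concatenated columns (default 5000).
#' @param seed RNG seed.
#' @return list of [gene_alignment()] objects.
#' @export
simulate_core_gene_alignments <- function(tree, n_genes = 38L, total_sites = 5000L,
                                          seed = 1L) {
  base_len <- total_sites %/% n_genes
  lens <- rep(base_len, n_genes)
  extra <- total_sites - base_len * n_genes
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  lapply(seq_len(n_genes), function(i) {
    evolve_alignment(tree, lens[i], seed = (seed * 1000L + i) %% .Machine$integer.max,
                     gene = sprintf("gene%02d", i))
  })
}

#' Serialize / reload a ground-truth object as JSON
#' @param truth truth list from [simulate_genome()].
#' @param path JSON file.
#' @export
save_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_truth
#' @export
load_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("orfs", "hr_units", "variants"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  x
}
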