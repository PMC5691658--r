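# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (per-position walks, exhaustive enumeration,
# closed forms) so it shares no code path with the implementation.

# --- six-frame ORF oracle: walk codon-by-codon from every position --------
oracle_find_orfs <- function(genome, min_codons = 50L, start_codons = "ATG") {
  L <- genome$length
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else reverse_complement(genome$sequence)
    ch <- strsplit(s, "")[[1]]
    codon_at <- function(p) {
      idx <- ((p - 1L + 0:2) %% L) + 1L
      paste(ch[idx], collapse = "")
    }
    max_steps <- L %/% 3L
    by_stop <- list()  # stop position -> best (most upstream) start
    for (p in seq_len(L)) {
      if (!(codon_at(p) %in% start_codons)) next
      q <- p; steps <- 0L; stop_at <- NA_integer_
      while (steps < max_steps) {
        q2 <- ((q + 3L - 1L) %% L) + 1L
        steps <- steps + 1L
        if (codon_at(q2) %in% c("TAA", "TAG", "TGA")) { stop_at <- q2; break }
        q <- q2
      }
      if (is.na(stop_at)) next          # unterminated (wraps into itself)
      n_cod <- steps
      if (3L * (n_cod + 1L) > L) next   # self-overlapping on the circle
      key <- as.character(stop_at)
      if (is.null(by_stop[[key]]) || by_stop[[key]]$n_codons < n_cod)
        by_stop[[key]] <- list(a = p, n_codons = n_cod, stop_at = stop_at)
    }
    for (o in by_stop) {
      if (o$n_codons < min_codons) next
      e_loc <- ((o$stop_at + 2L - 1L) %% L) + 1L
      if (strand == "+") {
        res[[length(res) + 1L]] <- data.frame(
          start = o$a, end = e_loc, strand = strand, n_codons = o$n_codons)
      } else {
        res[[length(res) + 1L]] <- data.frame(
          start = L - o$a + 1L, end = L - e_loc + 1L, strand = strand,
          n_codons = o$n_codons)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_codons = integer(0)))
  df <- do.call(rbind, res)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

orf_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%d:%d:%s:%d", df$start, df$end, df$strand, df$n_codons))
}

# linear variant: no wrap anywhere
oracle_find_orfs_linear <- function(genome, min_codons = 50L, start_codons = "ATG") {
  L <- genome$length
  ch <- strsplit(genome$sequence, "")[[1]]
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") ch else strsplit(reverse_complement(genome$sequence), "")[[1]]
    codon_at <- function(p) paste(s[p:(p + 2L)], collapse = "")
    by_stop <- list()
    for (p in seq_len(max(L - 2L, 0L))) {
      if (!(codon_at(p) %in% start_codons)) next
      q <- p + 3L; n_cod <- 0L; stop_at <- NA_integer_
      while (q + 2L <= L) {
        n_cod <- n_cod + 1L
        if (codon_at(q) %in% c("TAA", "TAG", "TGA")) { stop_at <- q; break }
        q <- q + 3L
      }
      if (is.na(stop_at)) next
      key <- as.character(stop_at)
      if (is.null(by_stop[[key]]) || by_stop[[key]]$n_codons < n_cod)
        by_stop[[key]] <- list(a = p, n_codons = n_cod, stop_at = stop_at)
    }
    for (o in by_stop) {
      if (o$n_codons < min_codons) next
      e_loc <- o$stop_at + 2L
      if (strand == "+") {
        res[[length(res) + 1L]] <- data.frame(
          start = o$a, end = e_loc, strand = strand, n_codons = o$n_codons)
      } else {
        res[[length(res) + 1L]] <- data.frame(
          start = L - o$a + 1L, end = L - e_loc + 1L, strand = strand,
          n_codons = o$n_codons)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_codons = integer(0)))
  do.call(rbind, res)
}

# --- random genome helper -------------------------------------------------
random_genome <- function(len, gc = 0.4, topology = "circular") {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  circular_genome(paste(sample(c("A", "C", "G", "T"), len, TRUE, p), collapse = ""),
                  topology = topology)
}

# --- exhaustive global alignment score (affine gaps) ----------------------
# enumerates every monotone alignment path and scores it in full;
# a length-k gap run costs open + k * extend
oracle_align_score <- function(a, b, scheme) {
  sm <- baculokit:::scheme_subst_matrix(scheme)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  score_path <- function(moves) {
    i <- 0L; j <- 0L; sc <- 0; run <- ""
    for (m in moves) {
      if (m == "D") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + sm[ca[i], cb[j]]; run <- ""
      } else {
        if (m != run) sc <- sc - scheme$gap_open
        sc <- sc - scheme$gap_extend
        if (m == "U") i <- i + 1L else j <- j + 1L
        run <- m
      }
    }
    sc
  }
  recurse <- function(i, j, moves) {
    if (i == length(ca) && j == length(cb)) {
      s <- score_path(moves)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) recurse(i + 1L, j + 1L, c(moves, "D"))
    if (i < length(ca)) recurse(i + 1L, j, c(moves, "U"))
    if (j < length(cb)) recurse(i, j + 1L, c(moves, "L"))
  }
  recurse(0L, 0L, character(0))
  best
}

# --- exhaustive additive-topology search ----------------------------------
# path-edge incidence design matrix of a phylo tree; least-squares fit of
# branch lengths to a distance vector identifies the additive topology
# (residual ~ 0) among all unrooted topologies
edge_design <- function(tree) {
  ntip <- length(tree$tip.label)
  par <- rep(NA_integer_, max(tree$edge)); eidx <- integer(max(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    par[tree$edge[k, 2]] <- tree$edge[k, 1]; eidx[tree$edge[k, 2]] <- k
  }
  root_path <- function(v) {
    out <- integer(0)
    while (!is.na(par[v])) { out <- c(out, eidx[v]); v <- par[v] }
    out
  }
  paths <- lapply(seq_len(ntip), root_path)
  pairs <- t(combn(ntip, 2))
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (r in seq_len(nrow(pairs))) {
    sdiff <- c(setdiff(paths[[pairs[r, 1]]], paths[[pairs[r, 2]]]),
               setdiff(paths[[pairs[r, 2]]], paths[[pairs[r, 1]]]))
    X[r, sdiff] <- 1
  }
  X
}

# best topology for a distance matrix by exhaustive least squares
oracle_best_topology <- function(d) {
  labs <- rownames(d)
  tl <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  dvec <- as.vector(as.dist(d[labs, labs]))
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(tl)) {
    cand <- tl[[ti]]
    fit <- lm.fit(edge_design(cand), dvec)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- cand }
  }
  list(tree = best, rss = best_rss)
}

# random tree with strictly positive branch lengths and its additive matrix
random_additive_matrix <- function(n, min_bl = 0.15, max_bl = 1.5) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  labs <- paste0("t", seq_len(n))
  list(tree = tr, d = ape::cophenetic.phylo(tr)[labs, labs])
}

# balanced 10-taxon tree with two well-separated 5-taxon clades
deep_split_tree <- function() {
  nwk <- paste0(
    "(((A:0.15,B:0.15):0.12,(C:0.15,D:0.15):0.12):0.1,E:0.25,",
    "(((F:0.15,G:0.15):0.12,(H:0.15,I:0.15):0.12):0.1,J:0.25):0.5);")
  ape::read.tree(text = nwk)
}
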