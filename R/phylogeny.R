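#' Build a per-gene alignment object
#'
#' @param rows named character vector (taxon -> gapped amino-acid row),
#'   all rows the same length; gap character `-`.
#' @param gene gene name.
#' @return list of class `gene_alignment`: `gene`, `taxa`, `rows`, `length`.
#' @export
gene_alignment <- function(rows, gene = "gene") {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) stopf("rows must be named by taxon")
  if (anyDuplicated(names(rows))) stopf("duplicate taxa in alignment '%s'", gene)
  lens <- unique(nchar(rows))
  if (length(lens) != 1L) stopf("alignment '%s': rows have unequal lengths", gene)
  structure(list(gene = gene, taxa = names(rows), rows = toupper(rows), length = lens),
            class = "gene_alignment")
}

#' Read one gene alignment from FASTA
#'
#' @param path aligned FASTA.
#' @param gene gene name (default: file name without extension).
#' @return a [gene_alignment()].
#' @export
read_alignment_fasta <- function(path, gene = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readAAStringSet(path)
  gene_alignment(setNames(as.character(ss), sub("\\s.*$", "", names(ss))), gene = gene)
}

#' Concatenate per-gene alignments into a superalignment
#'
#' Every alignment must contain exactly the same taxon set (no silent
#' gap-filling). Rows are joined per taxon in gene order; a partition table
#' records each gene's 1-based inclusive column range.
#'
#' @param alignments list of [gene_alignment()] objects.
#' @return list of class `superalignment`: `taxa`, `rows`, `length`,
#'   `partitions` (data.frame gene/first/last).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(alignments[[1L]]$taxa)
  for (al in alignments) {
    if (!setequal(al$taxa, taxa)) {
      off <- c(setdiff(al$taxa, taxa), setdiff(taxa, al$taxa))
      stopf("alignment '%s': taxon set mismatch (%s)", al$gene,
            paste(off, collapse = ", "))
    }
  }
  taxa <- alignments[[1L]]$taxa
  rows <- setNames(rep("", length(taxa)), taxa)
  first <- integer(0); last <- integer(0); pos <- 0L
  for (al in alignments) {
    rows[taxa] <- paste0(rows[taxa], al$rows[taxa])
    first <- c(first, pos + 1L); last <- c(last, pos + al$length)
    pos <- pos + al$length
  }
  structure(list(taxa = taxa, rows = rows, length = pos,
                 partitions = data.frame(
                   gene = vapply(alignments, `[[`, character(1), "gene"),
                   first = first, last = last)),
            class = "superalignment")
}

#' Pairwise p-distance with pairwise deletion of gaps
#'
#' Fraction of differing residue pairs over the columns where both rows are
#' non-gap (pairwise deletion, never complete deletion).
#'
#' @param row_a,row_b gapped strings of equal length.
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(row_a, row_b) {
  a <- strsplit(row_a, "")[[1]]; b <- strsplit(row_b, "")[[1]]
  if (length(a) != length(b)) stopf("p_distance: rows have unequal lengths")
  ok <- a != "-" & b != "-"
  if (!any(ok)) stopf("p_distance: zero comparable columns")
  mean(a[ok] != b[ok])
}

#' Evolutionary distance from a p-distance
#'
#' `p` is the identity transform; `poisson` is -ln(1-p) (multiple-hit
#' correction); `gamma` is a((1-p)^(-1/a) - 1) with shape a, the
#' rate-variation-corrected form (converging to poisson as a grows).
#' All are monotone increasing in p.
#'
#' @param p p-distance(s), in \[0, 1).
#' @param model `"p"`, `"poisson"` or `"gamma"`.
#' @param gamma_shape shape parameter a (required for the gamma model).
#' @return corrected distance(s).
#' @export
model_distance <- function(p, model = c("p", "poisson", "gamma"), gamma_shape = 1.0) {
  model <- match.arg(model)
  if (any(p < 0)) stopf("model_distance: negative p")
  if (model != "p" && any(p >= 1))
    stopf("model_distance: saturated pair (p >= 1 under the %s model)", model)
  switch(model,
         p = p,
         poisson = -log(1 - p),
         gamma = {
           if (!is.numeric(gamma_shape) || gamma_shape <= 0)
             stopf("gamma model requires a positive gamma_shape")
           gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
         })
}

#' Pairwise distance matrix of a superalignment
#'
#' @param super a [concatenate_alignments()] superalignment (or any set of
#'   equal-length gapped rows).
#' @param model,gamma_shape passed to [model_distance()].
#' @return symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(super, model = "poisson", gamma_shape = 1.0) {
  m <- do.call(rbind, strsplit(unname(super$rows), ""))
  rownames(m) <- super$taxa
  dist_from_charmat(m, seq_len(ncol(m)), model, gamma_shape)
}

# distance matrix from a character matrix restricted to column index set idx
dist_from_charmat <- function(m, idx, model, gamma_shape) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sub <- m[, idx, drop = FALSE]
  gap <- sub == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stopf("zero comparable columns between %s and %s",
                        rownames(m)[i], rownames(m)[j])
    p <- mean(sub[i, ok] != sub[j, ok])
    d[i, j] <- d[j, i] <- model_distance(p, model, gamma_shape)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (the greedy heuristic for minimum-evolution
#' phylogenetics). Negative branch lengths are clamped to zero with a
#' warning. The tree is unrooted.
#'
#' @param d symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return an [ape::nj()] `phylo` object.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("nj_tree needs >= 3 taxa")
  if (any(!is.finite(d))) stopf("nj_tree: non-finite distance entries")
  if (max(abs(d - t(d))) > 1e-8) stopf("nj_tree: matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warnf("nj_tree: %d negative branch length(s) clamped to 0",
          sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Newick serialization
#' @param tree a `phylo` object.
#' @param digits branch-length digits (default 6, fixed for diffability).
#' @return Newick string.
#' @export
tree_newick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}

#' Point-estimate NJ tree with bootstrap supports
#'
#' Resamples superalignment columns with replacement (`n_reps` replicates
#' over the full concatenated length), rebuilds the distance matrix and NJ
#' tree per replicate, and labels each internal edge of the point-estimate
#' tree with the percentage of replicate trees containing the same
#' bipartition. Replicates producing a saturated or undefined distance are
#' dropped and counted; more than 10% dropped is an error. Seeded and
#' reproducible; trivial (leaf) bipartitions carry no support.
#'
#' @param super superalignment.
#' @param model,gamma_shape distance model.
#' @param n_reps bootstrap replicates (default 500; 0 = point estimate only).
#' @param seed RNG seed.
#' @return `phylo` with `node.label` holding supports in percent (root label
#'   empty); `attr(, "n_dropped")` counts dropped replicates.
#' @export
bootstrap_support <- function(super, model = "poisson", gamma_shape = 1.0,
                              n_reps = 500L, seed = 1L) {
  m <- do.call(rbind, strsplit(unname(super$rows), ""))
  rownames(m) <- super$taxa
  ncol_full <- ncol(m)
  point <- nj_tree(dist_from_charmat(m, seq_len(ncol_full), model, gamma_shape))
  if (n_reps == 0L) return(structure(point, n_dropped = 0L))
  set.seed(seed)
  reps <- vector("list", n_reps)
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol_full, ncol_full, replace = TRUE)
    tr <- tryCatch(
      suppressWarnings(nj_tree(dist_from_charmat(m, idx, model, gamma_shape))),
      error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else reps[[r]] <- tr
  }
  if (dropped > 0.10 * n_reps)
    stopf("bootstrap_support: %d of %d replicates dropped (saturated distances)",
          dropped, n_reps)
  reps <- reps[!vapply(reps, is.null, logical(1))]
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(supp)
  point$node.label[1L] <- ""   # root of the unrooted representation: trivial
  structure(point, n_dropped = dropped)
}

#' Bootstrap support of one bipartition
#'
#' @param tree `phylo` with supports in `node.label` (from
#'   [bootstrap_support()]).
#' @param taxa character vector: one side of the bipartition.
#' @return support percent, or NA if the point-estimate tree lacks the
#'   bipartition.
#' @export
bipartition_support <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  want <- sort(match(taxa, tree$tip.label))
  if (any(is.na(want))) stopf("unknown taxa in bipartition")
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    tips <- sort(unlist(phangorn_free_descendants(tree, node)))
    if (identical(tips, want) || identical(sort(setdiff(seq_len(n_tip), tips)), want)) {
      lab <- tree$node.label[node - n_tip]
      return(if (is.null(lab) || !nzchar(lab)) NA_real_ else as.numeric(lab))
    }
  }
  NA_real_
}

# tips descending from an internal node (simple recursion; avoids a
# dependency on phangorn for this one lookup)
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k)
    if (k <= n_tip) k else phangorn_free_descendants(tree, k)))
}
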