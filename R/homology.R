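#' Alignment scoring scheme
#'
#' Defaults follow community practice: BLOSUM62 with gap open 11 / extend 1
#' for proteins; match +2 / mismatch -3 with gap open 5 / extend 2 for
#' nucleotides. Gap penalties are magnitudes; a gap of length k costs
#' open + k * extend.
#'
#' @param type `"protein"` or `"dna"`.
#' @param matrix_name protein substitution matrix (protein type only).
#' @param match,mismatch nucleotide scores (dna type only).
#' @param gap_open,gap_extend affine gap penalties (magnitudes).
#' @return scoring scheme list.
#' @export
scoring_scheme <- function(type = c("protein", "dna"), matrix_name = "BLOSUM62",
                           match = 2, mismatch = -3,
                           gap_open = if (match.arg(type) == "protein") 11 else 5,
                           gap_extend = if (match.arg(type) == "protein") 1 else 2) {
  type <- match.arg(type)
  if (gap_open < 0 || gap_extend < 0) stopf("gap penalties are magnitudes (>= 0)")
  structure(list(type = type, matrix_name = matrix_name, match = match,
                 mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

scheme_subst_matrix <- function(scheme) {
  if (scheme$type == "protein") {
    e <- new.env()
    utils::data(list = scheme$matrix_name, package = "Biostrings", envir = e)
    get(scheme$matrix_name, envir = e)
  } else {
    m <- matrix(scheme$mismatch, 5, 5,
                dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
    diag(m) <- scheme$match
    m["N", ] <- 0; m[, "N"] <- 0
    m
  }
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch-Gotoh global alignment via
#' [Biostrings::pairwiseAlignment()]. Identity is computed from the aligned
#' strings under the chosen denominator policy (see [percent_identity()]).
#'
#' @param a,b sequences (character strings) over a consistent alphabet.
#' @param scheme a [scoring_scheme()].
#' @param policy identity denominator policy, passed to [percent_identity()].
#' @return list: `aligned_a`, `aligned_b` (gapped, equal length), `score`,
#'   `identity_pct`, `columns_counted`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme("protein"),
                         policy = c("excl_terminal_gaps", "aligned_columns")) {
  policy <- match.arg(policy)
  if (!nzchar(a) || !nzchar(b)) stopf("global_align: empty sequence")
  if (scheme$type == "dna" && (grepl("[^ACGTN]", toupper(a)) || grepl("[^ACGTN]", toupper(b))))
    stopf("global_align: non-nucleotide character under a dna scoring scheme")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = scheme_subst_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  aa <- as.character(Biostrings::alignedPattern(aln))
  bb <- as.character(Biostrings::alignedSubject(aln))
  id <- percent_identity(aa, bb, policy)
  list(aligned_a = aa, aligned_b = bb, score = Biostrings::score(aln),
       identity_pct = id$identity_pct, columns_counted = id$columns_counted)
}

#' Percent identity of an alignment
#'
#' Identical residue pairs divided by counted columns, times 100. Under the
#' default `excl_terminal_gaps` policy, leading and trailing gap columns
#' (overhangs of either sequence) are excluded, so a partial sequence is
#' compared over its overlap with the full one; under `aligned_columns`
#' every column counts.
#'
#' @param aligned_a,aligned_b gapped strings of equal length (gap = `-`).
#' @param policy denominator policy.
#' @return list: `identity_pct` (rounded to 2 decimals), `columns_counted`.
#' @export
percent_identity <- function(aligned_a, aligned_b,
                             policy = c("excl_terminal_gaps", "aligned_columns")) {
  policy <- match.arg(policy)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  if (length(ca) != length(cb)) stopf("aligned strings have unequal lengths")
  n <- length(ca)
  keep <- rep(TRUE, n)
  if (policy == "excl_terminal_gaps") {
    res_a <- which(ca != "-"); res_b <- which(cb != "-")
    lo <- max(min(res_a), min(res_b)); hi <- min(max(res_a), max(res_b))
    keep <- seq_len(n) >= lo & seq_len(n) <= hi
  }
  if (!any(keep)) stopf("percent_identity: zero counted columns")
  list(identity_pct = round(100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep), 2),
       columns_counted = sum(keep))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' The packaged synthetic core-gene reference proteome
#'
#' Loads the 38-entry reference protein set used by the core-gene inventory.
#' The sequences shipped with the package are synthetic stand-ins
#' (deterministically generated, labelled with the field's standard
#' baculovirus core-gene symbols); swap in a real group II alphabaculovirus
#' proteome via the `path` argument for accession-based work.
#'
#' @param path FASTA of reference proteins, named by core-gene symbol.
#' @return named character vector of 38 reference sequences.
#' @export
load_core_refs <- function(path = system.file("extdata", "core_gene_refs_synthetic.faa",
                                              package = "baculokit")) {
  read_protein_fasta(path)
}

#' Inventory core genes in a proteome
#'
#' For each reference core gene, the best-identity ORF product under global
#' alignment is recorded; the gene counts as found iff that identity reaches
#' `floor` percent.
#'
#' @param proteins named character vector: ORF id -> amino-acid sequence.
#' @param reference_set named character vector: core-gene symbol ->
#'   reference amino-acid sequence (default: packaged set).
#' @param floor identity floor in percent for presence (default 15).
#' @param scheme protein scoring scheme.
#' @return data.frame: `core_gene`, `best_orf`, `identity_pct`, `found`;
#'   the number found is `sum(.$found)`.
#' @export
inventory_core_genes <- function(proteins, reference_set = load_core_refs(),
                                 floor = 15, scheme = scoring_scheme("protein")) {
  hits <- lapply(names(reference_set), function(g) {
    if (length(proteins) == 0L)
      return(data.frame(core_gene = g, best_orf = "", identity_pct = NA_real_,
                        found = FALSE, stringsAsFactors = FALSE))
    ids <- vapply(proteins, function(p)
      global_align(reference_set[[g]], p, scheme)$identity_pct, numeric(1))
    best <- which.max(ids)
    found <- ids[best] >= floor
    data.frame(core_gene = g,
               best_orf = if (found) names(proteins)[best] else "",
               identity_pct = unname(ids[best]), found = found,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

#' Min / max / median identity over found core-gene hits
#'
#' The median of an even count is the mean of the central pair.
#'
#' @param hits data.frame from [inventory_core_genes()].
#' @return list: `table` (gene, identity_pct for found hits), `min`, `max`,
#'   `median`.
#' @export
identity_summary <- function(hits) {
  f <- hits[hits$found, , drop = FALSE]
  if (nrow(f) == 0L) stopf("identity_summary: no found hits")
  list(table = f[, c("core_gene", "identity_pct")],
       min = min(f$identity_pct), max = max(f$identity_pct),
       median = median(f$identity_pct))
}
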