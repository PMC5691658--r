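#' Enumerate ORF candidates on both strands of a genome
#'
#' Scans all six reading frames. On circular genomes the scan continues
#' across the origin: reading frames are decomposed into circular codon
#' cycles (one cycle when the genome length is not divisible by 3, three
#' otherwise), so ORFs spanning the origin are found like any other. For
#' each stop codon the reported candidate is the longest start-to-stop ORF,
#' i.e. the most upstream in-frame start codon after the previous stop.
#'
#' Coordinates follow the transcription direction: `start` is the genome
#' position of the first nucleotide of the start codon and `end` the last
#' nucleotide of the stop codon, so `start > end` on minus-strand ORFs.
#' `istart`/`iend` give the plus-strand genomic footprint (istart > iend
#' only when the ORF wraps the origin). Codons containing N never match a
#' start or stop, and candidates whose span contains N are flagged
#' (`has_n`), not silently scored.
#'
#' @param genome a [circular_genome()].
#' @param min_codons minimum ORF size in codons, excluding the stop
#'   (default 50).
#' @param start_codons allowed start codons (default ATG only).
#' @return data.frame of candidates sorted by footprint start position, with
#'   columns `orf_id`, `start`, `end`, `strand`, `frame`, `n_codons`,
#'   `wraps`, `istart`, `iend`, `has_n`.
#' @export
find_orfs <- function(genome, min_codons = 50L, start_codons = "ATG") {
  stopifnot(inherits(genome, "circular_genome"), min_codons >= 1L)
  L <- genome$length
  if (L < 3L) return(empty_orf_df())
  out <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") genome$sequence else reverse_complement(genome$sequence)
    cands <- scan_strand_orfs(seq, circular = genome$topology == "circular",
                              min_codons = min_codons, start_codons = start_codons)
    if (nrow(cands) == 0L) next
    if (strand == "+") {
      cands$start <- cands$a; cands$end <- cands$e
      cands$istart <- cands$a; cands$iend <- cands$e
    } else {
      cands$start <- L - cands$a + 1L; cands$end <- L - cands$e + 1L
      cands$istart <- L - cands$e + 1L; cands$iend <- L - cands$a + 1L
    }
    cands$strand <- strand
    out[[strand]] <- cands
  }
  if (length(out) == 0L) return(empty_orf_df())
  df <- do.call(rbind, out)
  df$wraps <- df$istart > df$iend
  df$frame <- (df$istart - 1L) %% 3L
  df <- df[order(df$istart, df$iend, df$strand), , drop = FALSE]
  df$orf_id <- sprintf("ORF%d", seq_len(nrow(df)))
  df$has_n <- vapply(seq_len(nrow(df)), function(i) {
    grepl("N", extract_subseq(genome, df$istart[i], df$iend[i]), fixed = TRUE)
  }, logical(1))
  rownames(df) <- NULL
  df[, c("orf_id", "start", "end", "strand", "frame", "n_codons",
         "wraps", "istart", "iend", "has_n")]
}

empty_orf_df <- function() {
  data.frame(orf_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0), n_codons = integer(0),
             wraps = logical(0), istart = integer(0), iend = integer(0),
             has_n = logical(0), stringsAsFactors = FALSE)
}

# ORFs in strand-local coordinates: columns a (first nt of start codon),
# e (last nt of stop codon, wrapped), n_codons
scan_strand_orfs <- function(seq, circular, min_codons, start_codons) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (circular) {
    c2 <- ch[c(2:L, 1L)]; c3 <- ch[c(3:L, 1L, 2L)]
  } else {
    c2 <- c(ch[-1L], "N"); c3 <- c(ch[-(1:2)], "N", "N")
  }
  codon <- paste0(ch, c2, c3)          # codon starting at each position
  is_stop <- codon %in% STOP_CODONS
  is_start <- codon %in% start_codons
  res_a <- integer(0); res_e <- integer(0); res_n <- integer(0)
  n_cycles <- if (circular && L %% 3L == 0L) 3L else if (circular) 1L else 3L
  for (f in seq_len(n_cycles)) {
    if (circular) {
      cyclen <- L %/% n_cycles
      cyc <- ((f - 1L + 3L * (seq_len(cyclen) - 1L)) %% L) + 1L
    } else {
      cyc <- seq.int(f, L - 2L, by = 3L)
      if (length(cyc) == 0L) next
      cyclen <- length(cyc)
    }
    stops <- which(is_stop[cyc])
    starts <- which(is_start[cyc])
    if (length(stops) == 0L || length(starts) == 0L) next
    for (k in seq_along(stops)) {
      s_i <- stops[k]
      prev <- if (circular) stops[if (k == 1L) length(stops) else k - 1L]
              else if (k == 1L) 0L else stops[k - 1L]
      # first start codon strictly after prev and before s_i (cyclic for circular)
      if (circular) {
        seg_len <- (s_i - prev - 1L) %% cyclen
        if (seg_len == 0L) next
        d <- (starts - prev) %% cyclen       # forward distance from prev
        n_from <- (s_i - starts) %% cyclen   # would-be n_codons per start
        # span on the circle is 3*(n_codons+1); an ORF cannot overlap itself
        ok <- d >= 1L & d <= seg_len & 3L * (n_from + 1L) <= L
        if (!any(ok)) next
        a_idx <- starts[ok][which.min(d[ok])]
        n_cod <- (s_i - a_idx) %% cyclen
      } else {
        ok <- starts > prev & starts < s_i
        if (!any(ok)) next
        a_idx <- min(starts[ok])
        n_cod <- s_i - a_idx
      }
      if (n_cod < min_codons) next
      a <- cyc[a_idx]
      e <- ((cyc[s_i] + 2L - 1L) %% L) + 1L   # last nt of stop codon
      res_a <- c(res_a, a); res_e <- c(res_e, e); res_n <- c(res_n, n_cod)
    }
  }
  data.frame(a = res_a, e = res_e, n_codons = res_n)
}

#' Translate an ORF candidate to protein
#'
#' Standard genetic code (translation table 1); the stop codon is excluded.
#' Codons containing N translate to X.
#'
#' @param genome the [circular_genome()].
#' @param orf one row of a [find_orfs()] data.frame.
#' @return amino-acid string of length `n_codons`.
#' @export
orf_protein <- function(genome, orf) {
  nt <- extract_subseq(genome, orf$istart, orf$iend, strand = orf$strand)
  nt <- substr(nt, 1L, 3L * orf$n_codons)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- unname(gc_tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Read an ORF evidence table
#'
#' Tab-separated columns: `orf_id`, `best_subject`, `best_identity`,
#' `evalue`, `fgenes`, `zcurve`. Homology support (`has_homology`) requires a
#' non-empty subject with E-value at or below `evalue_max`.
#'
#' @param path TSV file.
#' @param evalue_max significance cutoff on the tabulated E-value
#'   (default 1e-5).
#' @return data.frame with columns `orf_id`, `has_homology`, `best_subject`,
#'   `best_identity`, `fgenes_pred`, `zcurve_pred`.
#' @export
read_evidence_tsv <- function(path, evalue_max = 1e-5) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "best_subject", "best_identity", "evalue", "fgenes", "zcurve")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("evidence TSV missing column(s): %s", paste(miss, collapse = ", "))
  data.frame(
    orf_id = df$orf_id,
    has_homology = !is.na(df$best_subject) & nzchar(df$best_subject) &
      !is.na(df$evalue) & df$evalue <= evalue_max,
    best_subject = ifelse(is.na(df$best_subject), "", df$best_subject),
    best_identity = df$best_identity,
    fgenes_pred = as.logical(df$fgenes),
    zcurve_pred = as.logical(df$zcurve),
    stringsAsFactors = FALSE
  )
}

#' Apply the ORF acceptance rules
#'
#' A candidate is accepted iff it has homology evidence, or it lacks homology
#' but (a) is predicted protein-coding by both ab initio gene finders and
#' (b) overlaps every larger accepted ORF by fewer than `max_overlap`
#' nucleotides. Overlap is measured in shared genomic positions on the
#' circle, strand-agnostic. Candidates are processed in decreasing size
#' order ("larger" compares `n_codons`; ties break by earlier footprint
#' start, then strand) so "larger accepted ORF" is well defined; the result
#' is independent of input order.
#'
#' @param candidates data.frame from [find_orfs()].
#' @param evidence data.frame from [read_evidence_tsv()] (at most one row
#'   per candidate). Candidates with no evidence row are treated as having
#'   no support of either kind.
#' @param genome the genome (for circular overlap arithmetic).
#' @param max_overlap overlap tolerance in nt (default 75: a 74-nt overlap
#'   passes, a 75-nt overlap fails).
#' @param min_codons minimum size; smaller candidates are rejected as
#'   `too_short`.
#' @return annotation data.frame: candidate columns plus `accepted`,
#'   `rejection_reason` (none / too_short / overlap_no_evidence /
#'   no_evidence), `conservation_class` (NA until
#'   [classify_conservation()]), `product`; rows in genomic order.
#' @export
resolve_overlaps <- function(candidates, evidence, genome,
                             max_overlap = 75L, min_codons = 50L) {
  L <- genome$length
  if (nrow(candidates) == 0L) {
    ann <- cbind(empty_orf_df(),
                 data.frame(accepted = logical(0), rejection_reason = character(0),
                            conservation_class = character(0), product = character(0)))
    return(ann)
  }
  unknown <- setdiff(evidence$orf_id, candidates$orf_id)
  if (length(unknown))
    stopf("evidence references unknown orf_id(s): %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(evidence$orf_id))
    stopf("more than one evidence record for orf_id(s): %s",
          paste(unique(evidence$orf_id[duplicated(evidence$orf_id)]), collapse = ", "))
  ev <- evidence[match(candidates$orf_id, evidence$orf_id), , drop = FALSE]
  has_hom <- !is.na(ev$has_homology) & ev$has_homology
  both_ab <- !is.na(ev$fgenes_pred) & ev$fgenes_pred &
    !is.na(ev$zcurve_pred) & ev$zcurve_pred

  ord <- order(-candidates$n_codons, candidates$istart, candidates$strand)
  accepted <- logical(nrow(candidates))
  reason <- rep("none", nrow(candidates))
  acc_idx <- integer(0)
  for (i in ord) {
    if (candidates$n_codons[i] < min_codons) {
      reason[i] <- "too_short"; next
    }
    if (has_hom[i]) {
      accepted[i] <- TRUE; acc_idx <- c(acc_idx, i); next
    }
    if (!both_ab[i]) {
      reason[i] <- "no_evidence"; next
    }
    larger <- acc_idx[candidates$n_codons[acc_idx] > candidates$n_codons[i]]
    ov <- vapply(larger, function(j) {
      circ_overlap(candidates$istart[i], candidates$iend[i],
                   candidates$istart[j], candidates$iend[j], L)
    }, numeric(1))
    if (length(ov) && max(ov) >= max_overlap) {
      reason[i] <- "overlap_no_evidence"
    } else {
      accepted[i] <- TRUE; acc_idx <- c(acc_idx, i)
    }
  }
  ann <- candidates
  ann$accepted <- accepted
  ann$rejection_reason <- reason
  ann$conservation_class <- NA_character_
  ann$product <- ""
  ann <- ann[order(ann$istart, ann$iend, ann$strand), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Label accepted ORFs by conservation class
#'
#' Classes: `core` (best hit of a found core-gene inventory entry),
#' `alpha_beta_conserved` (conserved across alpha- and betabaculoviruses,
#' from an optional second hit table), `subset` (other homology evidence),
#' `unique` (no evidence). Rejected ORFs keep NA.
#'
#' @param annotations data.frame from [resolve_overlaps()].
#' @param core_hits data.frame from [inventory_core_genes()].
#' @param evidence optional evidence table (for the subset class).
#' @param alpha_beta_ids optional character vector of orf_ids conserved in
#'   alpha+beta baculovirus genomes.
#' @return annotations with `conservation_class` filled; per-class counts in
#'   `attr(, "class_counts")`.
#' @export
classify_conservation <- function(annotations, core_hits, evidence = NULL,
                                  alpha_beta_ids = character(0)) {
  core_ids <- core_hits$best_orf[core_hits$found]
  cls <- rep(NA_character_, nrow(annotations))
  hom_ids <- if (!is.null(evidence)) evidence$orf_id[evidence$has_homology] else character(0)
  for (i in seq_len(nrow(annotations))) {
    if (!annotations$accepted[i]) next
    id <- annotations$orf_id[i]
    cls[i] <- if (id %in% core_ids) "core"
      else if (id %in% alpha_beta_ids) "alpha_beta_conserved"
      else if (id %in% hom_ids) "subset"
      else "unique"
  }
  annotations$conservation_class <- cls
  counts <- table(factor(cls, levels = c("core", "alpha_beta_conserved", "subset", "unique")))
  attr(annotations, "class_counts") <- as.integer(counts) |> setNames(names(counts))
  annotations
}

#' Convert ORF annotations to a feature table for GFF3/BED export
#'
#' @param annotations data.frame from [resolve_overlaps()]; only accepted
#'   rows are exported.
#' @param genome the genome (for wrap handling).
#' @return feature data.frame.
#' @export
orfs_as_features <- function(annotations, genome) {
  acc <- annotations[annotations$accepted, , drop = FALSE]
  if (nrow(acc) == 0L)
    return(feature_record(character(0), integer(0), integer(0))[0, ])
  do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
    feature_record(acc$orf_id[i], acc$istart[i], acc$iend[i],
                   strand = acc$strand[i], kind = "ORF",
                   attributes = c(n_codons = acc$n_codons[i]))
  }))
}
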