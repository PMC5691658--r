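#' The default 48-bp degenerate repeat-unit consensus
#'
#' Mixed-case convention: uppercase positions are invariant across aligned
#' repeat units ("strict" positions, required to match exactly in strict
#' scans); lowercase positions are variable. This is the consensus of the
#' imperfect inverted repeat that recurs in the homologous repeat (hr)
#' regions of the OpbuNPV genome.
#'
#' @return the 48-character mixed-case consensus string.
#' @export
hr_consensus <- function() {
  "aACGAtCcgtcgcAgcAATTtaaaattaAATTtgTgCGatagatcGTt"
}

#' Build a degenerate-consensus object
#'
#' @param sequence mixed-case DNA text; uppercase marks strict positions.
#' @return list with `sequence`, `strict_positions` (indices of uppercase
#'   letters) and `length`.
#' @export
degenerate_consensus <- function(sequence = hr_consensus()) {
  ch <- strsplit(sequence, "")[[1]]
  if (!all(ch %in% c(DNA_BASES, tolower(DNA_BASES))))
    stopf("consensus must contain only A/C/G/T in either case")
  list(sequence = sequence,
       strict_positions = which(ch %in% DNA_BASES),
       length = length(ch))
}

#' Inverted-repeat (palindromicity) score
#'
#' Fraction of positions i whose base Watson-Crick-complements the base at
#' the mirrored position L+1-i. The center position of odd-length input is
#' excluded. A perfect palindrome scores 1. N never complements.
#'
#' @param seq DNA text (A/C/G/T/N).
#' @return fraction in \[0, 1\].
#' @export
ir_score <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) == 0L) stopf("ir_score: empty sequence")
  if (!all(ch %in% c(DNA_BASES, "N"))) stopf("ir_score: non-DNA character in input")
  L <- length(ch)
  keep <- if (L %% 2L == 1L) seq_len(L)[-((L + 1L) %/% 2L)] else seq_len(L)
  comp <- unname(DNA_COMP[ch])
  comp[ch == "N"] <- "?"           # N treated as never complementary
  mean(ch[keep] == rev(comp)[keep])
}

#' Scan a genome for degenerate-consensus repeat units
#'
#' Every fixed-length window on both strands (continuing across the origin
#' of circular genomes) is compared position-by-position to the consensus;
#' windows with at most `max_mismatch` total mismatches are reported. In
#' strict mode the uppercase (invariant) consensus positions must match
#' exactly. N in a window counts as a mismatch and the match is flagged.
#'
#' Overlapping hits are resolved by keeping the lower-mismatch window,
#' across strands (ties: lower position, then plus strand). Cross-strand
#' resolution matters here: the default consensus is palindromic enough that
#' a genuine repeat copy is also hit, with about ten extra mismatches, on
#' the opposite strand.
#'
#' @param genome a [circular_genome()].
#' @param consensus a [degenerate_consensus()] (or mixed-case string).
#' @param max_mismatch total mismatch budget (default 12 = 25% of the 48-nt
#'   consensus).
#' @param strict require exact match at uppercase positions (default TRUE).
#' @return data.frame of matches sorted by position: `position` (1-based
#'   leftmost genome coordinate of the window), `strand`, `matched_seq`
#'   (window read in consensus orientation), `mismatch_total`,
#'   `mismatch_strict`, `ir_score`, `has_n`.
#' @export
scan_degenerate <- function(genome, consensus = degenerate_consensus(),
                            max_mismatch = 12L, strict = TRUE) {
  if (is.character(consensus)) consensus <- degenerate_consensus(consensus)
  k <- consensus$length
  L <- genome$length
  if (k > L) stopf("consensus longer than genome")
  if (max_mismatch >= k) stopf("max_mismatch must be < consensus length (vacuous scan)")
  cons <- toupper(consensus$sequence)
  cons_ch <- strsplit(cons, "")[[1]]
  strict_idx <- consensus$strict_positions

  g <- strsplit(genome$sequence, "")[[1]]
  n_win <- if (genome$topology == "circular") L else L - k + 1L
  ext <- if (genome$topology == "circular") c(g, g[seq_len(k - 1L)]) else g

  hits <- list()
  for (strand in c("+", "-")) {
    if (strand == "+") {
      target <- cons_ch; s_idx <- strict_idx
    } else {
      # window matches consensus on the minus strand <=> window (as written
      # on the plus strand) matches the reverse complement of the consensus;
      # strict positions mirror accordingly
      target <- strsplit(reverse_complement(cons), "")[[1]]
      s_idx <- k + 1L - strict_idx
    }
    total <- integer(n_win); strict_mm <- integer(n_win); has_n <- logical(n_win)
    for (j in seq_len(k)) {
      col <- ext[seq_len(n_win) + j - 1L]
      mm <- col != target[j]
      total <- total + mm
      if (j %in% s_idx) strict_mm <- strict_mm + mm
      has_n <- has_n | col == "N"
    }
    keep <- total <= max_mismatch
    if (strict) keep <- keep & strict_mm == 0L
    pos <- which(keep)
    if (length(pos) == 0L) next
    mseq <- vapply(pos, function(p) paste(ext[p:(p + k - 1L)], collapse = ""), character(1))
    if (strand == "-") mseq <- vapply(mseq, reverse_complement, character(1), USE.NAMES = FALSE)
    hits[[strand]] <- data.frame(
      position = pos, strand = strand, matched_seq = mseq,
      mismatch_total = total[pos], mismatch_strict = strict_mm[pos],
      ir_score = vapply(mseq, ir_score, numeric(1), USE.NAMES = FALSE),
      has_n = has_n[pos], stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty_hr_match_df())
  df <- do.call(rbind, hits)

  # overlap resolution: greedy by (mismatch_total, position, "+" first)
  df <- df[order(df$mismatch_total, df$position, df$strand), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    ovl <- FALSE
    for (j in kept) {
      d <- abs(df$position[i] - df$position[j])
      if (genome$topology == "circular") d <- min(d, L - d)
      if (d < k) { ovl <- TRUE; break }
    }
    if (!ovl) kept <- c(kept, i)
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_hr_match_df <- function() {
  data.frame(position = integer(0), strand = character(0),
             matched_seq = character(0), mismatch_total = integer(0),
             mismatch_strict = integer(0), ir_score = numeric(0),
             has_n = logical(0), stringsAsFactors = FALSE)
}

#' Cluster repeat-unit matches into hr regions
#'
#' Single-linkage clustering along the circle: consecutive matches whose
#' start-to-start distance is at most `max_gap` join one region; on circular
#' genomes the first and last match can join across the origin. Region
#' spans cover all member repeat units.
#'
#' @param matches data.frame from [scan_degenerate()].
#' @param genome the scanned genome.
#' @param max_gap maximum start-to-start distance within a region
#'   (default 1000 nt).
#' @param unit_length repeat-unit length (consensus length, default 48).
#' @return data.frame of regions ordered by span start: `region_id`,
#'   `span_start`, `span_end`, `copy_count`, plus the member matches in
#'   `attr(, "members")` (a list of data.frames).
#' @export
cluster_matches <- function(matches, genome, max_gap = 1000L, unit_length = 48L) {
  if (nrow(matches) == 0L)
    return(structure(data.frame(region_id = character(0), span_start = integer(0),
                                span_end = integer(0), copy_count = integer(0)),
                     members = list()))
  L <- genome$length
  m <- matches[order(matches$position), , drop = FALSE]
  n <- nrow(m)
  grp <- cumsum(c(1L, diff(m$position) > max_gap))
  if (genome$topology == "circular" && n > 1L && max(grp) > 1L) {
    wrap_gap <- m$position[1L] + L - m$position[n]
    if (wrap_gap <= max_gap) grp[grp == max(grp)] <- grp[1L]  # join across origin
  }
  regions <- lapply(unique(grp), function(gid) m[grp == gid, , drop = FALSE])
  span <- lapply(regions, function(mem) {
    p <- mem$position
    if (length(p) > 1L && any(diff(p) > max_gap)) {
      # region joined across the origin: span wraps
      brk <- which(diff(p) > max_gap)[1L]
      c(p[brk + 1L], ((p[brk] + unit_length - 2L) %% L) + 1L)
    } else {
      c(p[1L], ((p[length(p)] + unit_length - 2L) %% L) + 1L)
    }
  })
  df <- data.frame(
    span_start = vapply(span, `[`, numeric(1), 1L),
    span_end = vapply(span, `[`, numeric(1), 2L),
    copy_count = vapply(regions, nrow, integer(1)))
  ord <- order(df$span_start)
  df <- df[ord, , drop = FALSE]
  regions <- regions[ord]
  df <- cbind(region_id = sprintf("hr%d", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  structure(df, members = regions)
}

#' Consensus of aligned equal-length repeat units, with shading classes
#'
#' Per alignment column: all residues identical gives an uppercase consensus
#' letter shaded black; a single residue occupying more than half the rows
#' gives a lowercase letter shaded black; otherwise, if one base class
#' (purine or pyrimidine) occupies more than half the rows the column is
#' shaded gray, lettered with the lowercase majority residue when one exists
#' and with the IUPAC class letter (r/y) when none does; remaining columns
#' are unshaded and lettered n.
#'
#' @param repeats character vector of >= 2 equal-length DNA strings
#'   (repeat units aligned by consensus coordinates).
#' @return list: `consensus` (mixed-case string), `identity` (per-column
#'   fraction of the modal residue), `shading` (per-column black/gray/none).
#' @export
build_consensus <- function(repeats) {
  if (length(repeats) < 2L) stopf("build_consensus needs at least 2 sequences")
  lens <- nchar(repeats)
  if (length(unique(lens)) != 1L) stopf("build_consensus: sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(repeats), ""))
  n <- nrow(mat); k <- ncol(mat)
  cons <- character(k); ident <- numeric(k); shade <- character(k)
  for (j in seq_len(k)) {
    tab <- table(mat[, j])
    top <- names(tab)[which.max(tab)]
    fmax <- max(tab) / n
    ident[j] <- fmax
    if (fmax == 1) {
      cons[j] <- top; shade[j] <- "black"
    } else if (fmax > 0.5) {
      cons[j] <- tolower(top); shade[j] <- "black"
    } else {
      pur <- sum(mat[, j] %in% c("A", "G")) / n
      pyr <- sum(mat[, j] %in% c("C", "T")) / n
      if (pur > 0.5 || pyr > 0.5) {
        shade[j] <- "gray"
        cons[j] <- if (sum(tab == max(tab)) == 1L) tolower(top)
                   else if (pur > 0.5) "r" else "y"
      } else {
        shade[j] <- "none"; cons[j] <- "n"
      }
    }
  }
  list(consensus = paste(cons, collapse = ""), identity = ident, shading = shade)
}

#' Convert hr regions and their repeat units to a feature table
#'
#' @param regions data.frame from [cluster_matches()].
#' @param genome the genome.
#' @param unit_length repeat-unit length.
#' @return feature data.frame with one `hr` row per region and one
#'   `repeat_unit` row per member match.
#' @export
hrs_as_features <- function(regions, genome, unit_length = 48L) {
  members <- attr(regions, "members")
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rows[[length(rows) + 1L]] <-
      feature_record(regions$region_id[i], regions$span_start[i],
                     regions$span_end[i], strand = "+", kind = "hr",
                     attributes = c(copy_count = regions$copy_count[i]))
    mem <- members[[i]]
    for (j in seq_len(nrow(mem))) {
      e <- ((mem$position[j] + unit_length - 2L) %% genome$length) + 1L
      rows[[length(rows) + 1L]] <-
        feature_record(sprintf("%s_u%d", regions$region_id[i], j),
                       mem$position[j], e, strand = mem$strand[j],
                       kind = "repeat_unit",
                       attributes = c(mismatches = mem$mismatch_total[j]))
    }
  }
  if (length(rows) == 0L) return(feature_record(character(0), integer(0), integer(0))[0, ])
  do.call(rbind, rows)
}
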