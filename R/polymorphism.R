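#' Read a per-position pileup table
#'
#' The canonical exchange format is a TSV with columns `position`, `ref`,
#' `depth`, `A`, `C`, `G`, `T`, `ins`, `del`. `ins` holds semicolon-joined
#' `SEQ:count` entries (inserted sequence after this position), `del` holds
#' `LEN:count` entries (deletion of LEN nt starting at the next position);
#' both may be empty. Missing positions are allowed and treated as depth 0.
#'
#' @param path TSV file (with header).
#' @return data.frame sorted by position.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) return(empty_pileup_df())
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(ins = "character", del = "character"))
  need <- c("position", "ref", "depth", "A", "C", "G", "T", "ins", "del")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("pileup missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(empty_pileup_df())
  df$ins[is.na(df$ins)] <- ""; df$del[is.na(df$del)] <- ""
  base_sum <- df$A + df$C + df$G + df$T
  bad <- base_sum > df$depth
  if (any(bad))
    stopf("pileup base counts exceed depth at position(s): %s",
          paste(df$position[which(bad)[seq_len(min(5, sum(bad)))]], collapse = ", "))
  df <- df[order(df$position), need, drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_pileup_df <- function() {
  data.frame(position = integer(0), ref = character(0), depth = integer(0),
             A = integer(0), C = integer(0), G = integer(0), T = integer(0),
             ins = character(0), del = character(0), stringsAsFactors = FALSE)
}

#' Write a pileup table
#' @param pileup data.frame as returned by [read_pileup()].
#' @param path output TSV.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_indel_field <- function(s) {
  if (is.na(s) || !nzchar(s)) return(data.frame(key = character(0), count = integer(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(key = vapply(parts, `[`, character(1), 1L),
             count = as.integer(vapply(parts, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

format_indel_field <- function(keys, counts) {
  if (length(keys) == 0L) "" else paste(sprintf("%s:%d", keys, counts), collapse = ";")
}

#' Call SNPs and indels from a pileup
#'
#' At each column with depth at least `min_depth`, every non-reference
#' allele (substitution base, inserted sequence, or deletion length)
#' observed in at least `min_alt` reads and at a frequency of at least
#' `min_freq` percent becomes one call; multi-allelic columns produce one
#' call per alternate allele. Frequency is 100 * alt_count / depth, reported
#' to 2 decimals (the indel denominator is the column depth, same as SNPs).
#'
#' @param pileup data.frame from [read_pileup()] / [simulate_pileup()].
#' @param min_depth minimum column depth (default 20 reads).
#' @param min_alt minimum reads supporting the allele (default 2).
#' @param min_freq minimum frequency in percent (default 1.0).
#' @return data.frame of calls sorted by position: `position`, `ref`, `alt`,
#'   `kind` (SNP/insertion/deletion), `alt_count`, `depth`, `frequency`.
#' @export
call_polymorphisms <- function(pileup, min_depth = 20L, min_alt = 2L, min_freq = 1.0) {
  calls <- list()
  ok_depth <- pileup$depth >= min_depth
  for (b in DNA_BASES) {
    cnt <- pileup[[b]]
    sel <- ok_depth & pileup$ref != b & cnt >= min_alt &
      100 * cnt / pileup$depth >= min_freq
    if (any(sel))
      calls[[b]] <- data.frame(
        position = pileup$position[sel], ref = pileup$ref[sel], alt = b,
        kind = "SNP", alt_count = cnt[sel], depth = pileup$depth[sel],
        stringsAsFactors = FALSE)
  }
  has_indel <- which((nzchar(pileup$ins) | nzchar(pileup$del)) & ok_depth)
  for (i in has_indel) {
    for (fld in c("ins", "del")) {
      tab <- parse_indel_field(pileup[[fld]][i])
      for (r in seq_len(nrow(tab))) {
        if (tab$count[r] < min_alt) next
        if (100 * tab$count[r] / pileup$depth[i] < min_freq) next
        calls[[length(calls) + 1L]] <- data.frame(
          position = pileup$position[i],
          ref = if (fld == "ins") "-" else strrep("N", as.integer(tab$key[r])),
          alt = if (fld == "ins") tab$key[r] else "-",
          kind = if (fld == "ins") "insertion" else "deletion",
          alt_count = tab$count[r], depth = pileup$depth[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L)
    return(data.frame(position = integer(0), ref = character(0), alt = character(0),
                      kind = character(0), alt_count = integer(0), depth = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, calls)
  df$frequency <- round(100 * df$alt_count / df$depth, 2)
  df <- df[order(df$position, df$kind, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify the coding effect of each call
#'
#' A SNP inside an accepted ORF is translated on the ORF's strand and frame:
#' same amino acid is `synonymous`, different is `nonsynonymous`, alternate
#' codon encoding a stop is `nonsense` (loss of the annotated stop codon is
#' reported as nonsynonymous). An indel inside an ORF is `frameshift` when
#' its length is not divisible by 3 and `nonsynonymous` (in-frame
#' insertion/deletion of residues) otherwise. Calls outside all accepted
#' ORFs are `intergenic`. A call inside two overlapping ORFs is reported
#' once per ORF.
#'
#' @param calls data.frame from [call_polymorphisms()].
#' @param annotations data.frame from [resolve_overlaps()] (accepted rows
#'   are used).
#' @param genome the reference genome the pileup was made against.
#' @return calls with columns `effect` and `orf_id` added (possibly more
#'   rows than input for calls in overlapping ORFs).
#' @export
classify_effect <- function(calls, annotations, genome) {
  L <- genome$length
  if (any(calls$position < 1L | calls$position > L))
    stopf("call position outside genome [1, %d]", L)
  acc <- annotations[annotations$accepted, , drop = FALSE]
  gc_tab <- Biostrings::GENETIC_CODE
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, , drop = FALSE]
    pos <- cl$position
    hit <- which(vapply(seq_len(nrow(acc)), function(j) {
      circ_overlap(pos, pos, acc$istart[j], acc$iend[j], L) > 0L
    }, logical(1)))
    if (length(hit) == 0L) {
      cl$effect <- "intergenic"; cl$orf_id <- ""
      out[[i]] <- cl
      next
    }
    rows <- lapply(hit, function(j) {
      o <- acc[j, ]
      r <- cl
      r$orf_id <- o$orf_id
      if (cl$kind != "SNP") {
        len <- if (cl$kind == "insertion") nchar(cl$alt) else nchar(cl$ref)
        r$effect <- if (len %% 3L != 0L) "frameshift" else "nonsynonymous"
        return(r)
      }
      span <- 3L * (o$n_codons + 1L)
      off_left <- circ_fwd_dist(o$istart, pos, L)       # 0-based from footprint left
      t <- if (o$strand == "+") off_left else span - 1L - off_left
      ci <- t %/% 3L                                    # codon index, 0-based
      cp <- t %% 3L                                     # position within codon
      codon_start_t <- 3L * ci
      codon_pos <- vapply(0:2, function(w) {
        tt <- codon_start_t + w
        if (o$strand == "+") ((o$istart - 1L + tt) %% L) + 1L
        else ((o$iend - 1L - tt) %% L + L) %% L + 1L
      }, numeric(1))
      get_base <- function(p) substr(genome$sequence, p, p)
      comp1 <- function(b) unname(DNA_COMP[b])
      read_base <- function(p) if (o$strand == "+") get_base(p) else comp1(get_base(p))
      ref_codon <- paste(vapply(codon_pos, read_base, character(1)), collapse = "")
      alt_b <- if (o$strand == "+") cl$alt else comp1(cl$alt)
      alt_codon <- ref_codon
      substr(alt_codon, cp + 1L, cp + 1L) <- alt_b
      ref_aa <- unname(gc_tab[ref_codon]); alt_aa <- unname(gc_tab[alt_codon])
      if (is.na(ref_aa)) ref_aa <- "X"
      if (is.na(alt_aa)) alt_aa <- "X"
      r$effect <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
        else if (alt_aa == ref_aa) "synonymous"
        else "nonsynonymous"
      r
    })
    out[[i]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L) {
    calls$effect <- character(0); calls$orf_id <- character(0)
    return(calls)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize the variant frequency spectrum
#'
#' @param calls data.frame from [call_polymorphisms()].
#' @param thresholds frequency thresholds in percent (default `c(6, 8)`).
#' @param top_k size of the top-frequency list (default 10).
#' @return list: `total`, `n_ge` / `n_le` (named by threshold), `top`
#'   (calls sorted by decreasing frequency, first `top_k`).
#' @export
summarize_frequencies <- function(calls, thresholds = c(6, 8), top_k = 10L) {
  n_ge <- vapply(thresholds, function(t) sum(calls$frequency >= t), integer(1))
  n_le <- vapply(thresholds, function(t) sum(calls$frequency <= t), integer(1))
  names(n_ge) <- names(n_le) <- paste0(thresholds, "%")
  top <- calls[order(-calls$frequency, calls$position), , drop = FALSE]
  list(total = nrow(calls), n_ge = n_ge, n_le = n_le,
       top = head(top, top_k))
}

#' Write polymorphism calls as TSV
#' @param calls calls data.frame.
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  calls$frequency <- sprintf("%.2f", calls$frequency)
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
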