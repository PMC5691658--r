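#' Construct a circular (or linear) genome object
#'
#' The genome is stored as an uppercase character string restricted to the
#' alphabet A, C, G, T, N. Input case is not semantic. Ambiguity codes other
#' than N are rejected: they do not occur in finished nucleopolyhedrovirus
#' assemblies and silently scoring them would corrupt downstream ORF and
#' repeat calls.
#'
#' @param sequence DNA text (any case).
#' @param id sequence identifier.
#' @param topology `"circular"` (genomes) or `"linear"` (gene sequences).
#' @return an object of class `circular_genome` with fields `id`, `sequence`,
#'   `topology` and `length`.
#' @export
circular_genome <- function(sequence, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(sequence) || length(sequence) != 1L)
    stopf("sequence must be a single character string")
  seq <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stopf("sequence contains non-ACGTN characters: %s",
          paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(
    list(id = id, sequence = seq, topology = topology, length = nchar(seq)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s, %d bp\n", x$id, x$topology, x$length))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param topology topology assigned to every record (circular for genome
#'   assemblies, linear for gene sequences).
#' @return list of [circular_genome()] objects, in file order.
#' @export
read_genome_fasta <- function(path, topology = "circular") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(ss) == 0L) stopf("empty FASTA file: %s", path)
  lapply(seq_along(ss), function(i) {
    circular_genome(as.character(ss[[i]]), id = sub("\\s.*$", "", names(ss)[i]),
                    topology = topology)
  })
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences, or a list of
#'   `circular_genome` objects.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1), "circular_genome")))
    seqs <- setNames(vapply(seqs, `[[`, character(1), "sequence"),
                     vapply(seqs, `[[`, character(1), "id"))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. An involution on
#' the A/C/G/T/N alphabet.
#'
#' @param seq DNA text.
#' @return reverse-complemented text, same case-normalized alphabet.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stopf("reverse_complement: non-ACGTN character in input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' G+C content of a genome, in percent
#'
#' Computed as 100 * (G+C) / (A+C+G+T); N is excluded from the denominator.
#'
#' @param genome a `circular_genome` or a DNA string.
#' @param digits decimals reported (default 2, the convention used for genome
#'   statistics in baculovirus genome reports).
#' @return percent G+C, rounded.
#' @export
gc_content <- function(genome, digits = 2L) {
  seq <- if (inherits(genome, "circular_genome")) genome$sequence else toupper(genome)
  ch <- strsplit(seq, "")[[1]]
  acgt <- sum(ch %in% DNA_BASES)
  if (acgt == 0L) stopf("gc_content: sequence has no A/C/G/T characters")
  round(100 * sum(ch %in% c("G", "C")) / acgt, digits)
}

#' Assemble a feature table row
#'
#' Features use 1-based inclusive coordinates (GenBank convention).
#' `start > end` is legal only for features wrapping the origin of a circular
#' genome.
#'
#' @param feature_id identifier.
#' @param start,end 1-based inclusive nt coordinates.
#' @param strand `"+"` or `"-"`.
#' @param kind `"ORF"`, `"hr"` or `"repeat_unit"`.
#' @param attributes named character vector of extra GFF3 attributes.
#' @return one-row data.frame.
#' @export
feature_record <- function(feature_id, start, end, strand = "+",
                           kind = c("ORF", "hr", "repeat_unit"), attributes = NULL) {
  kind <- match.arg(kind)
  attr_str <- if (is.null(attributes) || length(attributes) == 0L) "" else
    paste(sprintf("%s=%s", names(attributes), attributes), collapse = ";")
  data.frame(feature_id = feature_id, start = as.integer(start), end = as.integer(end),
             strand = strand, kind = kind, attributes = attr_str,
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome) {
  L <- genome$length
  bad <- features$start < 1L | features$start > L | features$end < 1L | features$end > L
  if (any(bad))
    stopf("feature(s) out of genome bounds [1, %d]: %s", L,
          paste(features$feature_id[bad], collapse = ", "))
  wrap <- features$start > features$end
  if (any(wrap) && genome$topology != "circular")
    stopf("origin-wrapping feature(s) on a linear genome: %s",
          paste(features$feature_id[wrap], collapse = ", "))
  invisible(TRUE)
}

gff3_type <- c(ORF = "CDS", hr = "repeat_region", repeat_unit = "repeat_unit")

#' Write features as GFF3
#'
#' Coordinates are 1-based inclusive. A feature wrapping the origin of a
#' circular genome is emitted as two part-lines sharing one `ID` (the GFF3
#' multi-part convention), split at the origin.
#'
#' @param features feature data.frame (see [feature_record()]).
#' @param genome the `circular_genome` the features annotate.
#' @param path output file.
#' @export
write_gff3 <- function(features, genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  if (nrow(features) > 0L) {
    validate_features(features, genome)
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      type <- gff3_type[[f$kind]]
      attrs <- sprintf("ID=%s", f$feature_id)
      if (nzchar(f$attributes)) attrs <- paste(attrs, f$attributes, sep = ";")
      parts <- if (f$start <= f$end) list(c(f$start, f$end)) else
        list(c(f$start, genome$length), c(1L, f$end))
      for (p in parts) {
        lines <- c(lines, paste(genome$id, "baculokit", type, p[1], p[2],
                                ".", f$strand, ".", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write repeat-unit features as BED
#'
#' Converts the internal 1-based inclusive model to BED's 0-based half-open
#' intervals at this boundary. Origin-wrapping features are split in two.
#'
#' @inheritParams write_gff3
#' @export
write_bed <- function(features, genome, path) {
  rows <- character(0)
  if (nrow(features) > 0L) {
    validate_features(features, genome)
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      parts <- if (f$start <= f$end) list(c(f$start, f$end)) else
        list(c(f$start, genome$length), c(1L, f$end))
      for (p in parts)
        rows <- c(rows, paste(genome$id, p[1] - 1L, p[2], f$feature_id, 0L,
                              f$strand, sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Extract a (possibly origin-wrapping) subsequence
#'
#' @param genome a `circular_genome`.
#' @param start,end 1-based inclusive endpoints; `start > end` wraps the
#'   origin (circular genomes only).
#' @param strand if `"-"`, the reverse complement of the span is returned.
#' @return DNA string.
#' @export
extract_subseq <- function(genome, start, end, strand = "+") {
  L <- genome$length
  if (start <= end) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (genome$topology != "circular") stopf("wrapping extraction on a linear genome")
    s <- paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1L, end))
  }
  if (strand == "-") reverse_complement(s) else s
}
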