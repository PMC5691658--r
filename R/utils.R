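#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist median rbinom rpois runif setNames uniroot
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Length of a (possibly origin-wrapping) span on a circular sequence
#'
#' @param start,end 1-based inclusive endpoints; `start > end` denotes a span
#'   crossing the origin.
#' @param len genome length in nt.
#' @return integer span length.
#' @keywords internal
circ_span_length <- function(start, end, len) {
  ifelse(start <= end, end - start + 1L, len - start + 1L + end)
}

# positions covered by a circular span, walking forward from start
circ_positions <- function(start, n, len) {
  ((start - 1L + seq_len(n) - 1L) %% len) + 1L
}

# decompose a circular span into 1 or 2 linear [lo, hi] intervals
circ_intervals <- function(start, end, len) {
  if (start <= end) list(c(start, end)) else list(c(start, len), c(1L, end))
}

#' Shared nucleotides between two circular spans (strand-agnostic)
#' @keywords internal
circ_overlap <- function(start1, end1, start2, end2, len) {
  i1 <- circ_intervals(start1, end1, len)
  i2 <- circ_intervals(start2, end2, len)
  ov <- 0L
  for (a in i1) for (b in i2) {
    lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
    if (lo <= hi) ov <- ov + (hi - lo + 1L)
  }
  ov
}

# circular forward distance from position a to position b (0 if equal)
circ_fwd_dist <- function(a, b, len) (b - a) %% len
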