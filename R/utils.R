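# Internal helpers shared across modules.

#' @importFrom methods as is
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_refscaf <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert Phred+33 quality strings to integer lists
#'
#' @param quals character vector of Phred+33 encoded quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_ints <- function(quals) {
  lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param q integer vector of Phred scores (0-41).
#' @return single character string.
#' @export
phred_string <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper over Biostrings.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse each string (no complement); used for quality strings.
str_reverse <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Width of the union of 0-based half-open intervals.
interval_union_width <- function(start, end) {
  if (length(start) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(as.numeric(IRanges::width(ir)))
}

# Round half away from zero (printed-table convention), vectorised.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# First index (1-based) in each read at which the quality drops below
# `q_floor`, or len+1 when no base is below threshold.  Operates on the
# concatenated Phred+33 representation so it stays vectorised for millions
# of reads of heterogeneous length.
first_below_threshold <- function(quals, q_floor) {
  n <- length(quals)
  if (n == 0L) return(integer(0))
  lens <- nchar(quals)
  big <- paste(quals, collapse = "")
  qi <- as.integer(charToRaw(big)) - 33L
  offsets <- c(0L, cumsum(lens))
  below <- which(qi < q_floor)                      # global positions, sorted
  out <- lens + 1L
  if (length(below)) {
    ridx <- findInterval(below - 0.5, offsets)      # read index for each hit
    keep <- !duplicated(ridx)                       # first hit per read
    out[ridx[keep]] <- below[keep] - offsets[ridx[keep]]
  }
  out
}
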