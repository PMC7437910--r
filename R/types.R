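#' Core tabular containers
#'
#' The toolkit passes data between stages as plain tibbles with fixed column
#' contracts, validated by the constructors below.
#'
#' * **reads** (`quality_reads()`): `read_id`, `bases`, `quals` (Phred+33
#'   string, same length as `bases`), `run_label`, `mate_role` (one of
#'   `fragment`, `mate_first`, `mate_second`).
#' * **placements** (`placements()`): `read_id`, `ref_name`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand` (`+`/`-`), `proj_bases`
#'   (reference-projected bases, one symbol per reference column; `-` marks a
#'   deletion column; insertions relative to the reference are dropped),
#'   `mapq`, and optionally `proj_quals` (Phred+33, `!` at deletion columns)
#'   plus `run_label`/`mate_role` carried from the reads.
#' * **contigs**: `contig_id`, `seq`, `ref_name`, `ref_start`, `ref_end`,
#'   `support` (list of read ids), `status` (`unconfirmed`/`confirmed`/
#'   `conflicted`), `del_cols` (list of 0-based anchor-relative deletion
#'   columns).
#'
#' @name refscaf-types
NULL

MATE_ROLES <- c("fragment", "mate_first", "mate_second")
REPEAT_FAMILIES <- c("LINE", "LTR", "SINE", "Simple repeat", "Satellite",
                     "ncRNA", "Others")

#' Construct a validated read table
#'
#' @param read_id character vector of non-empty read identifiers.
#' @param bases character vector of base strings over `{A,C,G,T,N}`.
#' @param quals character vector of Phred+33 quality strings, one symbol per
#'   base.
#' @param run_label run (library) label, recycled.
#' @param mate_role one of `fragment`, `mate_first`, `mate_second`, recycled.
#' @return tibble with the read column contract.
#' @export
quality_reads <- function(read_id, bases, quals,
                          run_label = "run1", mate_role = "fragment") {
  x <- tibble::tibble(read_id = as.character(read_id),
                      bases = as.character(bases),
                      quals = as.character(quals),
                      run_label = as.character(run_label),
                      mate_role = as.character(mate_role))
  validate_reads(x)
  x
}

validate_reads <- function(x) {
  stopifnot(all(c("read_id", "bases", "quals", "run_label", "mate_role") %in%
                  names(x)))
  if (any(!nzchar(x$read_id))) stop_refscaf("empty read_id")
  bad <- which(nchar(x$bases) != nchar(x$quals))
  if (length(bad)) {
    stop_refscaf("read '%s': bases (%d) and qualities (%d) differ in length",
                 x$read_id[bad[1]], nchar(x$bases[bad[1]]),
                 nchar(x$quals[bad[1]]))
  }
  if (any(!x$mate_role %in% MATE_ROLES)) {
    stop_refscaf("mate_role must be one of %s",
                 paste(MATE_ROLES, collapse = ", "))
  }
  invisible(x)
}

#' Construct a validated placement table
#'
#' Coordinates are 0-based half-open on the reference.
#'
#' @param read_id,ref_name,ref_start,ref_end,strand,proj_bases,mapq placement
#'   fields; see [refscaf-types].
#' @param proj_quals optional reference-projected Phred+33 qualities.
#' @param ... further columns carried through (e.g. `run_label`).
#' @return tibble with the placement column contract.
#' @export
placements <- function(read_id, ref_name, ref_start, ref_end, strand,
                       proj_bases, mapq = 60L, proj_quals = NULL, ...) {
  x <- tibble::tibble(read_id = as.character(read_id),
                      ref_name = as.character(ref_name),
                      ref_start = as.integer(ref_start),
                      ref_end = as.integer(ref_end),
                      strand = as.character(strand),
                      proj_bases = as.character(proj_bases),
                      mapq = as.integer(mapq), ...)
  if (!is.null(proj_quals)) x$proj_quals <- as.character(proj_quals)
  validate_placements(x)
  x
}

validate_placements <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$ref_start >= x$ref_end)) stop_refscaf("placement with ref_start >= ref_end")
  if (!all(x$strand %in% c("+", "-"))) stop_refscaf("strand must be '+' or '-'")
  bad <- which(nchar(x$proj_bases) != x$ref_end - x$ref_start)
  if (length(bad)) {
    stop_refscaf("placement '%s': proj_bases length %d != interval width %d",
                 x$read_id[bad[1]], nchar(x$proj_bases[bad[1]]),
                 x$ref_end[bad[1]] - x$ref_start[bad[1]])
  }
  invisible(x)
}

#' Describe a sequencing library
#'
#' @param name library name; must match the `run_label` of its reads.
#' @param insert_mean,insert_sd insert-size mean and standard deviation (bp).
#' @param orientation expected relative orientation of the two mates:
#'   `"same"` (SOLiD-style mate pair, both mates on one strand) or
#'   `"inward"` (Illumina-style paired end, mates facing each other).
#' @return one-row tibble.
#' @export
library_spec <- function(name, insert_mean, insert_sd,
                         orientation = c("same", "inward")) {
  orientation <- match.arg(orientation)
  if (insert_mean <= 0) stop_refscaf("insert_mean must be positive")
  if (insert_sd < 0) stop_refscaf("insert_sd must be non-negative")
  tibble::tibble(name = name, insert_mean = as.numeric(insert_mean),
                 insert_sd = as.numeric(insert_sd), orientation = orientation)
}

# Empty placement table with the full column contract.
empty_placements <- function() {
  placements(character(0), character(0), integer(0), integer(0),
             character(0), character(0), integer(0))
}
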