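# Coalescing colinear whole-genome alignment segments into syntenic blocks,
# and gene-structure verification within scaffolds.

#' Coalesce colinear alignment segments into syntenic blocks
#'
#' Segments shorter than `min_seg` on the reference are discarded.  The rest
#' are grouped by (reference sequence, query sequence, strand), sorted by
#' reference start, and consecutive segments are chained when both the
#' reference gap and the query gap are at most `max_join_gap` and the query
#' order is monotone (increasing for `+`, decreasing for `-`).  Overlapping
#' reference intervals are first trimmed at the midpoint of their overlap so
#' chaining operates on disjoint segments.
#'
#' @param segments alignment segment tibble (see [read_annotations()] with
#'   `kind = "paf"`).
#' @param max_join_gap largest bridgeable gap in bp on either genome
#'   (default 50 kb).
#' @param min_seg minimum reference length of a usable segment (default
#'   100 bp).
#' @return block tibble: `ref_name`, `ref_start`, `ref_end`, `qry_name`,
#'   `qry_start`, `qry_end`, `strand`, `n_segments`, `span`
#'   (`ref_end - ref_start`), plus a `segments` list column holding the row
#'   indices of the retained, trimmed segments in each block.
#' @export
coalesce_segments <- function(segments, max_join_gap = 50000L,
                              min_seg = 100L) {
  seg <- segments[segments$ref_end - segments$ref_start >= min_seg, ,
                  drop = FALSE]
  if (nrow(seg) == 0L) return(empty_blocks())
  key <- paste(seg$ref_name, seg$qry_name, seg$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(seg)), key), function(idx) {
    g <- seg[idx, , drop = FALSE]
    o <- order(g$ref_start, g$ref_end)
    g <- g[o, , drop = FALSE]
    idx <- idx[o]
    # trim reference overlaps at the midpoint (queries trimmed by the same
    # amount, alignments being treated as 1:1 for this purpose)
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        ov <- g$ref_end[i - 1L] - g$ref_start[i]
        if (ov > 0L) {
          left <- ov %/% 2L
          right <- ov - left
          g$ref_end[i - 1L] <- g$ref_end[i - 1L] - left
          g$ref_start[i] <- g$ref_start[i] + right
          if (g$strand[1] == "+") {
            g$qry_end[i - 1L] <- g$qry_end[i - 1L] - left
            g$qry_start[i] <- g$qry_start[i] + right
          } else {
            g$qry_start[i - 1L] <- g$qry_start[i - 1L] + left
            g$qry_end[i] <- g$qry_end[i] - right
          }
        }
      }
      g <- g[g$ref_end > g$ref_start & g$qry_end > g$qry_start, ,
             drop = FALSE]
    }
    if (nrow(g) == 0L) return(NULL)
    ref_gap <- c(Inf, g$ref_start[-1L] - g$ref_end[-nrow(g)])
    if (g$strand[1] == "+") {
      qry_gap <- c(Inf, g$qry_start[-1L] - g$qry_end[-nrow(g)])
    } else {
      qry_gap <- c(Inf, g$qry_start[-nrow(g)] - g$qry_end[-1L])
    }
    chain <- cumsum(!(ref_gap >= 0 & ref_gap <= max_join_gap &
                        qry_gap >= 0 & qry_gap <= max_join_gap))
    blocks <- lapply(split(seq_len(nrow(g)), chain), function(m) {
      tibble::tibble(ref_name = g$ref_name[1],
                     ref_start = min(g$ref_start[m]),
                     ref_end = max(g$ref_end[m]),
                     qry_name = g$qry_name[1],
                     qry_start = min(g$qry_start[m]),
                     qry_end = max(g$qry_end[m]),
                     strand = g$strand[1],
                     n_segments = length(m),
                     segments = list(idx[m]))
    })
    do.call(rbind, blocks)
  })
  blocks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  blocks$span <- blocks$ref_end - blocks$ref_start
  blocks <- blocks[order(blocks$ref_name, blocks$ref_start, blocks$qry_name), ,
                   drop = FALSE]
  blocks
}

empty_blocks <- function() {
  tibble::tibble(ref_name = character(0), ref_start = integer(0),
                 ref_end = integer(0), qry_name = character(0),
                 qry_start = integer(0), qry_end = integer(0),
                 strand = character(0), n_segments = integer(0),
                 segments = list(), span = integer(0))
}

#' Filter syntenic blocks by minimum reference span
#'
#' @param blocks block tibble from [coalesce_segments()].
#' @param min_block minimum `span` in bp (e.g. 1 Mb, or 500 kb for sparser
#'   assemblies).
#' @return the blocks whose span is at least `min_block`.
#' @export
filter_blocks <- function(blocks, min_block) {
  blocks[blocks$span >= min_block, , drop = FALSE]
}

#' Verify conservation of a gene structure within one scaffold
#'
#' A gene is `verified` when all its exons lie on one scaffold, share one
#' strand, and their scaffold coordinates follow transcript order
#' (reversed on `-`).  Failures are categorised in the order `split` (more
#' than one scaffold), `strand_mixed`, `disordered`.
#'
#' @param exons tibble of exon placements in transcript order:
#'   `scaffold_id`, `start`, `end`, `strand`.
#' @return one of `"verified"`, `"split"`, `"strand_mixed"`, `"disordered"`.
#' @export
verify_gene_structure <- function(exons) {
  if (nrow(exons) == 0L) stop_refscaf("gene with no exon placements")
  if (length(unique(exons$scaffold_id)) > 1L) return("split")
  if (length(unique(exons$strand)) > 1L) return("strand_mixed")
  s <- exons$start
  ordered <- if (exons$strand[1] == "+") all(diff(s) > 0) else
    all(diff(s) < 0)
  if (!ordered) return("disordered")
  "verified"
}

#' Per-sequence reference coverage of a set of intervals
#'
#' @param intervals tibble with `ref_name`, `ref_start`, `ref_end` (0-based
#'   half-open); alignment segments and placements both qualify.
#' @param ref_lengths named vector of reference sequence lengths.
#' @return list with `per_sequence` (tibble of covered fraction per
#'   sequence, including sequences with no intervals) and `mean_fraction`
#'   (unweighted mean across sequences).
#' @export
reference_coverage <- function(intervals, ref_lengths) {
  unknown <- setdiff(unique(intervals$ref_name), names(ref_lengths))
  if (length(unknown)) {
    stop_refscaf("interval on unknown reference sequence '%s'", unknown[1])
  }
  per <- lapply(names(ref_lengths), function(r) {
    x <- intervals[intervals$ref_name == r, , drop = FALSE]
    tibble::tibble(ref_name = r,
                   ref_length = as.numeric(ref_lengths[[r]]),
                   covered_fraction =
                     interval_union_width(x$ref_start, x$ref_end) /
                     as.numeric(ref_lengths[[r]]))
  })
  per <- do.call(rbind, per)
  list(per_sequence = per, mean_fraction = mean(per$covered_fraction))
}
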