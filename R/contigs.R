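# Contig construction: overlap clustering of reference placements and
# per-column majority consensus in the reference-projected frame.

CODE_BASES <- c("A", "C", "G", "T", "N", "-")

# 256-entry raw -> symbol code lookup (unknown symbols count as N).
base_code_table <- function() {
  tab <- rep(5L, 256L)
  tab[as.integer(charToRaw(paste(CODE_BASES, collapse = ""))) + 1L] <-
    seq_along(CODE_BASES)
  tab[as.integer(charToRaw("acgtn")) + 1L] <- c(1L, 2L, 3L, 4L, 5L)
  tab
}
.code_tab <- base_code_table()

str_codes <- function(x) .code_tab[as.integer(charToRaw(x)) + 1L]

#' Cluster placements that overlap by at least `min_overlap` bases
#'
#' Two placements are chained iff their reference intervals share at least
#' `min_overlap` bases; clusters are the connected components of that
#' relation.  Placements shorter than `min_overlap` can never chain and form
#' singleton clusters.
#'
#' @param pl placement tibble on a single reference sequence (sorted
#'   internally).
#' @param min_overlap minimum shared bases (default 50).
#' @return the placements sorted by `ref_start`, with an integer `cluster`
#'   column; cluster ids are dense and ordered by first appearance.
#' @export
group_placements <- function(pl, min_overlap = 50L) {
  if (length(unique(pl$ref_name)) > 1L) {
    stop_refscaf("group_placements: placements span multiple reference sequences")
  }
  if (nrow(pl) == 0L) {
    pl$cluster <- integer(0)
    return(pl)
  }
  ord <- order(pl$ref_start, pl$ref_end, pl$read_id)
  pl <- pl[ord, , drop = FALSE]
  s <- pl$ref_start
  e <- pl$ref_end
  n <- length(s)
  comp <- integer(n)                       # union-find parent as component id
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # Sweep: among placements wide enough to chain at all, the current open
  # component either absorbs the next placement (its running max end reaches
  # min_overlap into it) or can never connect to anything later and is
  # closed.  At most one component is ever open.
  wide <- (e - s) >= min_overlap
  cur <- 0L
  curmax <- -Inf
  for (i in seq_len(n)) {
    if (!wide[i]) next                     # can never share >= min_overlap
    if (cur > 0L && curmax >= s[i] + min_overlap) {
      parent[find(cur)] <- find(i)
      curmax <- max(curmax, e[i])
    } else {
      curmax <- e[i]
    }
    cur <- i
  }
  roots <- vapply(seq_len(n), find, integer(1))
  pl$cluster <- match(roots, unique(roots))
  pl
}

#' Call the consensus sequence of one placement cluster
#'
#' For every reference column covered by at least one placement the majority
#' projected symbol is emitted; a majority gap symbol (`-`) emits nothing and
#' is recorded as a deletion column.  Count ties are broken by (1) highest
#' summed base quality (when `proj_quals` are present), (2) the reference
#' base when a reference window is supplied, (3) the lexicographically
#' smallest symbol.
#'
#' @param cluster placement tibble forming one contiguous cluster.
#' @param reference_window optional reference base string covering the
#'   cluster anchor, used only for tie-breaking.
#' @param contig_id identifier for the resulting contig.
#' @return one-row contig tibble (see [refscaf-types]).
#' @export
consensus <- function(cluster, reference_window = NULL, contig_id = NULL) {
  if (nrow(cluster) == 0L) stop_refscaf("consensus of an empty cluster")
  ref <- cluster$ref_name[1]
  a0 <- min(cluster$ref_start)
  a1 <- max(cluster$ref_end)
  span <- a1 - a0
  contig_id <- contig_id %||% sprintf("%s:%d-%d", ref, a0, a1)
  lens <- cluster$ref_end - cluster$ref_start
  pos <- sequence(lens, from = cluster$ref_start - a0 + 1L)   # 1-based column
  code <- str_codes(paste(cluster$proj_bases, collapse = ""))
  cnt <- tabulate((pos - 1L) * 6L + code, nbins = 6L * span)
  m <- matrix(cnt, nrow = 6L)
  covered <- colSums(m) > 0L
  if (!all(covered)) {
    stop_refscaf("cluster %s has %d internal zero-coverage columns",
                 contig_id, sum(!covered))
  }
  win <- max.col(t(m), ties.method = "first")
  mx <- m[cbind(win, seq_len(span))]
  tied <- which(colSums(m == rep(mx, each = 6L)) > 1L)
  if (length(tied)) {
    win[tied] <- resolve_ties(m, tied, cluster, pos, code, a0,
                              reference_window)
  }
  is_gap <- win == 6L
  tibble::tibble(
    contig_id = contig_id,
    seq = paste(CODE_BASES[win[!is_gap]], collapse = ""),
    ref_name = ref, ref_start = a0, ref_end = a1,
    support = list(cluster$read_id),
    status = "unconfirmed",
    del_cols = list(which(is_gap) - 1L))
}

# Quality-sum / reference-base / lexicographic tie resolution for the
# (rare) columns whose top count is shared.
resolve_ties <- function(m, tied, cluster, pos, code, a0, reference_window) {
  have_q <- "proj_quals" %in% names(cluster)
  qsum <- NULL
  if (have_q) {
    colmap <- match(pos, tied)
    inidx <- !is.na(colmap)
    q <- as.integer(charToRaw(paste(cluster$proj_quals, collapse = ""))) - 33L
    key <- (colmap[inidx] - 1L) * 6L + code[inidx]
    agg <- rowsum(q[inidx], key)
    qsum <- numeric(6L * length(tied))
    qsum[as.integer(rownames(agg))] <- agg[, 1]
    qsum <- matrix(qsum, nrow = 6L)
  }
  lex_rank <- rank(CODE_BASES)                       # '-' < A < C < G < N < T
  out <- integer(length(tied))
  for (k in seq_along(tied)) {
    col <- tied[k]
    cand <- which(m[, col] == max(m[, col]))
    if (have_q && length(cand) > 1L) {
      cand <- cand[qsum[cand, k] == max(qsum[cand, k])]
    }
    if (!is.null(reference_window) && length(cand) > 1L) {
      rb <- toupper(substr(reference_window, col, col))
      hit <- cand[CODE_BASES[cand] == rb]
      if (length(hit)) cand <- hit
    }
    out[k] <- cand[order(lex_rank[cand])][1]
  }
  out
}

#' Build contigs from placements
#'
#' Placements are clustered per reference sequence with
#' [group_placements()] and each cluster is collapsed with [consensus()].
#'
#' @param pl placement tibble (any number of reference sequences).
#' @param min_overlap minimum stitching overlap in bp (default 50).
#' @param ref_lengths optional named vector of reference sequence lengths for
#'   the coverage summary (defaults to the largest placement end seen).
#' @param min_support drop contigs supported by fewer reads (default 1, i.e.
#'   keep all).
#' @param reference optional named character vector of reference sequences
#'   used for consensus tie-breaking.
#' @return list with `contigs` (contig tibble, ids `ctg000001`... ordered by
#'   locus) and `coverage` (per reference sequence: fraction covered by
#'   placements and by contig anchors).
#' @export
build_contigs <- function(pl, min_overlap = 50L, ref_lengths = NULL,
                          min_support = 1L, reference = NULL) {
  refs <- unique(pl$ref_name)
  all_contigs <- list()
  cov_rows <- list()
  for (r in sort(refs)) {
    sub <- group_placements(pl[pl$ref_name == r, , drop = FALSE], min_overlap)
    refseq <- if (!is.null(reference)) reference[[r]] else NULL
    cl_sizes <- tabulate(sub$cluster)
    singles <- which(cl_sizes == 1L)
    multis <- which(cl_sizes > 1L)
    rows <- vector("list", length(cl_sizes))
    if (length(singles)) {
      idx <- which(sub$cluster %in% singles)
      idx <- idx[order(sub$cluster[idx])]
      one <- sub[idx, , drop = FALSE]
      gaps <- gregexpr("-", one$proj_bases, fixed = TRUE)
      single_tbl <- tibble::tibble(
        contig_id = sprintf("%s:%d-%d", r, one$ref_start, one$ref_end),
        seq = gsub("-", "", one$proj_bases, fixed = TRUE),
        ref_name = r, ref_start = one$ref_start, ref_end = one$ref_end,
        support = as.list(one$read_id),
        status = "unconfirmed",
        del_cols = lapply(gaps, function(g) {
          if (g[1] == -1L) integer(0) else as.integer(g) - 1L
        }))
      rows[sort(singles)] <- split(single_tbl, seq_len(nrow(single_tbl)))
    }
    for (cl in multis) {
      w <- if (!is.null(refseq)) {
        sel <- sub$cluster == cl
        substr(refseq, min(sub$ref_start[sel]) + 1L, max(sub$ref_end[sel]))
      } else NULL
      rows[[cl]] <- consensus(sub[sub$cluster == cl, , drop = FALSE],
                              reference_window = w)
    }
    ctg <- do.call(rbind, rows)
    all_contigs[[r]] <- ctg
    rl <- if (!is.null(ref_lengths) && r %in% names(ref_lengths)) {
      as.numeric(ref_lengths[[r]])
    } else max(sub$ref_end)
    cov_rows[[r]] <- tibble::tibble(
      ref_name = r, ref_length = rl,
      placed_fraction = interval_union_width(sub$ref_start, sub$ref_end) / rl,
      contig_fraction = interval_union_width(ctg$ref_start, ctg$ref_end) / rl)
  }
  contigs <- do.call(rbind, all_contigs)
  contigs <- contigs[order(contigs$ref_name, contigs$ref_start,
                           contigs$ref_end), , drop = FALSE]
  keep <- lengths(contigs$support) >= min_support
  contigs <- contigs[keep, , drop = FALSE]
  contigs$contig_id <- sprintf("ctg%06d", seq_len(nrow(contigs)))
  list(contigs = contigs, coverage = do.call(rbind, cov_rows))
}

#' Collect the unmapped reads for external de novo assembly
#'
#' @param all_reads read tibble.
#' @param unmapped_ids ids returned by [read_alignments()].
#' @return the unmapped reads in their original order; ids not present in
#'   `all_reads` raise a warning and are counted in attribute `n_missing`.
#' @export
collect_unmapped <- function(all_reads, unmapped_ids) {
  hit <- unmapped_ids %in% all_reads$read_id
  if (any(!hit)) {
    warning(sprintf("%d unmapped id(s) not found in the read set", sum(!hit)),
            call. = FALSE)
  }
  out <- all_reads[all_reads$read_id %in% unmapped_ids, , drop = FALSE]
  attr(out, "n_missing") <- sum(!hit)
  out
}
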