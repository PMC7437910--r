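# Mate-pair bundling and greedy path-merging scaffolding.

#' Estimate the gap implied by one spanning link
#'
#' Standard insert-size arithmetic: `insert_mean - d_a - d_b`, where each
#' `d` is the distance from a mate's outer coordinate to the gap-facing end
#' of its contig.  Negative values imply overlapping contigs.
#'
#' @param insert_mean library insert mean (bp).
#' @param d_a,d_b outer-coordinate distances (bp).
#' @return gap estimate in bp (real, possibly negative); vectorised.
#' @export
estimate_gap <- function(insert_mean, d_a, d_b) insert_mean - d_a - d_b

#' Bundle spanning links into weighted contig-end edges
#'
#' Links are grouped by contig pair and orientation class (which contig end
#' faces which).  Each group becomes one edge with `weight` = link count,
#' `gap_mean` and `gap_sd` over the per-link gap estimates.  When several
#' orientation classes exist for one contig pair only the heaviest class is
#' kept; the links of the losing classes are counted in `n_discarded`.
#'
#' @param links classified links ([classify_links()]); only `spanning` rows
#'   are used.
#' @return edge tibble: `contig_a`, `contig_b` (lexicographically ordered),
#'   `end_a`, `end_b` (`L`/`R`, the gap-facing end of each contig),
#'   `weight`, `gap_mean`, `gap_sd`, `n_discarded`.
#' @export
bundle_links <- function(links) {
  sp <- links[links$kind == "spanning", , drop = FALSE]
  if (nrow(sp) == 0L) {
    return(tibble::tibble(contig_a = character(0), contig_b = character(0),
                          end_a = character(0), end_b = character(0),
                          weight = integer(0), gap_mean = numeric(0),
                          gap_sd = numeric(0), n_discarded = integer(0)))
  }
  # normalise: contig_a < contig_b; the upstream contig faces with its R end,
  # the downstream one with its L end
  a_first <- sp$contig_up < sp$contig_down
  contig_a <- ifelse(a_first, sp$contig_up, sp$contig_down)
  contig_b <- ifelse(a_first, sp$contig_down, sp$contig_up)
  end_a <- ifelse(a_first, "R", "L")
  end_b <- ifelse(a_first, "L", "R")
  key <- paste(contig_a, contig_b, end_a, end_b, sep = "\r")
  groups <- split(seq_len(nrow(sp)), key)
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    f <- strsplit(k, "\r", fixed = TRUE)[[1]]
    tibble::tibble(contig_a = f[1], contig_b = f[2], end_a = f[3],
                   end_b = f[4], weight = length(idx),
                   gap_mean = mean(sp$gap[idx]),
                   gap_sd = stats::sd(sp$gap[idx]), n_discarded = 0L)
  })
  edges <- do.call(rbind, rows)
  # keep only the heaviest orientation class per contig pair
  pair <- paste(edges$contig_a, edges$contig_b, sep = "\r")
  o <- order(pair, -edges$weight, edges$end_a, edges$end_b)
  edges <- edges[o, , drop = FALSE]
  pair <- pair[o]
  keep <- !duplicated(pair)
  lost <- tapply(edges$weight * as.integer(!keep), pair, sum)
  edges <- edges[keep, , drop = FALSE]
  edges$n_discarded <- as.integer(lost[paste(edges$contig_a, edges$contig_b,
                                             sep = "\r")])
  edges[order(edges$contig_a, edges$contig_b), , drop = FALSE]
}

#' Drop transitive skip edges from a scaffold graph
#'
#' An edge A-C is transitive when some contig B carries edges A-B and B-C
#' chaining through compatible ends and the A-C gap estimate agrees with
#' `gap(A,B) + length(B) + gap(B,C)` within `n_sd` combined standard
#' deviations (with a floor of `tol_floor` bp).  Such edges are long-range
#' restatements of the two short-range joins; removing them prevents a heavy
#' skip edge from stealing the path terminus of a short intermediate contig.
#'
#' @param edges edge tibble from [bundle_links()].
#' @param contig_lengths named vector of contig sequence lengths.
#' @param n_sd agreement tolerance in combined SDs (default 3).
#' @param tol_floor minimum tolerance in bp (default 200).
#' @return the edges with transitive rows removed.
#' @export
reduce_transitive <- function(edges, contig_lengths, n_sd = 3,
                              tol_floor = 200) {
  if (nrow(edges) < 3L) return(edges)
  # directed view: each edge twice, as (from, from_end) -> (to, to_end)
  dir_from <- c(edges$contig_a, edges$contig_b)
  dir_fend <- c(edges$end_a, edges$end_b)
  dir_to <- c(edges$contig_b, edges$contig_a)
  dir_tend <- c(edges$end_b, edges$end_a)
  dir_gap <- rep(edges$gap_mean, 2L)
  dir_sd <- rep(edges$gap_sd, 2L)
  by_from <- split(seq_along(dir_from), dir_from)
  flip <- c(L = "R", R = "L")
  drop <- rep(FALSE, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges$contig_a[i]; ea <- edges$end_a[i]
    c_ <- edges$contig_b[i]; ec <- edges$end_b[i]
    for (j in by_from[[a]]) {                      # A -(E1)-> B
      if (dir_fend[j] != ea) next
      b <- dir_to[j]
      if (b == c_) next
      for (k in by_from[[b]]) {                    # B -(E2)-> C
        if (dir_to[k] != c_ || dir_tend[k] != ec) next
        if (dir_fend[k] != flip[[dir_tend[j]]]) next
        lb <- contig_lengths[[b]]
        if (is.null(lb) || is.na(lb)) next
        implied <- dir_gap[j] + lb + dir_gap[k]
        tol <- max(tol_floor,
                   n_sd * sqrt(sum(c(dir_sd[j], dir_sd[k],
                                     edges$gap_sd[i])^2, na.rm = TRUE)))
        if (abs(edges$gap_mean[i] - implied) <= tol) drop[i] <- TRUE
        if (drop[i]) break
      }
      if (drop[i]) break
    }
  }
  edges[!drop, , drop = FALSE]
}

#' Greedy path-merging of contigs into scaffold paths
#'
#' Edges below `min_weight` are discarded; when contig lengths are supplied,
#' transitive skip edges are removed with [reduce_transitive()].  The rest
#' are processed by weight (descending), then gap SD (ascending, unknown
#' last), then contig pair id.  An edge is accepted iff the two contig ends
#' it joins are currently free path termini in different paths; accepting it
#' merges the two paths (one may be reversed, which flips its contigs'
#' orientations consistently).  Contigs joined by no accepted edge come out
#' as singleton paths.
#'
#' @param contig_ids character vector of all contig ids.
#' @param edges edge tibble from [bundle_links()].
#' @param min_weight minimum supporting link count (default 3).
#' @param contig_lengths optional named vector of contig sequence lengths,
#'   enabling transitive-edge reduction.
#' @return tibble of path elements: `scaffold_id`, `element` (1-based order
#'   within the scaffold), `contig_id`, `orientation` (`+`/`-`), `gap_after`
#'   (bp, `NA` on the last element).
#' @export
greedy_path_merge <- function(contig_ids, edges, min_weight = 3L,
                              contig_lengths = NULL) {
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  if (!is.null(contig_lengths)) {
    edges <- reduce_transitive(edges, contig_lengths)
  }
  sdv <- edges$gap_sd
  sdv[is.na(sdv)] <- Inf
  o <- order(-edges$weight, sdv, edges$contig_a, edges$contig_b,
             edges$end_a, edges$end_b)
  edges <- edges[o, , drop = FALSE]

  paths <- lapply(contig_ids, function(id) {
    list(ids = id, orient = "+", gaps = numeric(0))
  })
  where <- stats::setNames(seq_along(contig_ids), contig_ids)

  # is local end `end` of contig `id` a free terminus of its path?
  terminus <- function(p, id, end) {
    k <- length(p$ids)
    if (p$ids[1] == id) {
      outward <- if (p$orient[1] == "+") "L" else "R"
      if (outward == end) return("left")
    }
    if (p$ids[k] == id) {
      outward <- if (p$orient[k] == "+") "R" else "L"
      if (outward == end) return("right")
    }
    NULL
  }
  rev_path <- function(p) {
    list(ids = rev(p$ids),
         orient = rev(chartr("+-", "-+", p$orient)),
         gaps = rev(p$gaps))
  }
  for (i in seq_len(nrow(edges))) {
    ia <- where[[edges$contig_a[i]]]
    ib <- where[[edges$contig_b[i]]]
    if (ia == ib) next                              # would create a cycle
    pa <- paths[[ia]]
    pb <- paths[[ib]]
    ta <- terminus(pa, edges$contig_a[i], edges$end_a[i])
    tb <- terminus(pb, edges$contig_b[i], edges$end_b[i])
    if (is.null(ta) || is.null(tb)) next            # end not free
    if (ta == "left") pa <- rev_path(pa)            # a's end must face right
    if (tb == "right") pb <- rev_path(pb)           # b's end must face left
    merged <- list(ids = c(pa$ids, pb$ids),
                   orient = c(pa$orient, pb$orient),
                   gaps = c(pa$gaps, edges$gap_mean[i], pb$gaps))
    paths[[ia]] <- merged
    paths[[ib]] <- NULL_PATH
    where[merged$ids] <- ia
  }
  live <- which(!vapply(paths, is.null, logical(1)) &
                  vapply(paths, function(p) length(p$ids) > 0L, logical(1)))
  rows <- lapply(seq_along(live), function(k) {
    p <- paths[[live[k]]]
    tibble::tibble(scaffold_id = sprintf("scaffold%05d", k),
                   element = seq_along(p$ids),
                   contig_id = p$ids,
                   orientation = p$orient,
                   gap_after = c(p$gaps, NA_real_))
  })
  do.call(rbind, rows)
}

NULL_PATH <- list(ids = character(0), orient = character(0), gaps = numeric(0))

#' Emit scaffold sequences and AGP layout from paths
#'
#' Contigs are concatenated in path order; reverse-oriented contigs are
#' reverse-complemented; consecutive contigs are separated by an `N` run of
#' length `max(round(gap_after), min_gap)`.
#'
#' @param paths path tibble from [greedy_path_merge()].
#' @param contig_seqs named character vector of contig sequences.
#' @param min_gap minimum emitted gap length in bp (default 10).
#' @return list with `seqs` (named character) and `agp` (AGP v2.1 tibble:
#'   `W` component lines and `N` gap lines).
#' @export
emit_scaffolds <- function(paths, contig_seqs, min_gap = 10L) {
  missing <- setdiff(paths$contig_id, names(contig_seqs))
  if (length(missing)) stop_refscaf("no sequence for contig '%s'", missing[1])
  seqs <- character(0)
  agp_rows <- list()
  for (sid in unique(paths$scaffold_id)) {
    p <- paths[paths$scaffold_id == sid, , drop = FALSE]
    p <- p[order(p$element), , drop = FALSE]
    comp <- unname(contig_seqs[p$contig_id])
    neg <- p$orientation == "-"
    if (any(neg)) comp[neg] <- revcomp(comp[neg])
    gaps <- pmax(round(p$gap_after[-nrow(p)]), min_gap)
    pieces <- character(2L * nrow(p) - 1L)
    pieces[seq(1L, length(pieces), 2L)] <- comp
    if (nrow(p) > 1L) pieces[seq(2L, length(pieces), 2L)] <- strrep("N", gaps)
    seqs[sid] <- paste(pieces, collapse = "")
    at <- 1L
    part <- 1L
    for (k in seq_len(nrow(p))) {
      w <- nchar(comp[k])
      agp_rows[[length(agp_rows) + 1L]] <- tibble::tibble(
        object = sid, object_beg = at, object_end = at + w - 1L,
        part_number = part, component_type = "W",
        col6 = p$contig_id[k], col7 = "1", col8 = as.character(w),
        col9 = p$orientation[k])
      at <- at + w
      part <- part + 1L
      if (k < nrow(p)) {
        g <- as.integer(gaps[k])
        agp_rows[[length(agp_rows) + 1L]] <- tibble::tibble(
          object = sid, object_beg = at, object_end = at + g - 1L,
          part_number = part, component_type = "N",
          col6 = as.character(g), col7 = "scaffold", col8 = "yes",
          col9 = "paired-ends")
        at <- at + g
        part <- part + 1L
      }
    }
  }
  list(seqs = seqs, agp = do.call(rbind, agp_rows))
}
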