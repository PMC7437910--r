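# Truth-derived alignment of simulated reads and truth-based evaluation of
# the assembled output.

#' Place (possibly trimmed) simulated reads on the reference from truth
#'
#' Reads are positioned through the donor/reference coordinate maps instead
#' of an external mapper, reproducing the "mapped reads" input boundary
#' hermetically.  Trimming is respected: a trimmed read is a 3' prefix, i.e.
#' the retained donor interval is the left part for `+` reads and the right
#' part for `-` reads.  Reads overlapping a novel (donor-only) segment have
#' no reference locus and are returned as unmapped — exactly the reads a
#' real mapper would fail to place.
#'
#' @param reads read tibble (trimmed or not); every `read_id` must appear in
#'   `truth`.
#' @param genomes result of [simulate_genomes()].
#' @param truth truth table from [simulate_reads()].
#' @return list with `placements` (reference-projected, with `proj_quals`,
#'   `run_label`, `mate_role`) and `unmapped_ids`.
#' @export
align_truth <- function(reads, genomes, truth) {
  ti <- match(reads$read_id, truth$read_id)
  if (anyNA(ti)) {
    stop_refscaf("read '%s' not present in the truth table",
                 reads$read_id[which(is.na(ti))[1]])
  }
  tr <- truth[ti, , drop = FALSE]
  l <- nchar(reads$bases)
  s <- ifelse(tr$strand == "+", tr$donor_start, tr$donor_end - l)
  e <- ifelse(tr$strand == "+", tr$donor_start + l, tr$donor_end)

  nov <- genomes$novel
  unmapped <- rep(FALSE, nrow(reads))
  if (nrow(nov) > 0L) {
    n_before_end <- findInterval(e - 0.5, nov$donor_start)
    n_closed <- findInterval(s, nov$donor_end)
    unmapped <- n_before_end > n_closed
  }

  maps <- genomes$maps
  idx_m <- which(!unmapped)
  ob <- reads$bases[idx_m]
  oq <- reads$quals[idx_m]
  neg <- tr$strand[idx_m] == "-"
  if (any(neg)) {
    ob[neg] <- revcomp(ob[neg])
    oq[neg] <- str_reverse(oq[neg])
  }
  sm <- s[idx_m]
  em <- e[idx_m]
  # reads whose span contains no indel edit take the constant-offset path
  ins_p <- maps$ins_pos
  n_ins <- findInterval(em - 1L, ins_p) - findInterval(sm, ins_p)
  n_del <- findInterval(em - 0.5, maps$del_start) -
    findInterval(sm, maps$del_end)
  slow <- which(n_ins > 0L | n_del > 0L)

  rs <- maps$d2r(sm)
  re <- maps$d2r(em - 1L) + 1L
  proj <- ob
  pq <- oq
  gap_raw <- charToRaw("-")
  bang_raw <- charToRaw("!")
  for (i in slow) {
    pos <- sm[i]:(em[i] - 1L)
    di <- findInterval(pos, maps$del_start)
    deleted <- di > 0L & pos < maps$del_end[pmax(di, 1L)]
    kept <- which(!deleted)
    rc <- maps$d2r(pos[kept])
    a <- rc[1L]
    b <- rc[length(rc)] + 1L
    span <- b - a
    pr <- rep(gap_raw, span)
    qr <- rep(bang_raw, span)
    br <- charToRaw(ob[i])
    qb <- charToRaw(oq[i])
    pr[rc - a + 1L] <- br[kept]
    qr[rc - a + 1L] <- qb[kept]
    rs[i] <- a
    re[i] <- b
    proj[i] <- rawToChar(pr)
    pq[i] <- rawToChar(qr)
  }
  pl <- placements(read_id = reads$read_id[idx_m], ref_name = "ref1",
                   ref_start = rs, ref_end = re,
                   strand = tr$strand[idx_m], proj_bases = proj,
                   mapq = 60L, proj_quals = pq,
                   run_label = tr$run_label[idx_m],
                   mate_role = tr$mate_role[idx_m])
  list(placements = pl, unmapped_ids = reads$read_id[unmapped])
}

#' Evaluate an assembly against the simulation truth
#'
#' Three recovery measures:
#' * **donor coverage**: fraction of the donor covered by the contig
#'   anchors, mapped through the reference-to-donor coordinate map;
#' * **consensus identity**: over all donor-backed reference columns inside
#'   contig anchors, the fraction whose consensus symbol equals the donor
#'   base (a consensus deletion at a donor-backed column counts as a miss);
#' * **adjacency accuracy**: among truly neighbouring contig pairs
#'   (consecutive non-contained anchors, restricted to pairs supported by a
#'   bundled edge of weight >= `min_weight` when `edges` are given), the
#'   fraction joined consecutively and in consistent orientation in the
#'   scaffold paths.  Realized joins between non-neighbouring contigs are
#'   counted as false joins; among those, joins whose true donor separation
#'   exceeds three insert SDs of the widest library are *far* false joins
#'   (a join that skips a short intermediate contig but places its flanks at
#'   the right distance is counted as false but not far).
#'
#' @param contigs contig tibble.
#' @param paths scaffold paths from [greedy_path_merge()] (may be NULL to
#'   skip adjacency).
#' @param genomes result of [simulate_genomes()].
#' @param edges optional bundled edges used to restrict evaluated pairs.
#' @param min_weight link-support threshold used for the restriction.
#' @return list with `coverage_pct`, `identity_pct`, `adjacency_pct`,
#'   `n_true_pairs`, `n_false_joins`, `n_false_joins_far`, `n_contigs`.
#' @export
truth_evaluate <- function(contigs, paths, genomes, edges = NULL,
                           min_weight = 3L) {
  maps <- genomes$maps
  donor_raw <- charToRaw(genomes$donor)

  ds <- maps$r2d(contigs$ref_start)
  de <- maps$r2d(contigs$ref_end - 1L) + 1L
  coverage <- interval_union_width(ds, de) / genomes$donor_len

  irs <- maps$ins_ref_start
  ilen <- maps$ins_ref_len
  matches <- 0
  denom <- 0
  for (i in seq_len(nrow(contigs))) {
    a0 <- contigs$ref_start[i]
    cols <- a0:(contigs$ref_end[i] - 1L)
    ii <- findInterval(cols, irs)
    backed <- !(ii > 0L & cols < irs[pmax(ii, 1L)] + ilen[pmax(ii, 1L)])
    if (length(irs) == 0L) backed <- rep(TRUE, length(cols))
    rel <- cols - a0
    dc <- contigs$del_cols[[i]]
    if (length(dc)) {
      j <- findInterval(rel, dc)
      isdel <- j > 0L & dc[pmax(j, 1L)] == rel
      charidx <- rel - findInterval(rel - 0.5, dc)
    } else {
      isdel <- rep(FALSE, length(rel))
      charidx <- rel
    }
    seq_raw <- charToRaw(contigs$seq[i])
    ok <- backed & !isdel
    dpos <- maps$r2d(cols[ok])
    matches <- matches + sum(seq_raw[charidx[ok] + 1L] ==
                               donor_raw[dpos + 1L])
    denom <- denom + sum(backed)
  }
  identity <- if (denom > 0) matches / denom else NA_real_

  # true neighbours: consecutive non-contained anchors in reference order
  o <- order(contigs$ref_name, contigs$ref_start, -contigs$ref_end)
  cc <- contigs[o, , drop = FALSE]
  contained <- logical(nrow(cc))
  for (r in unique(cc$ref_name)) {
    idx <- which(cc$ref_name == r)
    run_max <- cummax(c(-1L, cc$ref_end[idx]))[seq_along(idx)]
    contained[idx] <- cc$ref_end[idx] <= run_max
  }
  nc <- cc[!contained, , drop = FALSE]
  true_pairs <- NULL
  if (nrow(nc) > 1L) {
    adj <- nc$ref_name[-1L] == nc$ref_name[-nrow(nc)]
    true_pairs <- tibble::tibble(a = nc$contig_id[-nrow(nc)][adj],
                                 b = nc$contig_id[-1L][adj])
  }
  pkey <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  eval_pairs <- true_pairs
  if (!is.null(edges) && !is.null(true_pairs) && nrow(true_pairs)) {
    supported <- pkey(edges$contig_a[edges$weight >= min_weight],
                      edges$contig_b[edges$weight >= min_weight])
    eval_pairs <- true_pairs[pkey(true_pairs$a, true_pairs$b) %in% supported, ,
                             drop = FALSE]
  }
  adjacency <- NA_real_
  n_false <- NA_integer_
  n_false_far <- NA_integer_
  if (!is.null(paths)) {
    joins <- NULL
    for (sid in unique(paths$scaffold_id)) {
      p <- paths[paths$scaffold_id == sid, , drop = FALSE]
      p <- p[order(p$element), , drop = FALSE]
      if (nrow(p) < 2L) next
      joins <- rbind(joins, tibble::tibble(
        a = p$contig_id[-nrow(p)], oa = p$orientation[-nrow(p)],
        b = p$contig_id[-1L], ob = p$orientation[-1L]))
    }
    correct_join <- function(a, b) {
      if (is.null(joins)) return(FALSE)
      any(joins$a == a & joins$b == b & joins$oa == "+" & joins$ob == "+") ||
        any(joins$a == b & joins$b == a & joins$oa == "-" & joins$ob == "-")
    }
    if (!is.null(eval_pairs) && nrow(eval_pairs)) {
      hit <- mapply(correct_join, eval_pairs$a, eval_pairs$b)
      adjacency <- mean(hit)
    } else {
      adjacency <- 1
    }
    if (!is.null(joins)) {
      truth_keys <- if (!is.null(true_pairs)) pkey(true_pairs$a, true_pairs$b)
        else character(0)
      false_rows <- which(!pkey(joins$a, joins$b) %in% truth_keys)
      n_false <- length(false_rows)
      far_cut <- 3 * max(genomes$config$libraries$insert_sd)
      dstart <- stats::setNames(ds, contigs$contig_id)
      dend <- stats::setNames(de, contigs$contig_id)
      n_false_far <- 0L
      for (fr in false_rows) {
        a <- joins$a[fr]; b <- joins$b[fr]
        sep <- if (joins$oa[fr] == "+" && joins$ob[fr] == "+") {
          dstart[[b]] - dend[[a]]
        } else if (joins$oa[fr] == "-" && joins$ob[fr] == "-") {
          dstart[[a]] - dend[[b]]
        } else Inf                       # flipped reference-anchored contig
        if (abs(sep) > far_cut) n_false_far <- n_false_far + 1L
      }
    } else {
      n_false <- 0L
      n_false_far <- 0L
    }
  }
  list(coverage_pct = 100 * coverage,
       identity_pct = 100 * identity,
       adjacency_pct = 100 * adjacency,
       n_true_pairs = if (is.null(eval_pairs)) 0L else nrow(eval_pairs),
       n_false_joins = n_false,
       n_false_joins_far = n_false_far,
       n_contigs = nrow(contigs))
}
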