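# Mate-pair link classification and contig confirmation.

#' Lift reference placements into contig coordinates
#'
#' Each placement is assigned to the contig whose anchor it intersects; a
#' placement straddling two contigs goes to the one with the larger
#' intersection (ties to the lexicographically smaller `contig_id`).
#' Offsets are corrected for consensus deletion columns preceding them, so
#' they index into the contig *sequence*.  Placements intersecting no contig
#' are dropped and counted in attribute `n_dropped`.
#'
#' @param pl placement tibble.
#' @param contigs contig tibble from [build_contigs()].
#' @return tibble with `read_id`, `contig_id`, `cstart`, `cend` (0-based
#'   half-open in contig sequence coordinates), `strand`, and any
#'   `run_label`/`mate_role` columns carried through.
#' @export
lift_to_contigs <- function(pl, contigs) {
  keep_cols <- intersect(c("run_label", "mate_role"), names(pl))
  out <- list()
  n_dropped <- 0L
  for (r in unique(pl$ref_name)) {
    p <- pl[pl$ref_name == r, , drop = FALSE]
    ctg <- contigs[contigs$ref_name == r, , drop = FALSE]
    if (nrow(ctg) == 0L) {
      n_dropped <- n_dropped + nrow(p)
      next
    }
    q <- IRanges::IRanges(p$ref_start + 1L, p$ref_end)
    s <- IRanges::IRanges(ctg$ref_start + 1L, ctg$ref_end)
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    inter <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    # best contig per placement: widest intersection, then smaller id
    o <- order(qh, -inter, ctg$contig_id[sh])
    first <- !duplicated(qh[o])
    qi <- qh[o][first]
    ci <- sh[o][first]
    n_dropped <- n_dropped + (nrow(p) - length(qi))
    p <- p[qi, , drop = FALSE]
    cref <- ctg[ci, , drop = FALSE]
    rel_s <- pmax(p$ref_start - cref$ref_start, 0L)
    rel_e <- pmin(p$ref_end, cref$ref_end) - cref$ref_start
    cstart <- rel_s
    cend <- rel_e
    for (j in which(lengths(ctg$del_cols) > 0L)) {    # per-contig adjustment
      rows <- which(ci == j)
      if (!length(rows)) next
      d <- ctg$del_cols[[j]]
      cstart[rows] <- rel_s[rows] - findInterval(rel_s[rows] - 0.5, d)
      cend[rows] <- rel_e[rows] - findInterval(rel_e[rows] - 0.5, d)
    }
    res <- tibble::tibble(read_id = p$read_id,
                          contig_id = cref$contig_id,
                          cstart = as.integer(cstart),
                          cend = as.integer(cend),
                          strand = p$strand)
    for (k in keep_cols) res[[k]] <- p[[k]]
    out[[r]] <- res
  }
  res <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(read_id = character(0), contig_id = character(0),
                   cstart = integer(0), cend = integer(0),
                   strand = character(0))
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Classify mate-pair links against contigs
#'
#' A pair with both mates on one contig is `intra`.  For a cross-contig pair
#' the library chemistry fixes which mate is upstream (see below); the pair
#' is `spanning` when each mate then lies within `end_window` of the contig
#' end facing the implied gap and the strand combination is one the library
#' can produce (suffix-prefix geometry); any other cross-contig geometry is
#' `conflicting`.  For spanning links the gap is
#' estimated as `insert_mean - d_up - d_down` where each `d` is the distance
#' from the mate's outer coordinate to the gap-facing contig end.
#'
#' @param lifted lifted placements from [lift_to_contigs()] carrying
#'   `run_label` (matched against library names) and `mate_role`.
#' @param libraries tibble of [library_spec()] rows.
#' @param contigs contig tibble (for contig sequence lengths).
#' @param end_window distance window in bp; the default per link is
#'   `insert_mean + 4 * insert_sd + 50` of its library — the full insert
#'   support (inserts are modelled as truncated at 4 SD) plus the largest
#'   anchor overlap two abutting contigs can share without having been
#'   stitched.
#' @return one row per complete pair: `pair_id`, `kind`
#'   (`intra`/`spanning`/`conflicting`), contigs involved, and for spanning
#'   links the upstream/downstream contig, gap-facing distances and gap
#'   estimate.
#' @export
classify_links <- function(lifted, libraries, contigs, end_window = NULL) {
  if (!all(c("mate_role", "run_label") %in% names(lifted))) {
    return(empty_links())
  }
  m <- lifted[lifted$mate_role %in% c("mate_first", "mate_second"), ,
              drop = FALSE]
  if (nrow(m) == 0L) return(empty_links())
  stem <- pair_stem(m$read_id)
  a <- m[m$mate_role == "mate_first", , drop = FALSE]
  b <- m[m$mate_role == "mate_second", , drop = FALSE]
  sa <- pair_stem(a$read_id)
  sb <- pair_stem(b$read_id)
  common <- intersect(sa, sb)
  a <- a[match(common, sa), , drop = FALSE]
  b <- b[match(common, sb), , drop = FALSE]
  if (length(common) == 0L) return(empty_links())

  li <- match(a$run_label, libraries$name)
  if (anyNA(li)) {
    stop_refscaf("no library spec for run '%s'", a$run_label[which(is.na(li))[1]])
  }
  mean_i <- libraries$insert_mean[li]
  sd_i <- libraries$insert_sd[li]
  orient <- libraries$orientation[li]
  w <- if (is.null(end_window)) mean_i + 4 * sd_i + 50 else rep(end_window,
                                                                length(li))
  clen <- stats::setNames(nchar(contigs$seq), contigs$contig_id)
  len_a <- clen[a$contig_id]
  len_b <- clen[b$contig_id]

  # The upstream mate is fixed by the chemistry: the first mate sits at the
  # fragment 5' end, so on a same-strand library a "+/+" pair has the first
  # mate upstream and a "-/-" pair the second; on an inward library the "+"
  # mate is upstream.  Strand combinations a library cannot produce are
  # conflicting outright.
  ok_orient <- ifelse(orient == "same", a$strand == b$strand,
                      a$strand != b$strand)
  a_up <- a$strand == "+"
  d_up <- ifelse(a_up, len_a - a$cstart, len_b - b$cstart)
  d_dn <- ifelse(a_up, b$cend, a$cend)
  ok <- ok_orient & d_up <= w & d_dn <= w

  same <- a$contig_id == b$contig_id
  kind <- ifelse(same, "intra", ifelse(ok, "spanning", "conflicting"))
  up <- ifelse(a_up, a$contig_id, b$contig_id)
  dn <- ifelse(a_up, b$contig_id, a$contig_id)
  span <- kind == "spanning"
  tibble::tibble(
    pair_id = common,
    kind = kind,
    contig_a = a$contig_id, contig_b = b$contig_id,
    contig_up = ifelse(span, up, NA_character_),
    contig_down = ifelse(span, dn, NA_character_),
    d_up = ifelse(span, d_up, NA_real_),
    d_dn = ifelse(span, d_dn, NA_real_),
    gap = ifelse(span, estimate_gap(mean_i, d_up, d_dn), NA_real_),
    library = libraries$name[li],
    insert_mean = mean_i, insert_sd = sd_i)
}

#' Classify a single mate pair
#'
#' Convenience wrapper over [classify_links()] for one lifted pair.
#'
#' @param pair two-row lifted placement tibble (one `mate_first`, one
#'   `mate_second`).
#' @inheritParams classify_links
#' @return one-row link tibble.
#' @export
classify_link <- function(pair, libraries, contigs, end_window = NULL) {
  stopifnot(nrow(pair) == 2L)
  classify_links(pair, libraries, contigs, end_window)
}

empty_links <- function() {
  tibble::tibble(pair_id = character(0), kind = character(0),
                 contig_a = character(0), contig_b = character(0),
                 contig_up = character(0), contig_down = character(0),
                 d_up = numeric(0), d_dn = numeric(0), gap = numeric(0),
                 library = character(0), insert_mean = numeric(0),
                 insert_sd = numeric(0))
}

#' Confirm contigs from classified mate links
#'
#' A contig is `confirmed` when at least `min_support` intra links lie on it
#' and no more than `max_conflicts` conflicting links touch it; any contig
#' touched by more than `max_conflicts` conflicting links is `conflicted`;
#' everything else stays `unconfirmed`.
#'
#' @param contigs contig tibble.
#' @param links classified links from [classify_links()].
#' @param min_support minimum intra-link count (default 3).
#' @param max_conflicts tolerated conflicting links (default 0).
#' @return the contigs with `status` set.
#' @export
confirm_contigs <- function(contigs, links, min_support = 3L,
                            max_conflicts = 0L) {
  intra <- links[links$kind == "intra", , drop = FALSE]
  confl <- links[links$kind == "conflicting", , drop = FALSE]
  n_intra <- table(intra$contig_a)
  n_confl <- table(c(confl$contig_a, confl$contig_b))
  ni <- as.integer(n_intra[contigs$contig_id])
  nc <- as.integer(n_confl[contigs$contig_id])
  ni[is.na(ni)] <- 0L
  nc[is.na(nc)] <- 0L
  contigs$status <- ifelse(nc > max_conflicts, "conflicted",
                           ifelse(ni >= min_support, "confirmed",
                                  "unconfirmed"))
  contigs
}
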