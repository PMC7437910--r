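#' Read coordinate SAM alignments into placements
#'
#' Mapped records are projected onto the reference through their CIGAR:
#' `M`/`=`/`X` consume read and reference, `D`/`N` emit deletion (`-`)
#' columns, `I` consumes read only (the inserted bases are dropped), `S`
#' consumes read only, `H`/`P` consume nothing.  Records with the unmapped
#' flag or below the MAPQ threshold are returned as unmapped ids.  Secondary
#' and supplementary records (flags 0x100/0x800) are ignored so each read
#' contributes at most one placement; their count is reported as `n_rejected`.
#'
#' @param path SAM (or BAM) file with a header; conversion goes through
#'   Rsamtools.
#' @param min_mapq minimum MAPQ for a record to become a placement.
#' @return list with `placements` (tibble), `unmapped_ids` (character) and
#'   `n_rejected` (count of ignored secondary/supplementary records).
#' @export
read_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop_refscaf("no such file: %s", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  if (n == 0L) {
    return(list(placements = empty_placements(), unmapped_ids = character(0),
                n_rejected = 0L))
  }
  flag <- rec$flag
  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  low <- !unmapped & !secondary & rec$mapq < min_mapq
  keep <- !unmapped & !secondary & !low

  seqs <- as.character(rec$seq)
  quals <- as.character(rec$qual)
  rows <- which(keep)
  if (length(rows)) {
    cig <- rec$cigar[rows]
    if (anyNA(cig) || any(cig == "*")) {
      bad <- rows[which(is.na(cig) | cig == "*")[1]]
      stop_refscaf("mapped record '%s' has no CIGAR", rec$qname[bad])
    }
  }
  proj <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[i]
    proj[[i]] <- project_cigar(rec$cigar[r], seqs[r], quals[r],
                               qname = rec$qname[r])
  }
  ref_len <- vapply(proj, `[[`, integer(1), "ref_len")
  pl <- placements(
    read_id = rec$qname[rows],
    ref_name = as.character(rec$rname[rows]),
    ref_start = rec$pos[rows] - 1L,                 # SAM POS is 1-based
    ref_end = rec$pos[rows] - 1L + ref_len,
    strand = ifelse(bitwAnd(flag[rows], 0x10L) != 0L, "-", "+"),
    proj_bases = vapply(proj, `[[`, character(1), "bases"),
    mapq = rec$mapq[rows],
    proj_quals = vapply(proj, `[[`, character(1), "quals"))
  list(placements = pl,
       unmapped_ids = rec$qname[unmapped | low],
       n_rejected = sum(secondary))
}

# Project one read onto reference columns through its CIGAR.
project_cigar <- function(cigar, seq, qual, qname = "?") {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  known <- c("M", "=", "X", "I", "D", "N", "S", "H", "P")
  if (any(!ops %in% known)) {
    stop_refscaf("record '%s': unknown CIGAR opcode '%s'",
                 qname, setdiff(ops, known)[1])
  }
  have_qual <- !is.na(qual) && !identical(qual, "*")
  out_b <- character(length(ops))
  out_q <- character(length(ops))
  rp <- 1L
  for (k in seq_along(ops)) {
    op <- ops[k]; l <- lens[k]
    if (op %in% c("M", "=", "X")) {
      out_b[k] <- substr(seq, rp, rp + l - 1L)
      if (have_qual) out_q[k] <- substr(qual, rp, rp + l - 1L)
      rp <- rp + l
    } else if (op %in% c("D", "N")) {
      out_b[k] <- strrep("-", l)
      if (have_qual) out_q[k] <- strrep("!", l)
    } else if (op %in% c("I", "S")) {
      rp <- rp + l                                  # read-only: dropped
    }                                               # H/P: nothing
  }
  bases <- paste(out_b, collapse = "")
  list(bases = bases,
       quals = if (have_qual) paste(out_q, collapse = "") else
         strrep("!", nchar(bases)),
       ref_len = nchar(bases))
}

#' Write placements back out as a sorted text SAM file
#'
#' Reconstructs one SAM record per placement from its reference projection:
#' runs of `-` become `D` operations, everything else `M` (insertions
#' relative to the reference are not representable and are absent from
#' projections by construction).  Useful for exporting truth-derived
#' placements so they can be consumed by [read_alignments()] or external
#' tools.
#'
#' @param pl placement tibble.
#' @param ref_lengths named vector of reference sequence lengths (for the
#'   `@SQ` header).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_placements_sam <- function(pl, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  o <- order(pl$ref_name, pl$ref_start)
  pl <- pl[o, , drop = FALSE]
  cigar <- vapply(pl$proj_bases, function(p) {
    r <- rle(strsplit(p, "", fixed = TRUE)[[1]] == "-")
    paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  seq <- gsub("-", "", pl$proj_bases, fixed = TRUE)
  qual <- if ("proj_quals" %in% names(pl)) {
    q <- pl$proj_quals
    mapply(function(qq, pp) {
      rawToChar(charToRaw(qq)[charToRaw(pp) != charToRaw("-")])
    }, q, pl$proj_bases, USE.NAMES = FALSE)
  } else rep("*", nrow(pl))
  flag <- ifelse(pl$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 pl$read_id, flag, pl$ref_name, pl$ref_start + 1L,
                 pl$mapq, cigar, seq, qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
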