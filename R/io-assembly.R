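#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an assembly as FASTA (and optionally AGP)
#'
#' FASTA is wrapped at 60 columns.  When a scaffold layout is supplied an AGP
#' v2.1 file is written alongside: `W` lines for contig components (1-based
#' inclusive coordinates) and `N` lines for gaps (`gap_type` "scaffold",
#' `linkage` "yes", evidence "paired-ends").  Component coordinates must tile
#' each object exactly.
#'
#' @param seqs named character vector of sequences, or the list returned by
#'   [emit_scaffolds()] (its `seqs` and `agp` elements are used).
#' @param fasta_path output FASTA path.
#' @param agp_path optional output AGP path; requires a layout.
#' @param agp AGP layout tibble (as produced by [emit_scaffolds()]) when
#'   `seqs` is a plain vector.
#' @return `fasta_path`, invisibly.
#' @export
write_assembly <- function(seqs, fasta_path, agp_path = NULL, agp = NULL) {
  if (is.list(seqs) && !is.null(seqs$seqs)) {
    agp <- agp %||% seqs$agp
    seqs <- seqs$seqs
  }
  if (any(!nzchar(seqs))) stop_refscaf("empty sequence in assembly")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, fasta_path, width = 60L)
  if (!is.null(agp_path)) {
    if (is.null(agp)) stop_refscaf("agp layout required to write %s", agp_path)
    validate_agp(agp, nchar(seqs))
    header <- "##agp-version\t2.1"
    body <- apply(agp, 1L, function(r) paste(r, collapse = "\t"))
    writeLines(c(header, body), agp_path)
  }
  invisible(fasta_path)
}

# Components must tile each object 1..len without gaps or overlaps.
validate_agp <- function(agp, obj_lens) {
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, ]
    beg <- as.integer(rows$object_beg)
    end <- as.integer(rows$object_end)
    o <- order(beg)
    beg <- beg[o]; end <- end[o]
    if (beg[1] != 1L || any(beg[-1] != end[-length(end)] + 1L) ||
        (!is.null(obj_lens[obj]) && !is.na(obj_lens[obj]) &&
         end[length(end)] != obj_lens[obj])) {
      stop_refscaf("AGP components do not tile object '%s'", obj)
    }
  }
  invisible(agp)
}

#' Read a scaffold AGP file
#'
#' @param path AGP v2.1 file.
#' @return tibble with one row per AGP line.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(tibble::tibble())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tibble::tibble(object = f[, 1], object_beg = as.integer(f[, 2]),
                 object_end = as.integer(f[, 3]),
                 part_number = as.integer(f[, 4]),
                 component_type = f[, 5], col6 = f[, 6], col7 = f[, 7],
                 col8 = f[, 8], col9 = f[, 9])
}
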