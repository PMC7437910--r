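#' Read a FASTQ file into a read table
#'
#' Expects four-line records with Phred+33 qualities.  A record whose base and
#' quality strings differ in length aborts with an error naming the record.
#'
#' @param path FASTQ file.
#' @param run_label run label to attach; defaults to the file name without
#'   extension.
#' @param mate_role mate role for every read, or `"auto"` to infer
#'   `mate_first`/`mate_second` from a trailing `/1` or `/2` on the id.
#' @return read tibble (see [refscaf-types]); zero rows for an empty file.
#' @export
read_reads <- function(path, run_label = NULL, mate_role = "auto") {
  if (!file.exists(path)) stop_refscaf("no such file: %s", path)
  run_label <- run_label %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(quality_reads(character(0), character(0), character(0),
                         character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop_refscaf("%s: truncated FASTQ (line count %d not a multiple of 4)",
                 path, length(lines))
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop_refscaf("%s: malformed FASTQ header at record %d", path,
                 which(substr(hdr, 1L, 1L) != "@")[1])
  }
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  bases <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  role <- if (identical(mate_role, "auto")) {
    ifelse(grepl("/1$", ids), "mate_first",
           ifelse(grepl("/2$", ids), "mate_second", "fragment"))
  } else mate_role
  quality_reads(ids, bases, quals, run_label = run_label, mate_role = role)
}

#' Write a read table as FASTQ
#'
#' Inverse of [read_reads()]: writing and re-reading a well-formed file is
#' byte-identical.
#'
#' @param reads read tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  validate_reads(reads)
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, length(out), 4L)] <- reads$bases
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- reads$quals
  writeLines(out, path)
  invisible(path)
}
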