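#' Read repeat or whole-genome-alignment annotations
#'
#' Two kinds are supported:
#'
#' * `repeatmasker_out`: a RepeatMasker `.out` file (3-line header).
#'   Class/family strings are mapped onto the closed family set
#'   `LINE, LTR, SINE, Simple repeat, Satellite, ncRNA, Others`:
#'   `LINE/*` to LINE, `Low_complexity` merged into Simple repeat,
#'   `rRNA/scRNA/snRNA/srpRNA/tRNA` to ncRNA, anything unrecognised to
#'   Others.  1-based inclusive coordinates are converted to 0-based
#'   half-open.
#' * `paf`: minimap2-style PAF with at least 12 mandatory columns; PAF is
#'   already 0-based half-open, so coordinates and strand pass through.
#'
#' Unparseable lines are skipped with a warning; the number skipped is
#' attached as attribute `n_rejected`.
#'
#' @param path input file.
#' @param kind `"repeatmasker_out"` or `"paf"`.
#' @return tibble of repeat records (`family`, `ref_name`, `start`, `end`) or
#'   alignment segments (`ref_name`, `ref_start`, `ref_end`, `qry_name`,
#'   `qry_start`, `qry_end`, `strand`).
#' @export
read_annotations <- function(path, kind = c("repeatmasker_out", "paf")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_refscaf("no such file: %s", path)
  switch(kind,
         repeatmasker_out = read_rmout(path),
         paf = read_paf(path))
}

#' Map a RepeatMasker class/family string to the closed family set
#'
#' @param class_family character vector such as `"LINE/L1"` or
#'   `"SINE/tRNA-Core-RTE"`.
#' @return character vector over the closed family set.
#' @export
map_repeat_family <- function(class_family) {
  cls <- sub("/.*$", "", class_family)
  out <- rep("Others", length(cls))
  out[cls == "LINE"] <- "LINE"
  out[cls == "SINE"] <- "SINE"
  out[cls == "LTR"] <- "LTR"
  out[cls %in% c("Simple_repeat", "Low_complexity")] <- "Simple repeat"
  out[cls == "Satellite"] <- "Satellite"
  out[cls %in% c("rRNA", "scRNA", "snRNA", "srpRNA", "tRNA")] <- "ncRNA"
  out
}

read_rmout <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n_rej <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    beg <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (length(f) < 11L || is.na(beg) || is.na(end) || beg > end) {
      warning(sprintf("%s: skipping unparseable line %d", path, i + 3L),
              call. = FALSE)
      n_rej <- n_rej + 1L
      next
    }
    rows[[i]] <- tibble::tibble(family = map_repeat_family(f[11]),
                                ref_name = f[5],
                                start = beg - 1L, end = end)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(family = character(0), ref_name = character(0),
                          start = integer(0), end = integer(0))
  }
  attr(out, "n_rejected") <- n_rej
  out
}

read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_rej <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    nums <- suppressWarnings(as.integer(f[c(2:4, 7:9)]))
    if (length(f) < 12L || anyNA(nums) || !f[5] %in% c("+", "-")) {
      warning(sprintf("%s: skipping unparseable line %d", path, i),
              call. = FALSE)
      n_rej <- n_rej + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      ref_name = f[6], ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
      qry_name = f[1], qry_start = as.integer(f[3]), qry_end = as.integer(f[4]),
      strand = f[5])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(ref_name = character(0), ref_start = integer(0),
                          ref_end = integer(0), qry_name = character(0),
                          qry_start = integer(0), qry_end = integer(0),
                          strand = character(0))
  }
  attr(out, "n_rejected") <- n_rej
  out
}
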