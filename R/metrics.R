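# Assembly statistics, repeat-family summaries and report generation.

#' Nx / Lx of a set of record lengths
#'
#' Lengths are sorted in decreasing order; `Nx` is the smallest length in the
#' minimal prefix whose sum reaches `fraction` of the total, and `Lx` is that
#' prefix's size.
#'
#' @param lengths record lengths in bp (all >= 1).
#' @param fraction target fraction of total length (default 0.5, i.e.
#'   N50/L50).
#' @return list with `nx` and `lx`.
#' @export
nx_lx <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0L) stop_refscaf("nx_lx of an empty length set")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(l)
  k <- which(cs >= fraction * cs[length(cs)])[1]
  list(nx = l[k], lx = k)
}

#' Assembly statistics in the shape of a standard metrics table
#'
#' @param seqs named character vector of sequences, a `DNAStringSet`, or a
#'   FASTA path.
#' @return list with `total_len`, `ungapped_len` (excluding `N`/`n`),
#'   `n_records`, `n50`, `l50`, `max_len`, `mean_len`.
#' @export
assembly_stats <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    seqs <- read_fasta(seqs)
  }
  ss <- if (is(seqs, "DNAStringSet")) seqs else Biostrings::DNAStringSet(seqs)
  if (length(ss) == 0L) stop_refscaf("assembly_stats of an empty assembly")
  lens <- Biostrings::width(ss)
  n_count <- Biostrings::letterFrequency(ss, "N")[, 1]
  nl <- nx_lx(lens, 0.5)
  list(total_len = sum(as.numeric(lens)),
       ungapped_len = sum(as.numeric(lens)) - sum(as.numeric(n_count)),
       n_records = length(ss),
       n50 = nl$nx, l50 = nl$lx,
       max_len = max(lens), mean_len = mean(lens))
}

#' Repeat-family coverage summary
#'
#' Per family the covered bp is the length of the *union* of that family's
#' intervals on each reference sequence, so nested or overlapping hits are
#' not double counted.
#'
#' @param records repeat record tibble (`family`, `ref_name`, `start`,
#'   `end`; 0-based half-open), e.g. from [read_annotations()].
#' @param genome_len genome length in bp (> 0).
#' @return list with `families` (tibble of per-family bp and fractions of
#'   total repeat bp), `total_bp`, `genome_len` and `fraction_of_genome`.
#' @export
repeat_summary <- function(records, genome_len) {
  if (genome_len <= 0) stop_refscaf("genome_len must be positive")
  bp <- stats::setNames(numeric(length(REPEAT_FAMILIES)), REPEAT_FAMILIES)
  for (fam in REPEAT_FAMILIES) {
    rec <- records[records$family == fam, , drop = FALSE]
    if (nrow(rec) == 0L) next
    bp[fam] <- sum(vapply(split(rec, rec$ref_name), function(x) {
      interval_union_width(x$start, x$end)
    }, numeric(1)))
  }
  repeat_summary_from_totals(bp, genome_len)
}

#' Repeat summary from precomputed per-family bp totals
#'
#' Used when only a published per-family table is available rather than raw
#' repeat intervals.
#'
#' @param family_bp named numeric vector of bp per family (names drawn from
#'   the closed family set).
#' @param genome_len genome length in bp.
#' @return same structure as [repeat_summary()].
#' @export
repeat_summary_from_totals <- function(family_bp, genome_len) {
  if (genome_len <= 0) stop_refscaf("genome_len must be positive")
  bp <- stats::setNames(numeric(length(REPEAT_FAMILIES)), REPEAT_FAMILIES)
  bp[names(family_bp)] <- as.numeric(family_bp)
  total <- sum(bp)
  fam <- tibble::tibble(
    family = REPEAT_FAMILIES,
    bp = unname(bp),
    pct_of_repeats = if (total > 0) 100 * unname(bp) / total else
      rep(0, length(bp)))
  fam$pct_1dec <- round_half_up(fam$pct_of_repeats, 1)
  fam$pct_int <- round_half_up(fam$pct_of_repeats)
  fam$pct_trunc <- floor(fam$pct_of_repeats)
  list(families = fam, total_bp = total, genome_len = as.numeric(genome_len),
       fraction_of_genome = total / genome_len)
}

#' Sequencing depth as fold coverage
#'
#' @param total_yield total sequenced bases (bp).
#' @param genome_len genome length in bp (> 0).
#' @return `total_yield / genome_len`.
#' @export
coverage_fold <- function(total_yield, genome_len) {
  if (genome_len <= 0) stop_refscaf("genome_len must be positive")
  total_yield / genome_len
}

#' Render an assembly report
#'
#' Deterministic TSV-style report over assembly statistics and an optional
#' repeat summary; percentages carry both a 1-decimal and a nearest-integer
#' rendering.
#'
#' @param stats result of [assembly_stats()].
#' @param repeats optional result of [repeat_summary()].
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly when `path` is given.
#' @export
assembly_report <- function(stats, repeats = NULL, path = NULL) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c(
    "metric\tvalue",
    paste0("total_length\t", fmt(stats$total_len)),
    paste0("ungapped_length\t", fmt(stats$ungapped_len)),
    paste0("records\t", fmt(stats$n_records)),
    paste0("n50\t", fmt(stats$n50)),
    paste0("l50\t", fmt(stats$l50)),
    paste0("max_length\t", fmt(stats$max_len)),
    paste0("mean_length\t", fmt(round(stats$mean_len, 1))))
  if (!is.null(repeats)) {
    lines <- c(lines, "", "family\tbp\tpct_of_repeats\tpct_int")
    f <- repeats$families
    lines <- c(lines, sprintf("%s\t%s\t%.1f\t%d", f$family, fmt(f$bp),
                              f$pct_1dec, as.integer(f$pct_int)))
    lines <- c(lines,
               sprintf("Total\t%s\t100.0\t100", fmt(repeats$total_bp)),
               sprintf("fraction_of_genome\t%.4f\t%.1f\t%d",
                       repeats$fraction_of_genome,
                       round_half_up(100 * repeats$fraction_of_genome, 1),
                       as.integer(round_half_up(
                         100 * repeats$fraction_of_genome))))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
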