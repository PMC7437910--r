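#' Trimming policy
#'
#' Reads are truncated at the 3' side immediately before the first base whose
#' quality drops below `q_floor`; truncated reads shorter than `min_len` are
#' discarded.
#'
#' @param q_floor Phred threshold (default 15).
#' @param min_len minimum retained length in bp (default 30).
#' @return list with `q_floor` and `min_len`.
#' @export
trim_policy <- function(q_floor = 15L, min_len = 30L) {
  if (q_floor < 0L) stop_refscaf("q_floor must be >= 0")
  if (min_len < 1L) stop_refscaf("min_len must be >= 1")
  list(q_floor = as.integer(q_floor), min_len = as.integer(min_len))
}

#' Trim a single read
#'
#' @param read one-row read tibble.
#' @param policy a [trim_policy()].
#' @return the trimmed read (possibly unchanged), or a zero-row tibble when
#'   the retained prefix is shorter than `policy$min_len` (the discard
#'   marker).
#' @export
trim_read <- function(read, policy = trim_policy()) {
  stopifnot(nrow(read) == 1L)
  trim_reads(read, policy)
}

#' Trim many reads (vectorised)
#'
#' @param reads read tibble.
#' @param policy a [trim_policy()].
#' @return the retained reads, truncated in place; discarded reads are
#'   dropped.
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  validate_reads(reads)
  if (nrow(reads) == 0L) return(reads)
  cut <- first_below_threshold(reads$quals, policy$q_floor) - 1L  # kept length
  keep <- cut >= policy$min_len
  out <- reads[keep, , drop = FALSE]
  cut <- cut[keep]
  full <- cut == nchar(out$bases)
  if (any(!full)) {
    out$bases[!full] <- substr(out$bases[!full], 1L, cut[!full])
    out$quals[!full] <- substr(out$quals[!full], 1L, cut[!full])
  }
  out
}

#' Trim a read set and compute per-run statistics
#'
#' Statistics are computed per `run_label`, before trimming (all reads, "Q0")
#' and after trimming (retained reads only).  When `demote_widows` is TRUE a
#' mate whose partner was discarded is demoted to `fragment` status so that
#' every surviving `mate_first`/`mate_second` read still has its partner.
#'
#' @param reads read tibble.
#' @param policy a [trim_policy()].
#' @param demote_widows demote widowed mates to fragments (default TRUE).
#' @return list with `retained` (trimmed reads), `stats_q0` and
#'   `stats_policy` (per-run [run_stats()] tibbles).
#' @export
trim_set <- function(reads, policy = trim_policy(), demote_widows = TRUE) {
  stats_q0 <- run_stats(reads)
  retained <- trim_reads(reads, policy)
  if (demote_widows && nrow(retained)) {
    is_mate <- retained$mate_role %in% c("mate_first", "mate_second")
    stem <- pair_stem(retained$read_id)
    paired <- stem %in% stem[is_mate][duplicated(stem[is_mate])]
    retained$mate_role[is_mate & !paired] <- "fragment"
  }
  list(retained = retained,
       stats_q0 = stats_q0,
       stats_policy = run_stats(retained, runs = unique(reads$run_label)))
}

# Shared stem of a mate pair: read id without its /1 or /2 suffix.
pair_stem <- function(read_id) sub("/[12]$", "", read_id)

#' Per-run read-length statistics
#'
#' @param reads read tibble.
#' @param runs run labels to report (defaults to those present); runs with no
#'   reads are reported with `n_reads = 0` and `NA` mean/median.
#' @return tibble with `run_label`, `n_reads`, `total_bases`, `mean_len`,
#'   `median_len`.
#' @export
run_stats <- function(reads, runs = NULL) {
  runs <- runs %||% unique(reads$run_label)
  lens <- nchar(reads$bases)
  out <- lapply(runs, function(r) {
    l <- lens[reads$run_label == r]
    tibble::tibble(run_label = r, n_reads = length(l),
                   total_bases = sum(as.numeric(l)),
                   mean_len = if (length(l)) mean(l) else NA_real_,
                   median_len = if (length(l)) stats::median(l) else NA_real_)
  })
  do.call(rbind, out)
}

#' Percentage of reads retained by trimming
#'
#' @param stats_q0 pre-trim [run_stats()] (or anything with an `n_reads`
#'   column), summed over runs.
#' @param stats_q post-trim statistics over the same read universe.
#' @return retention as a percentage (real).
#' @export
percent_retained <- function(stats_q0, stats_q) {
  before <- sum(stats_q0$n_reads)
  after <- sum(stats_q$n_reads)
  if (before == 0) stop_refscaf("no reads before trimming")
  100 * after / before
}
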