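# Deterministic synthetic-data generator: a donor genome, a diverged
# reference, fragment and mate-pair read sets with decaying quality
# profiles, truth-derived alignments, and truth-based evaluation.

#' Simulation configuration
#'
#' The donor genome is the sequence to be recovered; the reference is the
#' donor with substitutions, 1 bp indels, and a number of *novel segments*
#' removed (donor-only sequence absent from the reference, emulating
#' species-specific loci missing from a related reference genome).  Reads
#' crossing a novel segment cannot be placed on the reference, so contigs
#' break there and mate pairs spanning the segment carry real gap
#' information — the regime a reference-guided assembler has to resolve.
#'
#' Quality decay is linear in absolute cycle with per-base Gaussian noise:
#' mean quality starts at `q_start` and crosses the Q15 floor near
#' `cross_cycle`, so that trimming statistics resemble a run in which a bit
#' over half of the reads survive.
#'
#' @param genome_len donor genome length in bp (>= 10 kb).
#' @param divergence substitution rate donor vs reference (default 0.02).
#' @param indel_rate 1 bp indel rate (default 0.001).
#' @param repeat_fraction fraction of the donor built from repeat-motif
#'   copies (default 0).
#' @param read_len_fragment,read_len_mate read lengths in bp (75 / 60).
#' @param coverage_fragment,coverage_mate fold coverage of the fragment
#'   library and of *each* mate library (30 / 10).
#' @param libraries tibble of [library_spec()] rows (defaults: 1 kb +- 100
#'   and 3 kb +- 300, same-strand mate pairs).
#' @param base_error_rate per-base sequencing error rate (default 0.01).
#' @param quality_decay list with `q_start`, `cross_cycle`, `sd`.
#' @param novel_segment_count number of donor-only segments (default one per
#'   100 kb).
#' @param novel_segment_len mean novel segment length in bp (default 300).
#' @param seed integer seed; mandatory, drives every stochastic call.
#' @return validated config list.
#' @export
sim_config <- function(genome_len = 2e6,
                       divergence = 0.02,
                       indel_rate = 0.001,
                       repeat_fraction = 0,
                       read_len_fragment = 75L,
                       read_len_mate = 60L,
                       coverage_fragment = 30,
                       coverage_mate = 10,
                       libraries = NULL,
                       base_error_rate = 0.01,
                       quality_decay = list(q_start = 32, cross_cycle = 110,
                                            sd = 3, fail_frac = 0.35,
                                            fail_cross = 18),
                       novel_segment_count = NULL,
                       novel_segment_len = 300,
                       seed) {
  if (missing(seed)) stop_refscaf("sim_config: seed is mandatory")
  if (genome_len < 1e4) stop_refscaf("genome_len must be >= 10 kb")
  for (r in c(divergence, indel_rate, repeat_fraction, base_error_rate)) {
    if (r < 0 || r >= 1) stop_refscaf("rates must lie in [0, 1)")
  }
  libraries <- libraries %||% rbind(
    library_spec("mp1k", 1000, 100, "same"),
    library_spec("mp3k", 3000, 300, "same"))
  novel_segment_count <- novel_segment_count %||% max(0L,
                                                      round(genome_len / 1e5))
  list(genome_len = as.integer(genome_len), divergence = divergence,
       indel_rate = indel_rate, repeat_fraction = repeat_fraction,
       read_len_fragment = as.integer(read_len_fragment),
       read_len_mate = as.integer(read_len_mate),
       coverage_fragment = coverage_fragment, coverage_mate = coverage_mate,
       libraries = libraries, base_error_rate = base_error_rate,
       quality_decay = quality_decay,
       novel_segment_count = as.integer(novel_segment_count),
       novel_segment_len = novel_segment_len,
       seed = as.integer(seed))
}

DNA_RAW <- charToRaw("ACGT")

random_dna <- function(n) {
  rawToChar(DNA_RAW[sample.int(4L, n, replace = TRUE)])
}

#' Simulate a donor genome and a diverged reference
#'
#' @param config a [sim_config()].
#' @return list with `donor` and `reference` (strings), `donor_len`,
#'   `ref_len`, `edits` (variant truth table: `type` in `sub`/`ins`/`del`,
#'   0-based `donor_pos`, `len`, `novel` flag, `ref_pos`), `novel` (donor
#'   intervals of the novel segments), `repeats` (implanted repeat
#'   annotation, when `repeat_fraction > 0`) and internal coordinate maps.
#' @export
simulate_genomes <- function(config) {
  set.seed(config$seed)
  n <- config$genome_len
  donor_raw <- DNA_RAW[sample.int(4L, n, replace = TRUE)]
  repeats <- NULL
  if (config$repeat_fraction > 0) {
    fams <- c("LINE", "SINE", "LTR", "Simple repeat", "Satellite")
    motifs <- vapply(sample(c(150L, 300L, 500L, 80L, 200L)), random_dna,
                     character(1))
    placed <- 0
    rows <- list()
    target <- config$repeat_fraction * n
    while (placed < target) {
      k <- sample.int(length(motifs), 1L)
      m <- charToRaw(motifs[k])
      p <- sample.int(n - length(m), 1L)
      donor_raw[p:(p + length(m) - 1L)] <- m
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = fams[k], ref_name = "donor1",
        start = p - 1L, end = p - 1L + length(m))
      placed <- placed + length(m)
    }
    repeats <- do.call(rbind, rows)
  }

  # novel segments: donor-only intervals, well separated and off the ends
  novel <- tibble::tibble(donor_start = integer(0), donor_end = integer(0))
  if (config$novel_segment_count > 0L) {
    lens <- pmax(50L, round(stats::rnorm(config$novel_segment_count,
                                         config$novel_segment_len,
                                         config$novel_segment_len / 6)))
    margin <- 5000L
    min_sep <- 10000L
    repeat {
      starts <- sort(sample.int(n - 2L * margin - max(lens),
                                config$novel_segment_count) + margin)
      if (config$novel_segment_count == 1L ||
          all(diff(starts) >= min_sep + max(lens))) break
    }
    novel <- tibble::tibble(donor_start = starts,
                            donor_end = starts + as.integer(lens))
  }
  in_novel <- function(p) {                       # 0-based positions
    if (nrow(novel) == 0L) return(rep(FALSE, length(p)))
    i <- findInterval(p, novel$donor_start)
    i > 0L & p < novel$donor_end[pmax(i, 1L)]
  }

  n_sub <- stats::rbinom(1L, n, config$divergence)
  sub_pos <- sort(sample.int(n, n_sub) - 1L)
  sub_pos <- sub_pos[!in_novel(sub_pos)]
  n_indel <- stats::rbinom(1L, n, config$indel_rate)
  ind_pos <- sort(sample.int(n, n_indel) - 1L)
  ind_pos <- ind_pos[!in_novel(ind_pos) & !ind_pos %in% sub_pos &
                       ind_pos > 0L & ind_pos < n - 1L]
  is_ins <- sample(c(TRUE, FALSE), length(ind_pos), replace = TRUE)
  ins_pos <- ind_pos[is_ins]
  del_pos <- ind_pos[!is_ins]

  edits <- rbind(
    tibble::tibble(type = "sub", donor_pos = sub_pos, len = 1L,
                   novel = FALSE),
    tibble::tibble(type = "ins", donor_pos = ins_pos, len = 1L,
                   novel = FALSE),
    tibble::tibble(type = "del", donor_pos = del_pos, len = 1L,
                   novel = FALSE),
    tibble::tibble(type = "del", donor_pos = novel$donor_start,
                   len = novel$donor_end - novel$donor_start, novel = TRUE))
  edits <- edits[order(edits$donor_pos), , drop = FALSE]

  # reference construction: substitutions in place, deletions masked out,
  # insertions interleaved by sort key
  ref_raw <- donor_raw
  if (length(sub_pos)) {
    old <- ref_raw[sub_pos + 1L]
    shift <- sample.int(3L, length(sub_pos), replace = TRUE)
    oldi <- match(old, DNA_RAW)
    ref_raw[sub_pos + 1L] <- DNA_RAW[((oldi - 1L + shift) %% 4L) + 1L]
  }
  keep <- rep(TRUE, n)
  del_rows <- edits[edits$type == "del", , drop = FALSE]
  if (nrow(del_rows)) {
    drop_idx <- sequence(del_rows$len, from = del_rows$donor_pos + 1L)
    keep[drop_idx] <- FALSE
  }
  ins_base <- DNA_RAW[sample.int(4L, length(ins_pos), replace = TRUE)]
  key <- c(2 * (which(keep) - 1L), 2 * ins_pos - 1)
  ref_raw <- c(ref_raw[keep], ins_base)[order(key)]
  reference <- rawToChar(ref_raw)

  maps <- build_coord_maps(edits)
  edits$ref_pos <- edit_ref_pos(edits, maps)
  list(donor = rawToChar(donor_raw), reference = reference,
       donor_len = n, ref_len = nchar(reference),
       edits = edits, novel = novel, repeats = repeats, maps = maps,
       config = config)
}

# Donor<->reference coordinate maps from the edit table.  d2r: position of a
# donor base on the reference (valid off deleted bases); r2d: position of a
# reference base on the donor (valid off inserted bases).
build_coord_maps <- function(edits) {
  ins <- edits[edits$type == "ins", , drop = FALSE]
  del <- edits[edits$type == "del", , drop = FALSE]
  # donor -> ref: an insertion at donor_pos p adds len for positions >= p;
  # a deletion [p, p+len) subtracts len for positions >= p+len
  thrD <- c(ins$donor_pos, del$donor_pos + del$len)
  dD <- c(ins$len, -del$len)
  o <- order(thrD)
  thrD <- thrD[o]
  cumD <- cumsum(dD[o])
  d2r <- function(q) q + c(0, cumD)[findInterval(q, thrD) + 1L]
  # ref -> donor mirrors it, using reference coordinates of the same edits
  rp <- edit_ref_pos(edits, list(d2r = d2r))
  thrR <- c(rp[edits$type == "del"],
            rp[edits$type == "ins"] + edits$len[edits$type == "ins"])
  dR <- c(edits$len[edits$type == "del"], -edits$len[edits$type == "ins"])
  o <- order(thrR)
  thrR <- thrR[o]
  cumR <- cumsum(dR[o])
  r2d <- function(q) q + c(0, cumR)[findInterval(q, thrR) + 1L]
  list(d2r = d2r, r2d = r2d,
       ins_pos = sort(edits$donor_pos[edits$type == "ins"]),
       del_start = del$donor_pos, del_end = del$donor_pos + del$len,
       ins_ref_start = sort(rp[edits$type == "ins"]),
       ins_ref_len = edits$len[edits$type == "ins"][
         order(rp[edits$type == "ins"])])
}

# Reference coordinate of each edit (start of the inserted run for "ins").
edit_ref_pos <- function(edits, maps) {
  out <- maps$d2r(edits$donor_pos)
  ins <- edits$type == "ins"
  out[ins] <- out[ins] - edits$len[ins]
  out
}

# Quality strings from the decay profile (chunked for memory).  Each read is
# drawn from one of two populations: a "failed" fraction whose mean quality
# crosses the Q15 floor very early (these reads fall to the trimmer), and
# good reads whose profile crosses late, so retained reads stay close to
# full length.
sim_quals <- function(n_reads, read_len, decay) {
  if (n_reads == 0L) return(character(0))
  cyc <- seq_len(read_len) - 1L
  fail_frac <- decay$fail_frac %||% 0
  fail_cross <- decay$fail_cross %||% decay$cross_cycle
  out <- character(n_reads)
  chunk <- 200000L
  for (lo in seq(1L, n_reads, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_reads)
    m <- hi - lo + 1L
    failed <- stats::runif(m) < fail_frac
    cross <- ifelse(failed, fail_cross, decay$cross_cycle)
    prof <- decay$q_start - (decay$q_start - 15) * (cyc %o% (1 / cross))
    q <- prof + stats::rnorm(read_len * m, sd = decay$sd)
    q <- pmin(pmax(round(q), 2), 41)
    big <- rawToChar(as.raw(as.integer(q) + 33L))
    out[lo:hi] <- substring(big, (seq_len(m) - 1L) * read_len + 1L,
                            seq_len(m) * read_len)
  }
  out
}

# Sequencing errors: mutate a Binomial(total bases, rate) sample of
# positions to a different base, via one concatenated raw pass.
apply_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  big <- charToRaw(paste(reads, collapse = ""))
  total <- length(big)
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  idx <- sample.int(total, n_err)
  oldi <- match(big[idx], DNA_RAW)
  oldi[is.na(oldi)] <- 1L                         # N and friends: treat as A
  shift <- sample.int(3L, n_err, replace = TRUE)
  big[idx] <- DNA_RAW[((oldi - 1L + shift) %% 4L) + 1L]
  all <- rawToChar(big)
  ends <- cumsum(lens)
  substring(all, ends - lens + 1L, ends)
}

#' Simulate fragment and mate-pair read sets from the donor
#'
#' Start positions are uniform; mate pairs are separated by normal insert
#' sizes truncated at +-4 SD; per-base errors occur at `base_error_rate`;
#' qualities follow the decaying profile.  True donor positions are recorded
#' in a truth table.
#'
#' @param genomes result of [simulate_genomes()].
#' @param config the same [sim_config()].
#' @return list with `reads` (read tibble over all libraries) and `truth`
#'   (per read: 0-based donor interval, strand, library, pair id).
#' @export
simulate_reads <- function(genomes, config) {
  set.seed(config$seed + 1L)
  n <- genomes$donor_len
  donor <- genomes$donor
  sets <- list()
  truths <- list()

  frag_n <- round(config$coverage_fragment * n / config$read_len_fragment)
  if (frag_n > 0L) {
    L <- config$read_len_fragment
    s <- sample.int(n - L + 1L, frag_n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), frag_n, replace = TRUE)
    bases <- substring(donor, s + 1L, s + L)
    bases <- apply_errors(bases, config$base_error_rate)
    neg <- strand == "-"
    if (any(neg)) bases[neg] <- revcomp(bases[neg])
    ids <- sprintf("frag_%07d", seq_len(frag_n))
    sets$frag <- quality_reads(ids, bases,
                               sim_quals(frag_n, L, config$quality_decay),
                               run_label = "frag", mate_role = "fragment")
    truths$frag <- tibble::tibble(read_id = ids, donor_start = s,
                                  donor_end = s + L, strand = strand,
                                  run_label = "frag",
                                  mate_role = "fragment",
                                  pair_id = NA_character_)
  }

  L <- config$read_len_mate
  for (k in seq_len(nrow(config$libraries))) {
    lib <- config$libraries[k, ]
    n_pairs <- round(config$coverage_mate * n / (2 * L))
    if (n_pairs == 0L) next
    ins <- stats::rnorm(n_pairs, lib$insert_mean, lib$insert_sd)
    for (it in 1:10) {
      bad <- abs(ins - lib$insert_mean) > 4 * lib$insert_sd
      if (!any(bad)) break
      ins[bad] <- stats::rnorm(sum(bad), lib$insert_mean, lib$insert_sd)
    }
    ins <- pmin(pmax(round(ins), 2L * L), n - 1L)
    s <- floor(stats::runif(n_pairs) * (n - ins)) ## fragment start
    f <- sample(c("+", "-"), n_pairs, replace = TRUE)
    left <- cbind(s, s + L)                       # donor interval, left end
    right <- cbind(s + ins - L, s + ins)
    first_left <- f == "+"                        # 5' mate sits left on "+"
    a_start <- ifelse(first_left, left[, 1], right[, 1])
    a_end <- ifelse(first_left, left[, 2], right[, 2])
    b_start <- ifelse(first_left, right[, 1], left[, 1])
    b_end <- ifelse(first_left, right[, 2], left[, 2])
    a_strand <- f
    b_strand <- if (lib$orientation == "same") f else chartr("+-", "-+", f)
    stem <- sprintf("%s_%07d", lib$name, seq_len(n_pairs))
    mk <- function(st, en, strand, role, suffix) {
      bases <- substring(donor, st + 1L, en)
      bases <- apply_errors(bases, config$base_error_rate)
      neg <- strand == "-"
      if (any(neg)) bases[neg] <- revcomp(bases[neg])
      ids <- paste0(stem, suffix)
      list(reads = quality_reads(ids, bases,
                                 sim_quals(n_pairs, L, config$quality_decay),
                                 run_label = lib$name, mate_role = role),
           truth = tibble::tibble(read_id = ids, donor_start = as.integer(st),
                                  donor_end = as.integer(en), strand = strand,
                                  run_label = lib$name, mate_role = role,
                                  pair_id = stem))
    }
    ra <- mk(a_start, a_end, a_strand, "mate_first", "/1")
    rb <- mk(b_start, b_end, b_strand, "mate_second", "/2")
    sets[[paste0(lib$name, "_1")]] <- ra$reads
    sets[[paste0(lib$name, "_2")]] <- rb$reads
    truths[[paste0(lib$name, "_1")]] <- ra$truth
    truths[[paste0(lib$name, "_2")]] <- rb$truth
  }
  if (length(sets) == 0L) {
    return(list(reads = quality_reads(character(0), character(0),
                                      character(0), character(0),
                                      character(0)),
                truth = tibble::tibble(read_id = character(0),
                                       donor_start = integer(0),
                                       donor_end = integer(0),
                                       strand = character(0),
                                       run_label = character(0),
                                       mate_role = character(0),
                                       pair_id = character(0))))
  }
  list(reads = do.call(rbind, sets), truth = do.call(rbind, truths))
}
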