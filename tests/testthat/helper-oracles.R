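# Independent brute-force oracles and small fixture builders used across the
# suite.  Every oracle is written against the definition, not against the
# implementation it checks.

# Character-walk CIGAR projection (independent of project_cigar).
oracle_project <- function(cigar, seq) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  out <- character(0)
  rp <- 1L
  for (t in toks) {
    l <- as.integer(sub("[A-Z=]$", "", t))
    op <- sub("^[0-9]+", "", t)
    if (op %in% c("M", "=", "X")) {
      for (k in seq_len(l)) {
        out <- c(out, substr(seq, rp, rp))
        rp <- rp + 1L
      }
    } else if (op %in% c("D", "N")) {
      out <- c(out, rep("-", l))
    } else if (op %in% c("I", "S")) {
      rp <- rp + l
    }
  }
  paste(out, collapse = "")
}

# O(n^2) connected components of the >=min_overlap interval-overlap graph.
oracle_overlap_components <- function(start, end, min_overlap) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            min(end[i], end[j]) - max(start[i], start[j]) >= min_overlap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Per-column tally consensus over a placement cluster (majority by count,
# ties by summed quality then reference then lexicographic symbol order).
oracle_consensus_seq <- function(cluster, reference_window = NULL) {
  a0 <- min(cluster$ref_start)
  a1 <- max(cluster$ref_end)
  out <- character(0)
  for (col in a0:(a1 - 1L)) {
    syms <- character(0)
    qs <- integer(0)
    for (i in seq_len(nrow(cluster))) {
      if (cluster$ref_start[i] <= col && col < cluster$ref_end[i]) {
        k <- col - cluster$ref_start[i] + 1L
        syms <- c(syms, substr(cluster$proj_bases[i], k, k))
        qs <- c(qs, if ("proj_quals" %in% names(cluster)) {
          as.integer(charToRaw(substr(cluster$proj_quals[i], k, k))) - 33L
        } else 0L)
      }
    }
    tab <- table(syms)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
      qsum <- vapply(cand, function(s) sum(qs[syms == s]), numeric(1))
      cand <- cand[qsum == max(qsum)]
    }
    if (length(cand) > 1L && !is.null(reference_window)) {
      rb <- substr(reference_window, col - a0 + 1L, col - a0 + 1L)
      if (rb %in% cand) cand <- rb
    }
    win <- sort(cand)[1]
    if (win != "-") out <- c(out, win)
  }
  paste(out, collapse = "")
}

# Exhaustive prefix-scan Nx/Lx.
oracle_nx_lx <- function(lengths, fraction) {
  l <- sort(lengths, decreasing = TRUE)
  total <- sum(l)
  acc <- 0
  for (k in seq_along(l)) {
    acc <- acc + l[k]
    if (acc >= fraction * total) return(list(nx = l[k], lx = k))
  }
}

# Quadratic chain construction for synteny blocks on one
# (ref, qry, strand) group of disjoint segments.
oracle_chain_ids <- function(g, max_join_gap) {
  o <- order(g$ref_start)
  g <- g[o, , drop = FALSE]
  n <- nrow(g)
  chain <- integer(n)
  chain[1] <- 1L
  for (i in seq_len(n - 1L)) {
    rg <- g$ref_start[i + 1L] - g$ref_end[i]
    qg <- if (g$strand[1] == "+") g$qry_start[i + 1L] - g$qry_end[i] else
      g$qry_start[i] - g$qry_end[i + 1L]
    chain[i + 1L] <- chain[i] +
      as.integer(!(rg >= 0 && rg <= max_join_gap && qg >= 0 &&
                     qg <= max_join_gap))
  }
  chain
}

# Exhaustive maximum-weight vertex-disjoint path cover over an edge set:
# enumerate every edge subset, keep those forming valid paths (every contig
# end used at most once, no cycle through the contig-internal connections).
oracle_best_path_weight <- function(edges) {
  n <- nrow(edges)
  if (n == 0L) return(0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) != 0L)
    if (!length(idx)) next
    sub <- edges[idx, , drop = FALSE]
    ends <- c(paste(sub$contig_a, sub$end_a), paste(sub$contig_b, sub$end_b))
    if (anyDuplicated(ends)) next
    # cycle test: union-find over contigs
    ids <- unique(c(sub$contig_a, sub$contig_b))
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (k in seq_len(nrow(sub))) {
      ra <- find(match(sub$contig_a[k], ids))
      rb <- find(match(sub$contig_b[k], ids))
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    best <- max(best, sum(sub$weight))
  }
  best
}

# Total edge weight realised by a set of scaffold paths.
paths_weight <- function(paths, edges) {
  w <- 0
  for (sid in unique(paths$scaffold_id)) {
    p <- paths[paths$scaffold_id == sid, ]
    p <- p[order(p$element), ]
    if (nrow(p) < 2L) next
    for (k in seq_len(nrow(p) - 1L)) {
      a <- p$contig_id[k]; b <- p$contig_id[k + 1L]
      hit <- (edges$contig_a == pmin(a, b) & edges$contig_b == pmax(a, b))
      w <- w + max(edges$weight[hit])
    }
  }
  w
}

# Random placements on one reference sequence.
random_placements <- function(n, ref_len = 1000L, min_w = 20L, max_w = 120L,
                              ref_name = "refX") {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample.int(ref_len - max_w, n, replace = TRUE) - 1L
  placements(read_id = sprintf("r%04d", seq_len(n)), ref_name = ref_name,
             ref_start = s, ref_end = s + w, strand = "+",
             proj_bases = vapply(w, function(k) {
               paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
             }, character(1)))
}

# Random well-formed reads.
random_reads <- function(n, min_len = 30L, max_len = 80L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  quality_reads(
    read_id = sprintf("rd%04d", seq_len(n)),
    bases = vapply(lens, function(k) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1)),
    quals = vapply(lens, function(k) {
      phred_string(sample(0:41, k, replace = TRUE))
    }, character(1)))
}

# Minimal SAM writer for fixtures.
write_sam_fixture <- function(path, records, sq = c(chr1 = 2000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
}
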