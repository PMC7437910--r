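edge_row <- function(a, b, w, gap = 0, sd = 10, ea = "R", eb = "L") {
  tibble::tibble(contig_a = a, contig_b = b, end_a = ea, end_b = eb,
                 weight = as.integer(w), gap_mean = gap, gap_sd = sd,
                 n_discarded = 0L)
}

test_that("gap estimates follow insert-size arithmetic", {
  expect_equal(estimate_gap(1000, 300, 400), 300)
  expect_equal(estimate_gap(1000, 600, 600), -200)
  expect_equal(estimate_gap(c(1000, 3000), c(0, 100), c(0, 200)),
               c(1000, 2700))
})

test_that("simulated spanning links recover the true gap", {
  set.seed(41)
  insert <- 1000
  sd <- 100
  true_gap <- 250
  n <- 50
  # mates at random distances from the junction-facing ends
  d_up <- sample(50:400, n, replace = TRUE)
  d_dn <- insert + rnorm(n, 0, sd) - true_gap - d_up
  gaps <- estimate_gap(insert, d_up, d_dn)
  expect_lt(abs(mean(gaps) - true_gap), 3 * sd / sqrt(n))
})

test_that("bundling groups links by pair and keeps the majority class", {
  links <- tibble::tibble(
    pair_id = sprintf("p%d", 1:4), kind = "spanning",
    contig_a = "A", contig_b = "B", contig_up = "A", contig_down = "B",
    d_up = 0, d_dn = 0, gap = c(100, 120, 80, 100),
    library = "l", insert_mean = 1000, insert_sd = 100)
  b <- bundle_links(links)
  expect_equal(nrow(b), 1L)
  expect_equal(b$weight, 4L)
  expect_equal(b$gap_mean, 100)
  expect_equal(b$end_a, "R")
  expect_equal(b$end_b, "L")

  mixed <- rbind(links[1:3, ],
                 within(links[4, ], { contig_up <- "B"; contig_down <- "A" }))
  bm <- bundle_links(mixed)
  expect_equal(nrow(bm), 1L)
  expect_equal(bm$weight, 3L)
  expect_equal(bm$n_discarded, 1L)
})

test_that("random link sets bundle to group means", {
  set.seed(42)
  n <- 120
  pairs <- sprintf("c%02d", sample(1:6, n, replace = TRUE))
  partner <- sprintf("c%02d", sample(7:9, n, replace = TRUE))
  links <- tibble::tibble(
    pair_id = sprintf("p%d", 1:n), kind = "spanning",
    contig_a = pairs, contig_b = partner, contig_up = pairs,
    contig_down = partner, d_up = 0, d_dn = 0,
    gap = round(rnorm(n, 200, 50)), library = "l",
    insert_mean = 1000, insert_sd = 100)
  b <- bundle_links(links)
  for (i in seq_len(nrow(b))) {
    sel <- links$gap[links$contig_a == b$contig_a[i] &
                       links$contig_b == b$contig_b[i]]
    expect_equal(b$weight[i], length(sel))
    expect_equal(b$gap_mean[i], mean(sel))
    expect_equal(b$gap_sd[i], sd(sel))
  }
  expect_equal(sum(b$weight), n)
})

test_that("consistent edges chain contigs into a single path", {
  edges <- rbind(edge_row("A", "B", 5, gap = 100),
                 edge_row("B", "C", 4, gap = 50))
  paths <- greedy_path_merge(c("A", "B", "C"), edges)
  expect_equal(length(unique(paths$scaffold_id)), 1L)
  expect_equal(paths$contig_id[order(paths$element)], c("A", "B", "C"))
  expect_equal(paths$orientation, rep("+", 3))
  expect_equal(paths$gap_after[1:2], c(100, 50))
})

test_that("a contig end can be used by only one accepted edge", {
  edges <- rbind(edge_row("A", "B", 5),            # uses A's right end
                 edge_row("A", "C", 4))            # also wants A's right end
  paths <- greedy_path_merge(c("A", "B", "C"), edges)
  grp <- split(paths$contig_id, paths$scaffold_id)
  sizes <- sort(lengths(grp))
  expect_equal(unname(sizes), c(1L, 2L))
  joined <- grp[[which(lengths(grp) == 2L)]]
  expect_setequal(joined, c("A", "B"))             # heavier edge won
})

test_that("edges below the weight threshold are ignored", {
  edges <- rbind(edge_row("A", "B", 2), edge_row("B", "C", 3))
  paths <- greedy_path_merge(c("A", "B", "C"), edges, min_weight = 3L)
  expect_equal(length(unique(paths$scaffold_id)), 2L)
})

test_that("greedy merging attains the exhaustive optimum on chain instances", {
  set.seed(43)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    ids <- sprintf("c%d", seq_len(n))
    order_true <- sample(ids)
    rows <- list()
    for (k in seq_len(n - 1L)) {
      if (runif(1) < 0.75) {
        a <- order_true[k]; b <- order_true[k + 1L]
        swap <- a > b
        rows[[length(rows) + 1L]] <- edge_row(
          if (swap) b else a, if (swap) a else b, sample(3:9, 1),
          gap = sample(50:500, 1), sd = sample(5:50, 1),
          ea = if (swap) "L" else "R", eb = if (swap) "R" else "L")
      }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else edge_row("c1", "c2", 0)[0, ]
    paths <- greedy_path_merge(ids, edges, min_weight = 1L)
    expect_equal(paths_weight(paths, edges), oracle_best_path_weight(edges))
    expect_setequal(paths$contig_id, ids)          # partition of contigs
    expect_equal(anyDuplicated(paths$contig_id), 0L)
  }
})

test_that("greedy merging is single-swap locally optimal with skip edges", {
  set.seed(44)
  valid_weight <- function(edges) {
    ends <- c(paste(edges$contig_a, edges$end_a),
              paste(edges$contig_b, edges$end_b))
    if (anyDuplicated(ends)) return(-Inf)
    ids <- unique(c(edges$contig_a, edges$contig_b))
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(edges))) {
      ra <- find(match(edges$contig_a[k], ids))
      rb <- find(match(edges$contig_b[k], ids))
      if (ra == rb) return(-Inf)
      parent[ra] <- rb
    }
    sum(edges$weight)
  }
  for (rep in 1:6) {
    n <- 8L
    ids <- sprintf("c%d", seq_len(n))
    rows <- list()
    for (k in seq_len(n - 1L)) {                  # adjacent edges
      rows[[length(rows) + 1L]] <- edge_row(ids[k], ids[k + 1L],
                                            sample(3:9, 1),
                                            gap = sample(0:300, 1))
    }
    for (j in 1:2) {                              # skip edges
      k <- sample(seq_len(n - 2L), 1)
      rows[[length(rows) + 1L]] <- edge_row(ids[k], ids[k + 2L],
                                            sample(3:9, 1),
                                            gap = sample(500:2000, 1))
    }
    edges <- unique(do.call(rbind, rows))
    paths <- greedy_path_merge(ids, edges, min_weight = 1L)
    # reconstruct the accepted edge set from consecutive path elements
    used <- logical(nrow(edges))
    for (sid in unique(paths$scaffold_id)) {
      p <- paths[paths$scaffold_id == sid, ]
      p <- p[order(p$element), ]
      if (nrow(p) < 2L) next
      for (k in seq_len(nrow(p) - 1L)) {
        a <- pmin(p$contig_id[k], p$contig_id[k + 1L])
        b <- pmax(p$contig_id[k], p$contig_id[k + 1L])
        used[edges$contig_a == a & edges$contig_b == b] <- TRUE
      }
    }
    w0 <- sum(edges$weight[used])
    for (e_in in which(!used)) {
      for (e_out in which(used)) {
        trial <- edges[c(which(used & seq_len(nrow(edges)) != e_out), e_in), ]
        expect_lte(valid_weight(trial), w0)
      }
    }
  }
})

test_that("scaffold emission concatenates, clamps gaps and reverse-complements", {
  paths <- tibble::tibble(scaffold_id = "s1", element = 1:2,
                          contig_id = c("A", "B"),
                          orientation = c("+", "+"),
                          gap_after = c(50, NA))
  seqs <- c(A = strrep("ACGTT", 20), B = strrep("GATTC", 16))
  sc <- emit_scaffolds(paths, seqs)
  expect_equal(unname(nchar(sc$seqs)), 230)
  st <- assembly_stats(sc$seqs)
  expect_equal(st$ungapped_len, 180)

  neg <- paths
  neg$gap_after[1] <- -200
  expect_equal(unname(nchar(emit_scaffolds(neg, seqs, min_gap = 10)$seqs)),
               100 + 10 + 80)

  flip <- tibble::tibble(scaffold_id = "s1", element = 1:2,
                         contig_id = c("A", "B"),
                         orientation = c("+", "-"), gap_after = c(20, NA))
  got <- emit_scaffolds(flip, seqs)$seqs
  # independent reverse complement: reverse the string, then swap letters
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seqs[["B"]], "")[[1]]), collapse = ""))
  expect_equal(unname(substr(got, 121, 200)), unname(rc))
})

test_that("scaffolding conserves bases and can only raise the N50", {
  set.seed(45)
  for (rep in 1:5) {
    n <- 12L
    ids <- sprintf("c%02d", seq_len(n))
    seqs <- stats::setNames(vapply(sample(200:2000, n), function(k) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1)), ids)
    rows <- list()
    for (k in seq_len(n - 1L)) {
      if (runif(1) < 0.5) {
        rows[[length(rows) + 1L]] <- edge_row(ids[k], ids[k + 1L],
                                              sample(3:9, 1),
                                              gap = sample(-100:400, 1))
      }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else
      edge_row("x", "y", 1)[0, ]
    paths <- greedy_path_merge(ids, edges)
    sc <- emit_scaffolds(paths, seqs)
    expect_equal(assembly_stats(sc$seqs)$ungapped_len,
                 sum(nchar(seqs)))
    expect_gte(assembly_stats(sc$seqs)$n50, assembly_stats(seqs)$n50)
    expect_equal(nrow(paths), n)                  # partition
  }
})

test_that("transitive skip edges are removed when they restate a chain", {
  lens <- c(A = 1000, B = 400, C = 1200)
  edges <- rbind(edge_row("A", "B", 10, gap = 20, sd = 30),
                 edge_row("B", "C", 8, gap = 50, sd = 30),
                 edge_row("A", "C", 12, gap = 20 + 400 + 50, sd = 40))
  red <- reduce_transitive(edges, lens)
  expect_equal(nrow(red), 2L)
  expect_false(any(red$contig_a == "A" & red$contig_b == "C"))
  # an inconsistent long edge is genuine evidence and survives
  edges$gap_mean[3] <- 5000
  expect_equal(nrow(reduce_transitive(edges, lens)), 3L)
  # with the reduction, the chain wins over the heavy skip edge
  paths <- greedy_path_merge(names(lens), rbind(edges[1:2, ],
                                                edge_row("A", "C", 12,
                                                         gap = 470, sd = 40)),
                             min_weight = 3L, contig_lengths = lens)
  expect_equal(paths$contig_id[order(paths$element)], c("A", "B", "C"))
})
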