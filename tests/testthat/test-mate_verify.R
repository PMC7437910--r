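# Shared fixtures: two contigs on one reference with a 200 bp gap.
two_contigs <- function() {
  tibble::tibble(contig_id = c("ctgA", "ctgB"),
                 seq = c(strrep("A", 5000), strrep("C", 4000)),
                 ref_name = "r", ref_start = c(0L, 5200L),
                 ref_end = c(5000L, 9200L),
                 support = list("x", "y"), status = "unconfirmed",
                 del_cols = list(integer(0), integer(0)))
}

lifted_row <- function(id, contig, cstart, cend, strand, role,
                       run = "lib1") {
  tibble::tibble(read_id = id, contig_id = contig, cstart = cstart,
                 cend = cend, strand = strand, run_label = run,
                 mate_role = role)
}

lib1 <- library_spec("lib1", 1000, 100, "same")

test_that("placements lift into contig sequence coordinates", {
  ctg <- tibble::tibble(contig_id = "c1", seq = strrep("A", 295),
                        ref_name = "r", ref_start = 100L, ref_end = 400L,
                        support = list("x"), status = "unconfirmed",
                        del_cols = list(c(10L, 11L, 12L, 150L, 250L)))
  pl <- placements(read_id = c("in", "out"), ref_name = "r",
                   ref_start = c(120L, 900L), ref_end = c(180L, 960L),
                   strand = "+", proj_bases = strrep("G", 60))
  got <- lift_to_contigs(pl, ctg)
  expect_equal(nrow(got), 1L)
  expect_equal(attr(got, "n_dropped"), 1L)
  # offset 20 on the anchor, minus the 3 deletion columns before it
  expect_equal(got$cstart, 17L)
  expect_equal(got$cend, 77L)                    # no deletions inside

  # no deletions: offsets are plain anchor offsets
  plain <- ctg
  plain$del_cols <- list(integer(0))
  got2 <- lift_to_contigs(pl[1, ], plain)
  expect_equal(got2$cstart, 20L)
  expect_equal(got2$cend, 80L)
})

test_that("lifted offsets match a per-base coordinate walk", {
  set.seed(31)
  for (rep in 1:5) {
    dels <- sort(sample(0:499, 25))
    ctg <- tibble::tibble(contig_id = "c1", seq = strrep("A", 500 - 25),
                          ref_name = "r", ref_start = 1000L,
                          ref_end = 1500L, support = list("x"),
                          status = "unconfirmed", del_cols = list(dels))
    s <- sample(1000:1400, 20)
    pl <- placements(read_id = sprintf("p%d", 1:20), ref_name = "r",
                     ref_start = s, ref_end = s + 50L, strand = "+",
                     proj_bases = strrep("T", 50))
    got <- lift_to_contigs(pl, ctg)
    walk <- vapply(s, function(x) {
      rel <- x - 1000L
      sum(!(seq_len(rel) - 1L) %in% dels)        # surviving columns before
    }, numeric(1))
    expect_equal(got$cstart, as.integer(walk))
  }
})

test_that("links partition into intra, spanning and conflicting", {
  ctg <- two_contigs()
  # both mates on ctgA
  intra <- rbind(lifted_row("p1/1", "ctgA", 100L, 160L, "+", "mate_first"),
                 lifted_row("p1/2", "ctgA", 900L, 960L, "+", "mate_second"))
  expect_equal(classify_link(intra, lib1, ctg)$kind, "intra")

  # first mate near ctgA's right end, second near ctgB's left end, same
  # strand: suffix-prefix geometry
  span <- rbind(lifted_row("p2/1", "ctgA", 4500L, 4560L, "+", "mate_first"),
                lifted_row("p2/2", "ctgB", 200L, 260L, "+", "mate_second"))
  got <- classify_link(span, lib1, ctg, end_window = 3000)
  expect_equal(got$kind, "spanning")
  expect_equal(got$contig_up, "ctgA")
  expect_equal(got$d_up, 500)
  expect_equal(got$d_dn, 260)
  expect_equal(got$gap, 1000 - 500 - 260)

  # second mate 50 kb inside a (long) contig: not suffix-prefix
  ctg_big <- ctg
  ctg_big$seq[2] <- strrep("C", 60000)
  ctg_big$ref_end[2] <- 5200L + 60000L
  confl <- rbind(lifted_row("p3/1", "ctgA", 4500L, 4560L, "+", "mate_first"),
                 lifted_row("p3/2", "ctgB", 50000L, 50060L, "+",
                            "mate_second"))
  expect_equal(classify_link(confl, lib1, ctg_big, end_window = 4000)$kind,
               "conflicting")

  # a strand combination the library cannot produce is conflicting
  bad <- rbind(lifted_row("p4/1", "ctgA", 4500L, 4560L, "+", "mate_first"),
               lifted_row("p4/2", "ctgB", 200L, 260L, "-", "mate_second"))
  expect_equal(classify_link(bad, lib1, ctg)$kind, "conflicting")

  # every classified pair receives exactly one kind
  all_links <- classify_links(rbind(intra, span, confl, bad), lib1, ctg_big,
                              end_window = 3000)
  expect_equal(nrow(all_links), 4L)
  expect_true(all(all_links$kind %in% c("intra", "spanning", "conflicting")))
})

test_that("chemistry fixes the upstream mate on minus-strand pairs", {
  ctg <- two_contigs()
  # -/- same-strand pair: the *second* mate is upstream (fragment flipped)
  pair <- rbind(lifted_row("p5/1", "ctgB", 200L, 260L, "-", "mate_first"),
                lifted_row("p5/2", "ctgA", 4500L, 4560L, "-", "mate_second"))
  got <- classify_link(pair, lib1, ctg)
  expect_equal(got$kind, "spanning")
  expect_equal(got$contig_up, "ctgA")
  expect_equal(got$contig_down, "ctgB")

  # inward library: the "+" mate is upstream, strands must differ
  inw <- library_spec("lib1", 1000, 100, "inward")
  fr <- rbind(lifted_row("p6/1", "ctgA", 4500L, 4560L, "+", "mate_first"),
              lifted_row("p6/2", "ctgB", 200L, 260L, "-", "mate_second"))
  expect_equal(classify_link(fr, inw, ctg)$kind, "spanning")
  ff <- rbind(lifted_row("p7/1", "ctgA", 4500L, 4560L, "+", "mate_first"),
              lifted_row("p7/2", "ctgB", 200L, 260L, "+", "mate_second"))
  expect_equal(classify_link(ff, inw, ctg)$kind, "conflicting")
  expect_error(classify_link(fr, library_spec("other", 1, 0), ctg),
               "no library spec")
})

test_that("confirmation needs three intra pairs and zero conflicts", {
  ctg <- two_contigs()
  mk_links <- function(n_intra, n_confl) {
    rows <- list()
    for (i in seq_len(n_intra)) {
      rows[[length(rows) + 1L]] <- rbind(
        lifted_row(sprintf("i%d/1", i), "ctgA", 100L, 160L, "+",
                   "mate_first"),
        lifted_row(sprintf("i%d/2", i), "ctgA", 700L, 760L, "+",
                   "mate_second"))
    }
    for (i in seq_len(n_confl)) {
      rows[[length(rows) + 1L]] <- rbind(
        lifted_row(sprintf("c%d/1", i), "ctgA", 2500L, 2560L, "+",
                   "mate_first"),
        lifted_row(sprintf("c%d/2", i), "ctgB", 2000L, 2060L, "+",
                   "mate_second"))
    }
    classify_links(do.call(rbind, rows), lib1, ctg)
  }
  status_a <- function(links) {
    confirm_contigs(ctg, links)$status[1]
  }
  expect_equal(status_a(mk_links(3, 0)), "confirmed")
  expect_equal(status_a(mk_links(2, 0)), "unconfirmed")
  expect_equal(status_a(mk_links(4, 0)), "confirmed")
  expect_equal(status_a(mk_links(5, 1)), "conflicted")
  expect_equal(status_a(mk_links(3, 1)), "conflicted")

  # monotonicity: adding intra links never demotes; adding a conflict demotes
  expect_equal(status_a(mk_links(6, 0)), "confirmed")
  expect_equal(confirm_contigs(ctg, mk_links(5, 1),
                               max_conflicts = 1)$status[1], "confirmed")
})

test_that("error-free simulated data yields no conflicting links", {
  cfg <- sim_config(genome_len = 1e5, base_error_rate = 0, seed = 13)
  res <- run_assembly_sim(cfg)
  expect_gt(sum(res$links$kind == "spanning"), 0L)
  expect_equal(sum(res$links$kind == "conflicting"), 0L)
})
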