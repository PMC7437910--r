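# refscaf

Reference-guided assembly toolkit: contig stitching, mate-pair scaffolding
and assembly metrics for short-read data anchored to a related genome.

## The problem

Assembling a large mammalian genome from very short reads (75 bp fragment
reads, 60 bp mate-pair reads, as produced by ligation-based sequencers) is
hopeless de novo: the reads are shorter than most repeats. When a
well-assembled genome of a closely related species exists, the reads can
instead be *anchored* to that reference, stitched into contigs at each
locus, and then ordered and oriented into scaffolds using mate-pair
libraries with long inserts (here 1 kb and 3 kb). `refscaf` implements that
workflow as reusable, testable R components, for anyone who wants to run,
study or evaluate a reference-guided assembly pipeline without the original
multi-hundred-gigabyte inputs.

## The method

1. **Quality trimming** — each read is truncated immediately before the
   first base with Phred quality below Q15; reads shorter than 30 bp are
   discarded. Per-run statistics (read counts, yield, mean/median length,
   before and after) reproduce the accounting of a sequencing-run table
   (`trim_set()`, `percent_retained()`).
2. **Contig stitching** — read-to-reference placements (SAM, projected
   through their CIGARs onto reference columns) are chained whenever two
   placements share at least 50 bp of reference interval; each connected
   component becomes a contig via per-column majority consensus, with ties
   broken by summed base quality, then the reference base, then symbol
   order (`read_alignments()`, `build_contigs()`). Unmapped reads are
   collected for external de novo assembly (`collect_unmapped()`).
3. **Mate-pair confirmation** — read pairs are lifted into contig
   coordinates and classified: `intra` (both mates one contig), `spanning`
   (suffix-prefix geometry across two contigs), or `conflicting`. A contig
   is *confirmed* when at least three pairs lie inside it and no
   conflicting pair touches it (`classify_links()`, `confirm_contigs()`).
4. **Scaffolding** — spanning pairs are bundled into weighted edges between
   contig ends with insert-arithmetic gap estimates
   (`gap = insert_mean − d_up − d_down`); transitive skip edges are
   reduced away; greedy path-merging then accepts edges by decreasing
   weight whenever both contig ends are free path termini
   (`bundle_links()`, `greedy_path_merge()`, `emit_scaffolds()`).
5. **Metrics & synteny** — N50/L50 and ungapped lengths
   (`assembly_stats()`), repeat-family coverage from RepeatMasker output as
   interval unions over the closed family set LINE/LTR/SINE/Simple
   repeat/Satellite/ncRNA/Others (`repeat_summary()`), and coalescing of
   colinear whole-genome alignments (PAF, ≥100 bp) into syntenic blocks
   filtered at 1 Mb or 500 kb (`coalesce_segments()`, `filter_blocks()`).

A deterministic simulator (`sim_config()`, `run_assembly_sim()`) generates
a donor genome, a diverged reference (substitutions, indels, and donor-only
"novel segments" that break contigs exactly where a reference-guided
assembler must scaffold), fragment and mate-pair reads with decaying
quality profiles, and truth tables for end-to-end evaluation.

## Worked example

```r
library(refscaf)

cfg <- sim_config(genome_len = 2e5, seed = 42)   # 200 kb donor, 2% divergence
res <- run_assembly_sim(cfg)                     # trim -> stitch -> verify -> scaffold
ev  <- res$evaluation

cat(sprintf("reads simulated   : %d\n", nrow(res$reads)))
cat(sprintf("retained at Q15   : %.1f%%\n",
            percent_retained(res$trim$stats_q0, res$trim$stats_policy)))
cat(sprintf("contigs           : %d (N50 %s bp)\n", nrow(res$contigs),
            format(res$contig_stats$n50, big.mark = ",")))
cat(sprintf("confirmed contigs : %d\n", sum(res$contigs$status == "confirmed")))
cat(sprintf("scaffolds         : %d (N50 %s bp)\n",
            res$scaffold_stats$n_records,
            format(res$scaffold_stats$n50, big.mark = ",")))
cat(sprintf("donor coverage    : %.2f%%\n", ev$coverage_pct))
cat(sprintf("consensus identity: %.3f%%\n", ev$identity_pct))
cat(sprintf("adjacency accuracy: %.1f%% of %d true pairs\n",
            ev$adjacency_pct, ev$n_true_pairs))
```

Output:

```
reads simulated   : 146668
retained at Q15   : 64.9%
contigs           : 23 (N50 19,090 bp)
confirmed contigs : 19
scaffolds         : 3 (N50 200,643 bp)
donor coverage    : 99.70%
consensus identity: 99.998%
adjacency accuracy: 95.0% of 20 true pairs
```

Reading: of ~147k simulated reads, 64.9% survive Q15 trimming (the failed
fraction of the quality model falls to the trimmer). The retained reads
stitch into 23 contigs covering 99.7% of the donor at 99.998% consensus
identity; mate pairs confirm 19 of them and merge the lot into 3 scaffolds
whose N50 jumps from 19 kb to 200 kb — 19 of 20 truly adjacent,
link-supported contig pairs are joined in the right order and orientation.

A command-line front end is installed with the package
(`exec/refscaf`): `refscaf trim`, `refscaf contigs`, `refscaf stats`,
`refscaf repeats`, `refscaf synteny`, `refscaf simulate`.

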