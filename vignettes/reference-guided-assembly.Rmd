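---
title: "Reference-guided assembly with refscaf: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided assembly with refscaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refscaf)
```

## The procedure and its assumptions

`refscaf` implements a reference-guided assembly workflow for very short
reads. The central assumption is that a closely related, well-assembled
genome exists and is colinear with the target genome over read-length
scales, so that a read's best placement on the reference identifies its
true locus. Under that assumption assembly decomposes into local,
independent problems: every reference column collects the read bases
projected onto it, and a per-column majority vote reconstructs the target
allele. Divergence between the genomes does not harm the consensus — reads
carry the target allele, so at a substituted site the majority is the
target base, not the reference base — but target sequence *absent from the
reference* can never be recovered by this route; it surfaces as unmapped
reads (delegated to external de novo assembly) and as breaks between
contigs that mate-pair libraries must then bridge.

Coordinates are 0-based half-open everywhere inside the package; 1-based
conventions appear only at the SAM and AGP serialisation edges.

## Stage by stage

**Trimming.** A read is cut immediately before its first base with quality
below `q_floor` (default Q15 ≈ 3% error probability); cut reads shorter
than `min_len` (default 30 bp) are dropped. This is a pure suffix
truncation — no 5' trimming and no sliding window — because ligation-era
quality degrades with cycle number and the accounting of run tables
(reads, yield, mean/median before and after) is exactly reproducible under
this rule. Mates are trimmed independently; a widowed mate is demoted to
fragment status rather than discarded, preserving its coverage while
keeping the pair set consistent.

**Stitching.** Two placements chain when their reference intervals share at
least `min_overlap` bases (default 50 bp); contigs are the connected
components of that relation, collapsed by majority consensus. Overlap is
measured on reference coordinates, not sequence identity, because the
placement step has already committed each read to a locus. Insertions
relative to the reference are dropped at projection time (the
reference-projected frame cannot host them without a realignment stage);
deletion columns are retained as gap symbols and removed when the majority
calls them. Consensus ties break by (1) the highest summed base quality,
(2) the reference base when a reference window is supplied, (3) the
lexicographically smallest symbol — in that order, so the tie-break is
deterministic with or without qualities. Note a structural consequence of
the overlap rule: a placement shorter than `min_overlap` can never chain,
so the pipeline entry point uses only placements of at least that width as
stitching input; shorter placements still participate in mate-link
classification by lifting onto the contigs that contain them. Seeding
single-read contigs inside real ones would otherwise manufacture spurious
cross-contig conflicts.

**Mate classification.** Pairs lifted into contig coordinates are `intra`,
`spanning` or `conflicting`. The library chemistry fixes which mate is
upstream: on a same-strand (mate-pair) library a `+/+` pair has its first
mate upstream and a `-/-` pair its second; on an inward (paired-end)
library the `+` mate is upstream. A cross-contig pair is spanning only if
each mate lies within `end_window` of the contig end facing the implied
gap. The default window is `insert_mean + 4·insert_sd + 50`: the simulator
(and the classifier's model of a library) treats inserts as supported on
±4 SD, and two abutting contigs can share up to `min_overlap − 1 ≈ 50` bp
of anchor, so a smaller window would misclassify legitimate tail-insert
pairs as conflicts. Confirmation follows the published rule: at least
three intra pairs and not a single conflicting pair (`--max-conflicts`
exposes a tolerance, default 0).

**Scaffolding.** Spanning links bundle into edges keyed by contig pair and
orientation class; per pair only the heaviest class is kept. Gap estimates
use standard insert arithmetic and may be negative (implied overlap).
Before path construction, *transitive* skip edges are removed: an edge A–C
is dropped when edges A–B and B–C chain through compatible ends and
`gap(A,C) ≈ gap(A,B) + len(B) + gap(B,C)` within three combined SDs
(floor 200 bp). Without this standard scaffold-graph step a heavy
long-insert edge that skips a short contig would claim a path terminus
before the true adjacent edges are processed. Greedy path-merging then
accepts edges by decreasing weight (ties: smaller gap SD, then pair id —
fully deterministic) whenever both implicated contig ends are free termini
of different paths; merging may reverse one path, which flips its contigs'
orientations consistently and never flips a contig relative to its own
path. Emitted gaps are `max(round(gap), min_gap)` Ns (default minimum 10);
negative estimates are clamped, not overlap-merged, since no overlap-merge
stage exists in this workflow.

**Metrics.** N50/L50 follow the minimal-prefix definition. Ungapped length
excludes `N`/`n` only; IUPAC ambiguity codes count as sequence. Repeat
coverage is the per-family union of intervals (nested RepeatMasker hits do
not double-count), with RepeatMasker class strings mapped onto the closed
set {LINE, LTR, SINE, Simple repeat, Satellite, ncRNA, Others};
`Low_complexity` merges into Simple repeat and the small structural RNAs
into ncRNA. Percentages are rendered both rounded (half away from zero)
and truncated, because published tables are not always consistent about
which they use.

**Synteny.** Alignment segments below 100 bp are discarded; segments on one
(reference, query, strand) triple chain when both coordinate gaps are at
most `max_join_gap` and the query order is monotone (reversed on `-`).
`max_join_gap` defaults to 50 kb — large enough to bridge repeat-masked
holes in whole-genome alignments, small enough not to fuse rearrangements;
it is exposed because no single value suits every genome pair. Overlapping
input segments are trimmed at the midpoint of their reference overlap
before chaining, a symmetric choice that makes chaining well-defined.
Strand inversions inside a block are not permitted (one strand per block).
Blocks are reported in reference coordinates and filtered at 1 Mb — or
500 kb for fragmented assemblies where the stricter threshold would leave
too little to plot.

## The simulator: what it emulates, and what it does not

`simulate_genomes()` builds a donor (the genome to recover) and derives the
reference from it by substitutions (default rate 0.02, the divergence
scale of closely related bovids), 1 bp indels (rate 0.001), and
`novel_segment_count` donor-only segments (default one per 100 kb, mean
300 bp). The novel segments are the load-bearing feature: they emulate
target-specific sequence absent from the related reference. Reads crossing
them cannot be placed, so contigs break there and mate pairs spanning them
carry real, nonzero gaps — without them a uniformly covered donor yields
one contig per chromosome and the scaffolder has nothing to do.

Reads are uniform-start; mate inserts are normal, truncated at ±4 SD
(defaults 1 kb ± 100 and 3 kb ± 300, same-strand orientation, 10× each;
fragments 75 bp at 30×). Qualities follow a two-population decay model:
a `fail_frac` (default 0.35) of reads whose mean quality crosses Q15 near
cycle 18 — these fall to the trimmer almost entirely — and good reads
whose profile crosses Q15 near cycle 110, i.e. beyond the read length, so
retained reads stay near full length. The defaults were chosen so that the
*retention fraction* (~60–65% of reads) resembles the published run
accounting while retained reads remain long enough for the 50 bp stitching
rule to chain them; a single-population model matching the published
*mean retained length* (~50 bp) instead would leave almost no pairwise
overlaps of 50 bp and contradict the contig sizes that workflow actually
reported. This is the one place where the generator favours internal
coherence over imitating every printed statistic at once, and it is the
reason passing tests speak to the pipeline's correctness, not to any claim
about real base-caller error profiles.

Alignment is truth-derived (`align_truth()`): reads are placed through the
donor↔reference coordinate maps rather than by an external mapper, which
keeps the pipeline hermetic and its "mapped reads" input boundary exact.
Consequently mapping *errors* (mismapping in repeats, clipped alignments)
are outside the simulation's scope; `repeat_fraction` exists to put repeat
sequence into the donor, but every read still maps to its true locus.
Truth-based evaluation measures donor coverage of contig anchors,
consensus identity over donor-backed columns (a consensus deletion at a
donor-backed column counts as a miss), and adjacency accuracy over
truly-neighbouring, link-supported contig pairs; joins that skip a short
contig but place their flanks at the right distance are reported as false
joins yet distinguished from *far* false joins (true separation beyond
three insert SDs), which are the genuinely harmful misassemblies.

## Numerical and degenerate-input choices

* Median of an even count is the mean of the two central values; a
  floor-style integer rendering is available at the reporting layer.
* `nx_lx()` errors on an empty length set; `assembly_stats()` errors on an
  empty assembly; `percent_retained()` errors when the before-count is 0.
* Empty FASTQ files parse to empty read sets (and write back as empty
  files); an empty unmapped-id set exports a zero-byte FASTQ.
* Cluster-internal zero-coverage columns are an error by construction
  (components of a positive-overlap relation are contiguous); the check
  guards against hand-built clusters.
* All generator randomness flows from a single integer seed
  (`sim_config(seed=)`), with reads drawn under `seed + 1` so genome and
  read sets are independently reproducible; no hash-order dependence.

## Problem sizes used by the test suite

Oracle-equivalence tests run at deliberately small sizes (hundreds of
placements or segments, path instances of ≤6 contigs against exhaustive
search, 1,000 random length sets for N50). The end-to-end recovery test
and the acceptance script use a 2 Mb donor at 30× fragment and 2×10× mate
coverage — about 1.5 million reads — which exercises every stage at
realistic depth while completing in a few minutes; recovery results are
stable across seeds at this size (coverage and identity fluctuate in the
third decimal, adjacency by at most one pair in ~180).

## Known limitations

* Insertions relative to the reference are not recovered; the consensus
  lives strictly in the reference-projected frame.
* Conflicted contigs are flagged, not broken; no contig-correction stage.
* One placement per read (secondary/supplementary SAM records ignored), so
  repeat-induced multi-mapping must be resolved upstream.
* Scaffolding implements a single greedy path-merging pass; short contigs
  whose direct link support falls below `min_links` can be bypassed (left
  as singletons) even when their neighbours join around them.
* Gap filling, overlap merging of negative-gap neighbours, and iterative
  re-scaffolding are out of scope.
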