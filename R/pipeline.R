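#' Run the full reference-guided assembly pipeline on simulated data
#'
#' Convenience wrapper chaining the stages end to end: simulate genomes and
#' reads, trim at the quality floor, place reads on the diverged reference
#' from truth, stitch placements into consensus contigs, classify mate-pair
#' links, confirm contigs, bundle links and greedily merge paths, emit
#' scaffold sequences, and score the result against the truth.
#'
#' Placements shorter than `min_overlap` are not used as stitching input
#' (they can never satisfy the overlap criterion and would only seed
#' single-read contigs inside real ones); they still participate in link
#' classification by lifting onto the contigs that contain them.
#'
#' @param config a [sim_config()].
#' @param min_overlap stitching overlap threshold in bp (default 50).
#' @param min_support mate-pair confirmation threshold (default 3).
#' @param min_links scaffold edge weight threshold (default 3).
#' @param min_gap minimum emitted scaffold gap in bp (default 10).
#' @param trim trimming policy (default [trim_policy()]).
#' @return list with every intermediate product: `genomes`, `reads`,
#'   `trim` (trim_set result), `aligned`, `contigs`, `coverage`, `links`,
#'   `edges`, `paths`, `scaffolds`, `contig_stats`, `scaffold_stats`,
#'   `evaluation`.
#' @export
run_assembly_sim <- function(config, min_overlap = 50L, min_support = 3L,
                             min_links = 3L, min_gap = 10L,
                             trim = trim_policy()) {
  genomes <- simulate_genomes(config)
  sim <- simulate_reads(genomes, config)
  tr <- trim_set(sim$reads, trim)
  aligned <- align_truth(tr$retained, genomes, sim$truth)
  pl <- aligned$placements
  stitch <- pl[pl$ref_end - pl$ref_start >= min_overlap, , drop = FALSE]
  built <- build_contigs(stitch, min_overlap = min_overlap,
                         ref_lengths = c(ref1 = genomes$ref_len),
                         reference = c(ref1 = genomes$reference))
  mates <- pl[pl$mate_role %in% c("mate_first", "mate_second"), ,
              drop = FALSE]
  lifted <- lift_to_contigs(mates, built$contigs)
  links <- classify_links(lifted, config$libraries, built$contigs)
  contigs <- confirm_contigs(built$contigs, links, min_support = min_support)
  edges <- bundle_links(links)
  paths <- greedy_path_merge(contigs$contig_id, edges,
                             min_weight = min_links,
                             contig_lengths = stats::setNames(
                               nchar(contigs$seq), contigs$contig_id))
  scaffolds <- emit_scaffolds(paths,
                              stats::setNames(contigs$seq,
                                              contigs$contig_id),
                              min_gap = min_gap)
  evaluation <- truth_evaluate(contigs, paths, genomes, edges,
                               min_weight = min_links)
  list(genomes = genomes, reads = sim$reads, truth = sim$truth, trim = tr,
       aligned = aligned, contigs = contigs, coverage = built$coverage,
       links = links, edges = edges, paths = paths, scaffolds = scaffolds,
       contig_stats = assembly_stats(contigs$seq),
       scaffold_stats = assembly_stats(scaffolds$seqs),
       evaluation = evaluation)
}
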