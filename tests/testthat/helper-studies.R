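# One complete simulated enrichment study: generate a genome with a
# 12-mer planted at the given per-promoter rates in the target set and
# background, run the full promoter/scan/Monte-Carlo pipeline, and
# return the strict empirical p-value for the planted motif.
simulate_study <- function(seed, rate_target, rate_background,
                           n_genes = 2000, target_set_size = 200,
                           n_random_sets = 500) {
  motif <- consensus_motif("planted", "TTGCCGTGGTAA")
  spec <- synthetic_genome_spec(
    n_genes, motifs = list(motif),
    planting_rate_target = rate_target,
    planting_rate_background = rate_background,
    target_set_size = target_set_size, seed = seed)
  bundle <- generate_genome(spec)
  promoters <- extract_promoters(bundle$genome,
                                 filter_by_length(bundle$genes))
  counts <- count_occurrences(promoters, list(motif))
  cfg <- mc_config(gene_set("universe", rownames(counts)),
                   n_random_sets = n_random_sets,
                   random_set_size = target_set_size,
                   seed = seed + 500000L)
  test <- run_mc_test(counts, bundle$truth$target_set, config = cfg)
  test$results$planted$p_strict
}
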