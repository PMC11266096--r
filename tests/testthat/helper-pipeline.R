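# Shared heavy fixtures for the split-and-reintegrate experiments. Built
# once per test run and cached.

split_benchmark_env <- new.env()

# Full pseudo-species benchmark: simulate one species, split it, identify
# proxies between the genome halves from the bulk network restricted to each
# half, and return everything downstream tests need.
split_benchmark <- function() {
  if (!is.null(split_benchmark_env$res)) return(split_benchmark_env$res)
  sim <- simulate_celltype_dataset(seed = 1)
  sp <- split_dataset(sim$sc, sim$families, seed = 2)
  net_full <- build_rank_network(sim$bulk)
  g1 <- intersect(names(sp$gene_half)[sp$gene_half == 1],
                  rownames(net_full$weights))
  g2 <- intersect(names(sp$gene_half)[sp$gene_half == 2],
                  rownames(net_full$weights))
  net_a <- subset_network(net_full, g1)
  net_b <- subset_network(net_full, g2)
  cm <- conservation_matrix(net_a, net_b, sp$families)
  selected <- select_proxies(cm, sp$families, "moderate")
  worst <- select_worst_proxies(cm, sp$families)
  random <- random_pairs(g1, g2, nrow(selected), seed = 3)
  res <- list(sim = sim, split = sp, scores = cm, selected = selected,
              worst = worst, random = random)
  split_benchmark_env$res <- res
  res
}

mixed_fraction <- function(expr_a, expr_b, pairs, seed = 0) {
  ad <- suppressWarnings(align_gene_spaces(expr_a, expr_b, pairs))
  cl <- joint_embed_cluster(ad, seed = seed)
  mixing_metrics(cl, ad$dataset_labels, ad$cell_types)
}
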