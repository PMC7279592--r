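# The 20-seed default-benchmark study shared by the larger acceptance
# checks: for each seed, the ground truth, the three point-estimate trees
# on the full concatenation (the "before" ensemble of the pruning
# experiment), their RF distances to the truth, the per-gene saturation
# indices, and the congruence of the ensemble before/after pruning.
# Computed once per session, on first use.
study_env <- new.env(parent = emptyenv())

recovery_study <- function(n_seeds = 20) {
  key <- paste0("study_", n_seeds)
  if (!is.null(study_env[[key]])) return(study_env[[key]])
  gene_tab <- default_gene_table()
  idx_mat <- matrix(NA_real_, n_seeds, nrow(gene_tab),
                    dimnames = list(NULL, gene_tab$gene))
  rf_truth <- matrix(NA_real_, n_seeds, 3,
                     dimnames = list(NULL, c("nj", "mp", "ml")))
  congruent_before <- congruent_after <- logical(n_seeds)
  genes_removed <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    truth <- make_benchmark(simulation_config(seed = s))
    aln <- truth$alignment
    pm <- truth$partition_map
    config <- benchmark_config(methods = c("nj", "mp", "ml"),
                               outgroup = truth$outgroup, seed = 1)
    px <- pruning_experiment(aln, pm, config, k = 4)
    rf_truth[s, ] <- vapply(c("nj", "mp", "ml"), function(m) {
      rf_distance(px$before$trees[[m]], truth$tree)
    }, numeric(1))
    congruent_before[s] <- px$congruent_before
    congruent_after[s] <- px$congruent_after
    genes_removed[[s]] <- px$genes_removed
    for (g in gene_tab$gene) {
      idx_mat[s, g] <- saturation_profile(extract_gene(aln, pm, g),
                                          pm$genes[[g]]$model,
                                          gene_name = g)$index_r
    }
  }
  out <- list(rf_truth = rf_truth,
              congruent_before = congruent_before,
              congruent_after = congruent_after,
              genes_removed = genes_removed,
              indices = idx_mat,
              multipliers = stats::setNames(gene_tab$rate_multiplier, gene_tab$gene))
  study_env[[key]] <- out
  out
}
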