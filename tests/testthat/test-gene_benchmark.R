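# shared small benchmark: 8 taxa, 4 genes, NJ-only reference with a
# modest bootstrap — big enough to exercise every stage, small enough to
# keep the suite fast
small_genes <- function() {
  tibble::tibble(
    gene = c("gA", "gB", "gC", "gD"),
    length = c(800L, 600L, 400L, 200L),
    model_name = c("HKY", "TN93", "HKY", "TN93"),
    rate_multiplier = c(0.5, 1, 2, 8)
  )
}

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- make_benchmark(simulation_config(n_taxa = 8, genes = small_genes(),
                                                seed = 101))
      config <- benchmark_config(methods = "nj", boot_replicates = 40, seed = 5)
      ref <- build_reference(truth$alignment, truth$partition_map, config)
      cache <<- list(truth = truth, config = config, ref = ref)
    }
    cache
  }
})

test_that("the reference set carries support-annotated trees per method", {
  w <- small_world()
  expect_named(w$ref$trees, "nj")
  sup <- tidy(bipartitions(w$ref$trees$nj))$support
  expect_true(all(sup >= 0 & sup <= 100))
  # single-method consensus is that method's tree
  expect_equal(rf_distance(w$ref$consensus, w$ref$trees$nj), 0)
})

test_that("self-evaluation of the full concatenation deviates by zero", {
  w <- small_world()
  ev <- evaluate_subset(gene_names(w$truth$partition_map),
                        w$truth$alignment, w$truth$partition_map,
                        w$ref, w$config)
  expect_true(all(ev$summary$deviation == 0))
  expect_true(all(ev$summary$n_conflicting == 0))
})

test_that("per-gene evaluation produces bounded deviations and is order-invariant", {
  w <- small_world()
  ev <- evaluate_gene("gA", w$truth$alignment, w$truth$partition_map, w$ref)
  n_ref_splits <- length(bipartitions(
    collapse_low_support(w$ref$trees$nj, w$config$cutoff))$splits)
  expect_true(all(ev$summary$deviation <= n_ref_splits))
  expect_equal(ev$summary$n_coinciding + ev$summary$n_conflicting +
                 ev$summary$n_unresolved, n_ref_splits)
  # permuting taxon order leaves the report unchanged
  perm <- alignment(unclass(w$truth$alignment)[sample(8), ])
  ev2 <- evaluate_gene("gA", perm, w$truth$partition_map, w$ref)
  expect_equal(ev2$summary$deviation, ev$summary$deviation)
  expect_error(evaluate_subset(character(0), w$truth$alignment,
                               w$truth$partition_map, w$ref), "at least one")
})

test_that("a saturated short gene deviates at least as much as a long slow gene", {
  # aggregated over a few replicates; mirrors the contrast between an
  # unsaturated rRNA-like gene and a fast-evolving mini-gene
  contrast_genes <- tibble::tibble(
    gene = c("gA", "gB", "gC", "gD"),
    length = c(800L, 600L, 400L, 400L),
    model_name = c("HKY", "TN93", "HKY", "HKY"),
    rate_multiplier = c(0.5, 1, 2, 4)
  )
  devs <- sapply(1:6, function(s) {
    truth <- make_benchmark(simulation_config(n_taxa = 8, genes = contrast_genes,
                                              seed = 200 + s, tree_depth = 0.12,
                                              outgroup_stem_multiplier = 2))
    config <- benchmark_config(methods = "nj", boot_replicates = 40, seed = s)
    ref <- build_reference(truth$alignment, truth$partition_map, config)
    c(slow = evaluate_gene("gA", truth$alignment, truth$partition_map, ref)$summary$deviation,
      fast = evaluate_gene("gD", truth$alignment, truth$partition_map, ref)$summary$deviation)
  })
  expect_gte(mean(devs["fast", ] >= devs["slow", ]), 0.8)
  expect_gt(mean(devs["fast", ]), mean(devs["slow", ]))
})

test_that("a gene saturated beyond its distance model is reported not evaluable", {
  w <- small_world()
  # gD: 200 bp at 8x on a deep tree; most pairwise distances overflow
  ev <- evaluate_gene("gD", w$truth$alignment, w$truth$partition_map, w$ref)
  expect_false(ev$summary$evaluable)
  expect_true(is.na(ev$summary$deviation))
  expect_match(ev$summary$reason, "undefined|failed")
})

test_that("the ranking table assembles lengths, sites, indices and deviations", {
  w <- small_world()
  bm <- gene_benchmark(w$truth$alignment, w$truth$partition_map, w$config)
  rk <- tidy(bm)
  expect_equal(nrow(rk), 4L)
  expect_true(all(c("gene", "bp", "n_variable_sites", "saturation_index",
                    "saturation_rank", "deviation_nj") %in% names(rk)))
  expect_equal(rk$bp, small_genes()$length)
  expect_true(all(rk$deviation_nj >= 0, na.rm = TRUE))
  expect_equal(glance(bm)$n_genes, 4L)

  # reports are reproducible byte for byte
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(bm, d1)
  bm2 <- gene_benchmark(w$truth$alignment, w$truth$partition_map, w$config)
  write_report(bm2, d2)
  expect_identical(readLines(file.path(d1, "gene_ranking.tsv")),
                   readLines(file.path(d2, "gene_ranking.tsv")))
  expect_true(file.exists(file.path(d1, "reference_nj.nwk")))
})

test_that("saturation-deviation correlation matches a constructed linear ranking", {
  rk <- tibble::tibble(gene = letters[1:10],
                       saturation_index = seq(0.2, 0.95, length.out = 10))
  rk$deviation_nj <- round(10 * (1 - rk$saturation_index))
  out <- saturation_deviation_correlation(rk, "nj")
  expect_lt(out$r, -0.95)
  expect_lt(out$p_value, 0.01)
  # constant deviation column: undefined
  rk$deviation_nj <- 3
  expect_true(is.na(saturation_deviation_correlation(rk, "nj")$r))
  # independent draws: usually small and non-significant
  set.seed(9)
  ps <- replicate(60, {
    rk$deviation_nj <- sample(0:5, 10, replace = TRUE)
    rk$saturation_index <- stats::runif(10)
    saturation_deviation_correlation(rk, "nj")$p_value
  })
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.8)
})

test_that("the pruning experiment removes the saturated genes and reruns", {
  truth <- make_benchmark(simulation_config(n_taxa = 8, genes = small_genes(),
                                            seed = 301))
  config <- benchmark_config(methods = c("nj", "mp"), boot_replicates = 10,
                             prune_k = 1, outgroup = truth$outgroup, seed = 2)
  px <- pruning_experiment(truth$alignment, truth$partition_map, config)
  expect_equal(length(px$genes_removed), 1L)
  expect_equal(px$taxa_removed, truth$outgroup)
  expect_true(all(!px$taxa_removed %in% px$after$trees$nj$tip.label))
  expect_true(is.logical(px$congruent_before) && is.logical(px$congruent_after))
  expect_error(
    pruning_experiment(truth$alignment, truth$partition_map,
                       benchmark_config(methods = "nj", outgroup = "ghost")),
    "outgroup")
  # no pruning, no exclusion: before and after agree
  cfg0 <- benchmark_config(methods = "nj", prune_k = 0, seed = 2)
  px0 <- pruning_experiment(truth$alignment, truth$partition_map, cfg0)
  expect_equal(rf_distance(px0$before$trees$nj, px0$after$trees$nj), 0)
})
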