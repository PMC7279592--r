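#' Benchmark configuration
#'
#' Run parameters of the gene-informativeness experiment: the inference
#' methods, bootstrap replicate count (100 by default in benchmark mode;
#' recorded in every report), the support cutoff below which nodes are
#' treated as unresolved (51 on the 0-100 bootstrap percentage scale),
#' the number of most-saturated genes to prune, the outgroup taxon
#' labels (explicit; no automatic outgroup detection), and the master
#' seed.
#'
#' @param methods Non-empty subset of `c("nj", "mp", "ml")`.
#' @param boot_replicates Bootstrap replicates (>= 1).
#' @param cutoff Support cutoff in `[0, 100]`.
#' @param prune_k Number of most-saturated genes removed by the pruning
#'   experiment.
#' @param outgroup Character vector of outgroup taxon labels (may be
#'   empty).
#' @param mp_starts Random-addition starts for heuristic MP searches.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods = c("nj", "mp", "ml"),
                             boot_replicates = 100, cutoff = 51,
                             prune_k = 4, outgroup = character(),
                             mp_starts = 3, seed = 1) {
  methods <- match.arg(methods, c("nj", "mp", "ml"), several.ok = TRUE)
  if (length(methods) == 0L) abort("at least one method is required")
  if (boot_replicates < 1L) abort("boot_replicates must be >= 1")
  if (cutoff < 0 || cutoff > 100) abort("cutoff must be in [0, 100]")
  structure(list(methods = methods,
                 boot_replicates = as.integer(boot_replicates),
                 cutoff = cutoff, prune_k = as.integer(prune_k),
                 outgroup = outgroup, mp_starts = as.integer(mp_starts),
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# per-method seed offsets keep method streams independent but reproducible
method_seed <- function(config, method, block = 0L) {
  config$seed + 100000L * block +
    10000L * match(method, c("nj", "mp", "ml"))
}

# model driving each method on a given alignment unit: NJ uses the
# partition's distance model, ML its default HKY-with-empirical-
# frequencies model, MP none
unit_builder <- function(method, model, config, seed) {
  method_builder(method,
                 model = if (method == "nj") model else NULL,
                 seed = seed, mp_starts = config$mp_starts)
}

#' Reference topologies from the full concatenation
#'
#' Builds the whole-matrix tree for every configured method (with
#' bootstrap supports when `support = TRUE`) plus their strict
#' consensus. A method whose builder fails is dropped from the ensemble
#' with a warning.
#'
#' @param aln The full concatenated alignment (control-region segments
#'   excluded upstream).
#' @param pm The [partition_map()] (carried into the result's metadata).
#' @param config A [benchmark_config()].
#' @param support Annotate each method tree with bootstrap supports.
#' @param model Distance model for the NJ reference; the log-det
#'   distance by default, the standard choice for a GTR-class
#'   supermatrix.
#' @return A list of class `reference_set`: `trees` (named by method),
#'   `consensus` (strict), `config`.
#' @export
build_reference <- function(aln, pm, config = benchmark_config(),
                            support = TRUE, model = model_spec("LOGDET")) {
  aln <- as_alignment(aln)
  trees <- list()
  for (m in config$methods) {
    seed_m <- method_seed(config, m)
    builder <- unit_builder(m, model, config, seed_m)
    tr <- tryCatch({
      if (support) bootstrap_support(aln, builder, config$boot_replicates, seed_m)
      else builder(aln)
    }, error = function(e) {
      warn(sprintf("method '%s' failed on the reference matrix: %s; dropped",
                   m, conditionMessage(e)))
      NULL
    })
    if (!is.null(tr)) trees[[m]] <- tr
  }
  if (!length(trees)) abort("every method failed on the reference matrix")
  structure(list(trees = trees,
                 consensus = if (length(trees) > 1L) strict_consensus(trees)
                             else trees[[1L]],
                 config = config),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set: methods %s>\n", paste(names(x$trees), collapse = ", ")))
  invisible(x)
}

# shared core of evaluate_gene / evaluate_subset
evaluate_unit <- function(sub, label, reference, config, model, block) {
  reports <- list()
  rows <- list()
  for (m in names(reference$trees)) {
    seed_m <- method_seed(config, m, block)
    builder <- unit_builder(m, model, config, seed_m)
    res <- tryCatch({
      if (m == "nj") {
        # a unit whose distances are mostly undefined is not evaluable
        dm <- withCallingHandlers(
          distance_matrix(sub, model),
          warning = function(w) invokeRestart("muffleWarning"))
        if (attr(dm, "n_undefined") > 0.25 * choose(nrow(sub), 2)) {
          abort(sprintf("'%s': >25%% of pairwise distances undefined under %s",
                        label, format_model_token(model)))
        }
      }
      test <- bootstrap_support(sub, builder, config$boot_replicates, seed_m)
      classify_splits(reference$trees[[m]], test, cutoff = config$cutoff,
                      reference_id = paste0("mitogenome-", m),
                      test_id = paste0(label, "-", m))
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "congruence_report")) {
      reports[[m]] <- res
      rows[[m]] <- dplyr::mutate(glance(res), method = m, evaluable = TRUE,
                                 reason = NA_character_)
    } else {
      rows[[m]] <- tibble(reference = paste0("mitogenome-", m),
                          test = paste0(label, "-", m),
                          support_cutoff = config$cutoff,
                          n_coinciding = NA_integer_, n_conflicting = NA_integer_,
                          n_unresolved = NA_integer_, deviation = NA_integer_,
                          method = m, evaluable = FALSE, reason = res)
    }
  }
  structure(list(label = label, reports = reports,
                 summary = dplyr::bind_rows(rows)),
            class = "gene_evaluation")
}

#' @export
print.gene_evaluation <- function(x, ...) {
  cat(sprintf("<gene_evaluation '%s'>\n", x$label))
  print(x$summary[, c("method", "n_coinciding", "n_conflicting",
                      "n_unresolved", "deviation", "evaluable")])
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_evaluation <- function(x, ...) x$summary

#' Evaluate one gene against the reference topology
#'
#' Extracts the gene, builds its tree with bootstrap supports for every
#' method of the reference, collapses both trees at the support cutoff,
#' and classifies the reference splits (per method, against the same
#' method's reference tree). The per-method `deviation` is the number of
#' conflicting plus unresolved reference nodes. A gene whose distances
#' are undefined for more than 25% of pairs under its model is reported
#' as not evaluable rather than silently skipped.
#'
#' @param gene Gene name in the partition map.
#' @param aln The full alignment the map indexes.
#' @param pm A [partition_map()].
#' @param reference A [build_reference()] result (support-annotated).
#' @param config The [benchmark_config()] used for the reference.
#' @return A `gene_evaluation` (per-method reports plus a summary
#'   tibble).
#' @export
evaluate_gene <- function(gene, aln, pm, reference, config = reference$config) {
  sub <- extract_gene(aln, pm, gene)
  model <- pm$genes[[gene]]$model
  if (is.null(model)) model <- default_model()
  evaluate_unit(sub, gene, reference, config,
                model, block = match(gene, gene_names(pm)))
}

#' @rdname evaluate_gene
#' @param genes Character vector of gene names (>= 1) to concatenate and
#'   evaluate as one unit, e.g. `c("16S", "CYTB")`.
#' @export
evaluate_subset <- function(genes, aln, pm, reference, config = reference$config) {
  if (length(genes) == 0L) abort("at least one gene name is required")
  sub <- concatenate_genes(aln, pm, genes)
  label <- paste(genes, collapse = "+")
  # subset model: the default GTR-class model of the concatenation
  evaluate_unit(sub, label, reference, config, default_model(),
                block = 99L)
}

#' Full gene-informativeness benchmark
#'
#' The end-to-end experiment: reference trees from the concatenation,
#' per-gene saturation profiles and congruence evaluations, and the
#' ranking table (one row per gene: length, variable sites, saturation
#' index, per-method deviation, saturation rank).
#'
#' @inheritParams evaluate_gene
#' @param config A [benchmark_config()].
#' @param taxon_subset Optional taxa restriction for the saturation
#'   profiles (e.g. ingroup only); profiles are labeled accordingly.
#' @return A list of class `gene_benchmark`: `ranking` (tibble),
#'   `reference`, `profiles`, `evaluations`, `config`.
#' @export
gene_benchmark <- function(aln, pm, config = benchmark_config(),
                           taxon_subset = NULL) {
  aln <- as_alignment(aln)
  reference <- build_reference(aln, pm, config)
  profiles <- lapply(gene_names(pm), function(g) {
    model <- pm$genes[[g]]$model
    if (is.null(model)) model <- default_model()
    saturation_profile(extract_gene(aln, pm, g), model,
                       taxon_subset = taxon_subset, gene_name = g,
                       subset_label = if (is.null(taxon_subset)) "all" else "subset")
  })
  names(profiles) <- gene_names(pm)
  evaluations <- lapply(gene_names(pm), function(g) {
    evaluate_gene(g, aln, pm, reference, config)
  })
  names(evaluations) <- gene_names(pm)
  ranks <- rank_genes_by_saturation(profiles)
  base <- partition_summary(aln, pm)
  dev <- dplyr::bind_rows(lapply(evaluations, function(ev) {
    tidyr::pivot_wider(
      dplyr::mutate(ev$summary, gene = ev$label),
      id_cols = "gene", names_from = "method", values_from = "deviation",
      names_prefix = "deviation_")
  }))
  ranking <- dplyr::left_join(base, tibble(gene = ranks$gene,
                                           saturation_index = ranks$index_r,
                                           saturation_rank = ranks$rank),
                              by = "gene")
  ranking <- dplyr::left_join(ranking, dev, by = "gene")
  structure(list(ranking = ranking, reference = reference,
                 profiles = profiles, evaluations = evaluations,
                 config = config),
            class = "gene_benchmark")
}

#' @export
print.gene_benchmark <- function(x, ...) {
  cat(sprintf("<gene_benchmark: %d genes, methods %s, %d bootstrap replicates, cutoff %g>\n",
              nrow(x$ranking), paste(x$config$methods, collapse = "/"),
              x$config$boot_replicates, x$config$cutoff))
  print(x$ranking)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_benchmark <- function(x, ...) x$ranking

#' @exportS3Method generics::glance
glance.gene_benchmark <- function(x, ...) {
  tibble(n_genes = nrow(x$ranking),
         methods = paste(x$config$methods, collapse = ","),
         boot_replicates = x$config$boot_replicates,
         cutoff = x$config$cutoff, seed = x$config$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gene_benchmark <- function(object, method = object$config$methods[1], ...) {
  col <- paste0("deviation_", method)
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$saturation_index, y = .data[[col]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "saturation index (transition-transversion correlation)",
                  y = sprintf("deviation from reference (%s)", method),
                  title = "Gene informativeness vs substitution saturation") +
    ggplot2::theme_minimal()
}

#' Correlation between saturation index and topological deviation
#'
#' Pearson correlation (with the two-sided t-approximation p-value)
#' between the per-gene saturation index and one method's deviation
#' column of a benchmark ranking. Undefined (`NA`) when either column is
#' constant or fewer than 3 genes have both values.
#'
#' @param ranking A `gene_benchmark` or its ranking tibble.
#' @param method Method whose deviation column to use.
#' @return A tibble: `method`, `r`, `p_value`, `n_genes`.
#' @export
saturation_deviation_correlation <- function(ranking, method = "nj") {
  if (inherits(ranking, "gene_benchmark")) ranking <- ranking$ranking
  col <- paste0("deviation_", method)
  if (!col %in% names(ranking)) abort(sprintf("no column '%s' in ranking", col))
  ok <- !is.na(ranking$saturation_index) & !is.na(ranking[[col]])
  x <- ranking$saturation_index[ok]
  y <- ranking[[col]][ok]
  if (length(x) < 3L || var(x) == 0 || var(y) == 0) {
    return(tibble(method = method, r = NA_real_, p_value = NA_real_,
                  n_genes = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(method = method, r = unname(ct$estimate),
         p_value = ct$p.value, n_genes = length(x))
}

#' Gene-pruning and outgroup-exclusion experiment
#'
#' Rebuilds the per-method reference topologies (point estimates) twice:
#' on all genes and all taxa, and after removing the `k` most saturated
#' genes and excluding the outgroup taxa. For each run the pairwise
#' Robinson-Foulds distances among methods are reported together with
#' whether the ensemble is fully congruent (all pairwise RF distances
#' zero) — the qualitative claim being that pruning saturated signal
#' makes the methods agree.
#'
#' Saturation profiles for the ranking are computed on the ingroup taxa
#' when an outgroup is configured (saturation assessed for the focal
#' clade, not dominated by outgroup pairs).
#'
#' @inheritParams gene_benchmark
#' @param k Number of genes to prune (default `config$prune_k`).
#' @return A list of class `pruning_experiment`: `before` / `after`
#'   (each with `trees` and `rf` tibble), `genes_removed`,
#'   `taxa_removed`, `congruent_before`, `congruent_after`.
#' @export
pruning_experiment <- function(aln, pm, config = benchmark_config(),
                               k = config$prune_k) {
  aln <- as_alignment(aln)
  if (length(config$outgroup)) {
    missing <- setdiff(config$outgroup, rownames(aln))
    if (length(missing)) {
      abort(sprintf("outgroup taxa not in alignment: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  ingroup <- setdiff(rownames(aln), config$outgroup)
  profile_subset <- if (length(config$outgroup)) ingroup else NULL
  profiles <- lapply(gene_names(pm), function(g) {
    model <- pm$genes[[g]]$model
    if (is.null(model)) model <- default_model()
    saturation_profile(extract_gene(aln, pm, g), model,
                       taxon_subset = profile_subset, gene_name = g,
                       subset_label = if (length(config$outgroup)) "ingroup-only" else "all")
  })
  run_ensemble <- function(a) {
    ref <- build_reference(a, pm, config, support = FALSE)
    ms <- names(ref$trees)
    rf <- if (length(ms) > 1L) {
      prs <- combn(ms, 2L)
      dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i) {
        tibble(method_a = prs[1L, i], method_b = prs[2L, i],
               rf = rf_distance(ref$trees[[prs[1L, i]]], ref$trees[[prs[2L, i]]]))
      }))
    } else tibble(method_a = character(0), method_b = character(0), rf = integer(0))
    list(trees = ref$trees, rf = rf,
         congruent = nrow(rf) == 0L || all(rf$rf == 0L))
  }
  before <- run_ensemble(aln)
  kept_genes <- prune_saturated(pm, profiles, k)
  pruned_aln <- concatenate_genes(aln[ingroup, ], pm, kept_genes)
  # the pruned run needs a partition map over the reduced concatenation
  offset <- 0L
  genes2 <- list()
  for (g in kept_genes) {
    len <- gene_length(pm, g)
    genes2[[g]] <- list(intervals = matrix(c(offset, offset + len), 1L, 2L),
                        model = pm$genes[[g]]$model)
    offset <- offset + len
  }
  pm2 <- partition_map(genes2, offset)
  after_ref <- build_reference(pruned_aln, pm2, config, support = FALSE)
  ms <- names(after_ref$trees)
  rf_after <- if (length(ms) > 1L) {
    prs <- combn(ms, 2L)
    dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i) {
      tibble(method_a = prs[1L, i], method_b = prs[2L, i],
             rf = rf_distance(after_ref$trees[[prs[1L, i]]],
                              after_ref$trees[[prs[2L, i]]]))
    }))
  } else tibble(method_a = character(0), method_b = character(0), rf = integer(0))
  structure(
    list(before = before,
         after = list(trees = after_ref$trees, rf = rf_after,
                      congruent = nrow(rf_after) == 0L || all(rf_after$rf == 0L)),
         genes_removed = setdiff(gene_names(pm), kept_genes),
         taxa_removed = config$outgroup,
         congruent_before = before$congruent,
         congruent_after = nrow(rf_after) == 0L || all(rf_after$rf == 0L),
         profiles = profiles),
    class = "pruning_experiment"
  )
}

#' @export
print.pruning_experiment <- function(x, ...) {
  cat(sprintf("<pruning_experiment: removed genes [%s], removed taxa [%s]>\n",
              paste(x$genes_removed, collapse = ","),
              paste(x$taxa_removed, collapse = ",")))
  cat(sprintf("  fully congruent ensemble: before = %s, after = %s\n",
              x$congruent_before, x$congruent_after))
  invisible(x)
}

#' Write benchmark reports to disk
#'
#' Emits the ranking as TSV (one row per gene), a JSON experiment record
#' (configuration, seed, methods), and Newick files for every reference
#' tree. Re-running from the same inputs and seed reproduces the files
#' byte for byte.
#'
#' @param benchmark A [gene_benchmark()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(as.data.frame(benchmark$ranking), file.path(dir, "gene_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(benchmark$config)
  jsonlite::write_json(cfg, file.path(dir, "experiment.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in names(benchmark$reference$trees)) {
    write_tree(benchmark$reference$trees[[m]],
               file.path(dir, sprintf("reference_%s.nwk", m)))
  }
  write_tree(benchmark$reference$consensus, file.path(dir, "reference_consensus.nwk"))
  for (g in names(benchmark$profiles)) {
    write_profile_tsv(benchmark$profiles[[g]],
                      file.path(dir, sprintf("profile_%s.tsv", g)))
  }
  invisible(dir)
}
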