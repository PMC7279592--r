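#' Sample a Yule (pure-birth) species tree
#'
#' Simulates a pure-birth process: starting from two lineages at the
#' root, the waiting time to the next speciation while `k` lineages
#' exist is exponential with rate `k * birth_rate`, and a uniformly
#' chosen lineage splits at each event. After the n-th lineage appears
#' the process runs for one further exponential waiting time (rate
#' `n * birth_rate`) before the tips are sampled, so the expected root
#' height is `sum_{k=2..n} 1 / (k * birth_rate)`. The result is
#' ultrametric with leaves labeled `t1..tn`.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional integer seed.
#' @return An ultrametric binary `phylo` tree.
#' @export
sample_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 2L) abort("n_taxa must be >= 2")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_taxa)
  root <- n + 1L
  next_internal <- n + 2L
  edges <- matrix(0L, 0L, 2L)
  lengths <- numeric(0)
  # active lineages: parent node id and birth time of the open branch
  act_parent <- c(root, root)
  act_birth <- c(0, 0)
  t_now <- 0
  while (length(act_parent) < n) {
    k <- length(act_parent)
    t_now <- t_now + rexp(1L, k * birth_rate)
    i <- sample.int(k, 1L)
    v <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(act_parent[i], v))
    lengths <- c(lengths, t_now - act_birth[i])
    act_parent <- c(act_parent[-i], v, v)
    act_birth <- c(act_birth[-i], t_now, t_now)
  }
  t_end <- t_now + rexp(1L, n * birth_rate)
  for (i in seq_len(n)) {
    edges <- rbind(edges, c(act_parent[i], i))
    lengths <- c(lengths, t_end - act_birth[i])
  }
  tr <- list(edge = edges, edge.length = lengths,
             tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# state propagation along one branch for a block of sites sharing a rate
propagate_states <- function(states, eig, t) {
  if (t <= 0) return(states)
  P <- transition_probs(eig, t)
  out <- states
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a gene alignment along a tree
#'
#' Forward simulation under a reversible nucleotide model: root states
#' are drawn from the stationary frequencies and each branch evolves
#' them with transition probabilities `P(t) = exp(Q * t)` (computed
#' exactly by eigendecomposition of the reversible rate matrix, which is
#' normalized to one expected substitution per unit branch length).
#' Branch lengths are scaled by `rate_multiplier` and by a per-site rate:
#' invariant sites (probability `p_invariant`) have rate 0 and the
#' remaining sites draw one of 4 discrete-gamma category rates, rescaled
#' so the expected rate over all sites is 1 and branch lengths keep their
#' substitutions-per-site meaning.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [model_spec()] (JC69 / K2P / HKY / TN93 / GTR).
#' @param length Number of sites to simulate.
#' @param rate_multiplier Positive gene-level rate scaler.
#' @param seed Optional integer seed.
#' @return A `phylosat_alignment` over the tree's leaves.
#' @export
simulate_gene <- function(tree, model, length, rate_multiplier = 1, seed = NULL) {
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (length < 1L) abort("length must be >= 1")
  if (rate_multiplier < 0) abort("rate_multiplier must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pi <- as.numeric(model$freqs)
  Q <- rate_matrix(model)
  eig <- rate_matrix_eigen(Q, pi)
  L <- as.integer(length)
  # per-site rates: invariant sites, then discrete gamma, mean 1 overall
  rates <- rep(1, L)
  if (model$p_invariant > 0) {
    inv <- runif(L) < model$p_invariant
  } else inv <- rep(FALSE, L)
  if (!is.null(model$gamma_alpha)) {
    cat_rates <- gamma_category_rates(model$gamma_alpha, 4L)
    rates <- cat_rates[sample.int(4L, L, replace = TRUE)]
  }
  rates[inv] <- 0
  if (any(!inv)) rates[!inv] <- rates[!inv] / (1 - model$p_invariant)
  n <- length(tree$tip.label)
  root <- n + 1L
  states <- matrix(0L, nrow = max(tree$edge), ncol = L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = pi)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  rate_groups <- split(seq_len(L), rates)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    bl <- tree$edge.length[e] * rate_multiplier
    child_states <- states[par, ]
    for (g in seq_along(rate_groups)) {
      r <- as.numeric(names(rate_groups)[g])
      idx <- rate_groups[[g]]
      child_states[idx] <- propagate_states(states[par, idx], eig, bl * r)
    }
    states[child, ] <- child_states
  }
  m <- matrix(.bases[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(m) <- tree$tip.label
  alignment(m)
}

#' Default gene table for synthetic benchmarks
#'
#' Fifteen mitochondrial genes with realistic lengths (161-1823 bp,
#' rRNAs plus the 13 protein-coding genes), a GTR/TN93/HKY model class
#' per gene with gamma rate heterogeneity and invariant sites, mito-like
#' A+T-rich base frequencies and a transition bias, and graded
#' rate multipliers spanning 0.5-8x so that the fastest genes reach
#' transition saturation while the rRNA-like genes stay unsaturated.
#'
#' @return A tibble with columns `gene`, `length`, `model_name`,
#'   `rate_multiplier`.
#' @export
default_gene_table <- function() {
  tibble(
    gene = c("12S", "16S", "ATP8", "ATP6", "COX1", "COX2", "COX3",
             "NADH1", "NADH2", "NADH3", "NADH4L", "NADH4", "NADH5",
             "NADH6", "CYTB"),
    length = c(959L, 1554L, 161L, 681L, 1544L, 687L, 783L,
               968L, 1032L, 345L, 296L, 1380L, 1823L, 515L, 1140L),
    model_name = c("GTR", "GTR", "TN93", "HKY", "GTR", "TN93", "GTR",
                   "TN93", "TN93", "HKY", "HKY", "HKY", "TN93", "TN93",
                   "GTR"),
    rate_multiplier = c(1, 0.5, 8, 2, 1, 2, 2,
                        4, 8, 4, 2, 1, 1, 2, 0.5)
  )
}

# concrete model parameters for the synthetic gene classes: A+T-rich
# composition and high transition/transversion rate ratios typical of
# vertebrate mitochondrial DNA
benchmark_gene_model <- function(model_name, gamma_alpha = 2, p_invariant = 0.1) {
  freqs <- c(0.33, 0.27, 0.13, 0.27)
  switch(model_name,
         GTR = model_spec("GTR", freqs = freqs,
                          rates = c(1, 2.5, 1, 0.5, 5, 1),
                          gamma_alpha = gamma_alpha, p_invariant = p_invariant),
         TN93 = model_spec("TN93", freqs = freqs, kappa1 = 2.5, kappa2 = 5,
                           gamma_alpha = gamma_alpha, p_invariant = p_invariant),
         HKY = model_spec("HKY", freqs = freqs, kappa = 4,
                          gamma_alpha = gamma_alpha, p_invariant = p_invariant),
         JC69 = model_spec("JC69", gamma_alpha = gamma_alpha,
                           p_invariant = p_invariant),
         abort(sprintf("unknown benchmark model class: %s", model_name)))
}

#' Simulation configuration
#'
#' Bundles everything [make_benchmark()] needs: taxon count, Yule birth
#' rate, the target root-to-tip depth in expected substitutions per site
#' (at rate multiplier 1), the stretch factor applied to the stem branch
#' of the outgroup clade (emulating a genetically distant outgroup
#' genus), the gene table and the master seed.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param birth_rate Yule speciation rate.
#' @param tree_depth Target root-to-tip path length at multiplier 1
#'   (substitutions/site); the sampled Yule tree is rescaled to this
#'   depth.
#' @param outgroup_stem_multiplier Stretch factor (>= 1) for the stem
#'   branch of the outgroup clade (the smaller side of the root split).
#' @param min_internal_edge Minimum internal branch length (expected
#'   substitutions/site at multiplier 1) the rescaled species tree must
#'   have; draws with a shorter edge are rejected and redrawn, so the
#'   benchmark emulates a fully resolvable radiation.
#' @param genes Gene table as in [default_gene_table()].
#' @param gamma_alpha,p_invariant Shared among-site-rate parameters of
#'   the per-gene models.
#' @param seed Master seed; the whole benchmark is a pure function of
#'   this configuration.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 20, birth_rate = 1, tree_depth = 0.2,
                              outgroup_stem_multiplier = 4,
                              genes = default_gene_table(),
                              gamma_alpha = 2, p_invariant = 0.1,
                              min_internal_edge = 0.003,
                              seed = 1) {
  if (n_taxa < 4L) abort("n_taxa must be >= 4")
  if (tree_depth <= 0) abort("tree_depth must be > 0")
  if (outgroup_stem_multiplier < 1) abort("outgroup_stem_multiplier must be >= 1")
  if (any(genes$length < 1L) || any(genes$rate_multiplier <= 0)) {
    abort("gene lengths must be >= 1 and multipliers > 0")
  }
  if (anyDuplicated(genes$gene)) abort("gene names must be unique")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 tree_depth = tree_depth,
                 outgroup_stem_multiplier = outgroup_stem_multiplier,
                 genes = genes, gamma_alpha = gamma_alpha,
                 p_invariant = p_invariant,
                 min_internal_edge = min_internal_edge,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a ground-truth benchmark data set
#'
#' Samples one Yule species tree, rescales it to the target depth,
#' stretches the stem of the outgroup clade (the smaller side of the
#' root split), simulates every gene of the configuration on that shared
#' tree (rate multipliers only rescale branches), and assembles the
#' concatenated supermatrix with its partition map. Fully determined by
#' the configuration, including its seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `benchmark_truth`: `tree` (the true `phylo`),
#'   `outgroup` (character vector of outgroup taxa), `gene_alignments`
#'   (named list), `alignment` (concatenation), `partition_map`,
#'   `config`.
#' @export
make_benchmark <- function(config = simulation_config()) {
  set.seed(config$seed)
  # draw species trees until every internal edge is resolvable at the
  # configured floor (a congruence benchmark needs a resolvable truth)
  floor_len <- if (is.null(config$min_internal_edge)) 0 else config$min_internal_edge
  repeat {
    tree <- sample_yule_tree(config$n_taxa, config$birth_rate)
    height <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * config$tree_depth / height
    internal <- tree$edge[, 2L] > length(tree$tip.label)
    if (!any(internal) || min(tree$edge.length[internal]) >= floor_len) break
  }
  # outgroup clade = smaller side of the root split; stretch its stem
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  sizes <- vapply(kids, function(v) {
    length(phangorn::Descendants(tree, v, "tips")[[1]])
  }, integer(1))
  og_node <- kids[which.min(sizes)]
  stem <- which(tree$edge[, 1L] == root & tree$edge[, 2L] == og_node)
  tree$edge.length[stem] <- tree$edge.length[stem] * config$outgroup_stem_multiplier
  outgroup <- tree$tip.label[phangorn::Descendants(tree, og_node, "tips")[[1]]]

  gene_alignments <- list()
  genes <- list()
  offset <- 0L
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes[i, ]
    model <- benchmark_gene_model(g$model_name, config$gamma_alpha, config$p_invariant)
    gene_alignments[[g$gene]] <- simulate_gene(
      tree, model, g$length, g$rate_multiplier,
      seed = config$seed + 1000L * i
    )
    genes[[g$gene]] <- list(
      intervals = matrix(c(offset, offset + g$length), 1L, 2L),
      model = model
    )
    offset <- offset + g$length
  }
  concat <- alignment(do.call(cbind, lapply(gene_alignments, unclass)))
  structure(
    list(tree = tree, outgroup = outgroup,
         gene_alignments = gene_alignments,
         alignment = concat,
         partition_map = partition_map(genes, offset),
         config = config),
    class = "benchmark_truth"
  )
}

#' @export
print.benchmark_truth <- function(x, ...) {
  cat(sprintf("<benchmark_truth: %d taxa, %d genes, %d sites; outgroup: %s>\n",
              length(x$tree$tip.label), length(x$gene_alignments),
              ncol(x$alignment), paste(x$outgroup, collapse = ",")))
  invisible(x)
}

#' Write a benchmark data set to plain-text files
#'
#' Per-gene FASTA, concatenated FASTA, partition file, true-tree Newick
#' and a JSON echo of the configuration.
#'
#' @param truth A [make_benchmark()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(truth$gene_alignments)) {
    write_fasta(truth$gene_alignments[[g]], file.path(dir, paste0(g, ".fasta")))
  }
  write_fasta(truth$alignment, file.path(dir, "concatenation.fasta"))
  write_partitions(truth$partition_map, file.path(dir, "partitions.txt"))
  write_tree(truth$tree, file.path(dir, "true_tree.nwk"))
  cfg <- truth$config
  cfg$genes <- as.data.frame(cfg$genes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
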