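as_phydat <- function(aln) {
  phangorn::phyDat(unclass(as_alignment(aln)), type = "DNA")
}

# normalize multiPhylo / list / tree_set input to a plain list of phylo
as_tree_list <- function(trees) {
  if (inherits(trees, "phylosat_treeset")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) abort("empty tree set")
  lapply(trees, function(t) { stopifnot(inherits(t, "phylo")); t })
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a model-based distance matrix. The
#' matrix must be complete: undefined (saturated) entries are refused,
#' naming the offending pairs, because silently imputing them would
#' fabricate topology. Negative estimated branch lengths are clamped to
#' zero with the deficit transferred to the adjacent branch (the usual
#' display fix); additive matrices are reconstructed exactly.
#'
#' @param dm A symmetric distance matrix with taxon dimnames (e.g. from
#'   [distance_matrix()]).
#' @return An unrooted binary `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  D <- unclass(as.matrix(dm))
  if (nrow(D) < 3L) abort("need at least 3 taxa")
  if (anyNA(D)) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    prs <- apply(idx, 1L, function(k) paste(rownames(D)[k[1]], colnames(D)[k[2]], sep = "~"))
    abort(sprintf("distance matrix has undefined entries: %s",
                  paste(prs, collapse = ", ")))
  }
  tr <- ape::nj(D)
  # clamp negative branch lengths, moving the deficit to a sibling branch
  for (pass in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tr$edge[e, 1L]
      sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
      if (length(sibs)) {
        tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fitch parsimony score of a fixed topology
#'
#' Minimum number of state changes needed to explain each site on the
#' given (unrooted) topology, summed over sites, with all changes
#' weighted equally. Gaps and ambiguity codes are treated as the full set
#' of compatible bases.
#'
#' @param tree A `phylo` topology whose leaves appear in the alignment.
#' @param aln An alignment.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  aln <- as_alignment(aln)
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing)) {
    abort(sprintf("leaves missing from alignment: %s", paste(missing, collapse = ", ")))
  }
  pd <- as_phydat(aln[tree$tip.label, , drop = FALSE])
  as.integer(phangorn::fitch(tree, pd, site = "pscore"))
}

#' Maximum parsimony tree search
#'
#' For 9 or fewer taxa the search is exact: every unrooted topology is
#' enumerated and scored. For more taxa a heuristic is used: `n_starts`
#' random-addition starting trees, each improved by SPR rearrangements to
#' a local optimum (the swap set is recorded in the result's metadata).
#' All distinct minimum-score topologies found are returned.
#'
#' @param aln An alignment with at least 4 taxa.
#' @param n_starts Number of random-addition starts (heuristic mode).
#' @param seed Integer seed; start `k` uses `seed + k`.
#' @param exact_limit Largest taxon count for exhaustive enumeration.
#' @return A `phylosat_treeset`: list with `trees` (list of `phylo`),
#'   `score`, `provenance` (`"mp-exact"` or `"mp-heuristic"`), and
#'   `metadata`.
#' @export
mp_search <- function(aln, n_starts = 5, seed = 1, exact_limit = 9) {
  aln <- as_alignment(aln)
  labs <- rownames(aln)
  if (length(labs) < 4L) abort("need at least 4 taxa")
  pd <- as_phydat(aln)
  if (length(labs) <= exact_limit) {
    trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
    scores <- phangorn::fitch(trees, pd)
    best <- min(scores)
    keep <- trees[scores == best]
    out <- lapply(seq_along(keep), function(i) keep[[i]])
    provenance <- "mp-exact"
    meta <- list(n_topologies = length(trees))
  } else {
    results <- lapply(seq_len(n_starts), function(k) {
      set.seed(seed + k)
      start <- phangorn::random.addition(pd)
      opt <- phangorn::optim.parsimony(start, pd, rearrangements = "SPR", trace = 0)
      list(tree = opt, score = phangorn::fitch(opt, pd))
    })
    scores <- vapply(results, `[[`, numeric(1), "score")
    best <- min(scores)
    cands <- lapply(results[scores == best], `[[`, "tree")
    # deduplicate topologies
    out <- list(cands[[1L]])
    if (length(cands) > 1L) for (t in cands[-1L]) {
      if (all(vapply(out, function(u) rf_distance(u, t) > 0, logical(1)))) {
        out <- c(out, list(t))
      }
    }
    provenance <- "mp-heuristic"
    meta <- list(n_starts = n_starts, swap_set = "SPR", seed = seed)
  }
  structure(list(trees = out, score = as.integer(best),
                 provenance = provenance, metadata = meta),
            class = "phylosat_treeset")
}

#' @export
print.phylosat_treeset <- function(x, ...) {
  cat(sprintf("<tree set: %d tree(s), provenance %s%s>\n",
              length(x$trees), x$provenance,
              if (!is.null(x$score)) sprintf(", score %d", x$score) else ""))
  invisible(x)
}

#' Felsenstein pruning log-likelihood
#'
#' Log-likelihood of an alignment on a fixed tree with branch lengths
#' under a reversible nucleotide model, with optional 4-category discrete
#' gamma rates and invariant sites; sites with missing data are
#' marginalized over the compatible states.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param aln An alignment covering the tree's leaves.
#' @param model A [model_spec()] (JC69 / K2P / HKY / TN93 / GTR families).
#' @return The log-likelihood (finite scalar).
#' @export
felsenstein_loglik <- function(tree, aln, model = model_spec("JC69")) {
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  aln <- as_alignment(aln)
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing)) {
    abort(sprintf("leaves missing from alignment: %s", paste(missing, collapse = ", ")))
  }
  pd <- as_phydat(aln[tree$tip.label, , drop = FALSE])
  has_g <- !is.null(model$gamma_alpha)
  fit <- phangorn::pml(tree, pd, bf = as.numeric(model$freqs),
                       Q = model_exchange(model),
                       k = if (has_g) 4L else 1L,
                       shape = if (has_g) model$gamma_alpha else 1,
                       inv = model$p_invariant)
  as.numeric(fit$logLik)
}

# rough transition/transversion rate ratio by counting, for the default
# HKY maximum-likelihood model
estimate_kappa <- function(aln) {
  labs <- rownames(aln)
  prs <- combn(labs, 2L)
  k <- min(ncol(prs), 60L)  # a sample of pairs is plenty
  sv <- vapply(seq_len(k), function(i) {
    cnt <- pair_counts(aln, prs[1L, i], prs[2L, i])
    c(cnt$p1 + cnt$p2, cnt$q)
  }, numeric(2))
  s_bar <- mean(sv[1L, ]); v_bar <- mean(sv[2L, ])
  if (v_bar <= 0) return(4)
  max(2 * s_bar / v_bar, 0.5)
}

# distance surrogate used to seed the ML search
start_distance_model <- function(model) {
  switch(model$name,
         JC69 = model_spec("JC69", gamma_alpha = model$gamma_alpha),
         GTR = ,
         LOGDET = model_spec("LOGDET"),
         TN93 = model_spec("TN93", freqs = model$freqs,
                           gamma_alpha = model$gamma_alpha),
         model_spec("K2P", gamma_alpha = model$gamma_alpha))
}

#' Maximum likelihood tree search
#'
#' Hill-climbing ML: the search starts from the neighbor-joining tree on
#' the model's distance surrogate, then alternates branch-length
#' optimization with nearest-neighbor-interchange sweeps, accepting
#' improvements until no rearrangement helps. By default an HKY model
#' with empirical base frequencies and a counted transition/transversion
#' ratio is used; gamma shape and invariant-site parameters are taken
#' from the model specification (no joint model + topology optimization).
#'
#' @param aln An alignment with at least 4 taxa.
#' @param model A [model_spec()], or `NULL` for the default HKY model
#'   with empirical frequencies.
#' @param seed Integer seed (the search is deterministic given the seed).
#' @return A `phylo` tree with optimized branch lengths; attributes
#'   `logLik` (final log-likelihood), `start_logLik` and `model`.
#' @export
ml_search <- function(aln, model = NULL, seed = 1) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 4L) abort("need at least 4 taxa")
  set.seed(seed)
  optimize_shape <- FALSE
  if (is.null(model)) {
    # default: HKY with empirical frequencies, counted Ti/Tv ratio and a
    # 4-category gamma whose shape is optimized along the branch lengths
    bf <- base_composition(aln)
    model <- model_spec("HKY",
                        freqs = as.numeric(bf[1, c("A", "C", "G", "T")]),
                        kappa = estimate_kappa(aln), gamma_alpha = 1)
    optimize_shape <- TRUE
  }
  dm <- suppressWarnings(distance_matrix(aln, start_distance_model(model)))
  if (anyNA(dm)) {
    # saturated start distances: cap at a large finite value; this only
    # seeds the search, the likelihood drives the final tree
    mx <- max(dm, na.rm = TRUE)
    dm[is.na(dm)] <- 2 * max(mx, 1)
  }
  start <- nj_tree(dm)
  start$edge.length[start$edge.length <= 0] <- 1e-8
  pd <- as_phydat(aln)
  has_g <- !is.null(model$gamma_alpha)
  fit <- phangorn::pml(start, pd, bf = as.numeric(model$freqs),
                       Q = model_exchange(model),
                       k = if (has_g) 4L else 1L,
                       shape = if (has_g) model$gamma_alpha else 1,
                       inv = model$p_invariant)
  opt <- phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                             optGamma = optimize_shape,
                             control = phangorn::pml.control(trace = 0, epsilon = 1e-8))
  tr <- opt$tree
  attr(tr, "logLik") <- as.numeric(opt$logLik)
  attr(tr, "start_logLik") <- as.numeric(fit$logLik)
  attr(tr, "model") <- format_model_token(model)
  tr
}

#' Nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and annotates each internal edge of the
#' point-estimate tree (built on the original data) with the percentage
#' of replicate trees containing that bipartition. Replicates whose
#' builder fails (e.g. undefined distances under saturation) are skipped
#' and counted; more than 10% skips attaches a warning.
#'
#' @param aln An alignment.
#' @param builder A function `alignment -> phylo` (see
#'   [method_builder()]).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @return The point-estimate `phylo` with supports as node labels;
#'   attributes `n_replicates`, `n_skipped`.
#' @export
bootstrap_support <- function(aln, builder, n_replicates = 100, seed = 1) {
  aln <- as_alignment(aln)
  if (n_replicates < 1L) abort("n_replicates must be >= 1")
  point <- builder(aln)
  pkeys <- names(bipartitions(point)$splits)
  counts <- setNames(rep(0L, length(pkeys)), pkeys)
  skipped <- 0L
  L <- ncol(aln)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    idx <- sample.int(L, L, replace = TRUE)
    rep_tree <- tryCatch(builder(aln[, idx]), error = function(e) NULL)
    if (is.null(rep_tree)) { skipped <- skipped + 1L; next }
    keys <- names(bipartitions(rep_tree)$splits)
    hit <- pkeys %in% keys
    counts[hit] <- counts[hit] + 1L
  }
  n_ok <- n_replicates - skipped
  if (n_ok == 0L) abort("all bootstrap replicates failed")
  supports <- 100 * counts / n_ok
  out <- annotate_supports(point, supports)
  attr(out, "n_replicates") <- n_replicates
  attr(out, "n_skipped") <- skipped
  if (skipped > 0.1 * n_replicates) {
    msg <- sprintf("%d of %d bootstrap replicates failed", skipped, n_replicates)
    attr(out, "warning") <- msg
    warn(msg)
  }
  out
}

# write per-split support values onto the node labels of a tree
annotate_supports <- function(tree, supports) {
  nt <- length(tree$tip.label)
  if (nt >= 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  anchor <- sort(tree$tip.label)[1L]
  n_node <- tree$Nnode
  labs <- rep("", n_node)
  for (v in seq.int(nt + 1L, nt + n_node)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1]]]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) <= 1L || length(tips) >= nt - 1L) next
    key <- paste(sort(tips), collapse = "\r")
    if (key %in% names(supports)) {
      labs[v - nt] <- format(round(supports[[key]], 1))
    }
  }
  tree$node.label <- labs
  tree
}

#' Tree builders for the inference methods
#'
#' Returns a closure `alignment -> phylo` for one inference method, as
#' needed by [bootstrap_support()] and the benchmark orchestrator. The
#' MP builder returns the strict consensus of all equally parsimonious
#' topologies found.
#'
#' @param method `"nj"`, `"mp"` or `"ml"`.
#' @param model A [model_spec()] (used by NJ for the distance formula and
#'   by ML for the likelihood model; ignored by MP). `NULL` gives the
#'   method default.
#' @param seed Integer seed forwarded to the stochastic searches.
#' @param mp_starts Random-addition starts for heuristic MP.
#' @return A function of one argument (an alignment) returning a `phylo`.
#' @export
method_builder <- function(method = c("nj", "mp", "ml"), model = NULL,
                           seed = 1, mp_starts = 2) {
  method <- match.arg(method)
  switch(method,
         nj = function(a) {
           m <- if (is.null(model)) default_model() else model
           nj_tree(distance_matrix(a, m))
         },
         mp = function(a) {
           res <- mp_search(a, n_starts = mp_starts, seed = seed)
           if (length(res$trees) == 1L) res$trees[[1L]] else strict_consensus(res)
         },
         ml = function(a) ml_search(a, model = model, seed = seed))
}

consensus_splits <- function(trees) {
  trees <- as_tree_list(trees)
  uni <- sort(trees[[1L]]$tip.label)
  sets <- lapply(trees, function(t) {
    s <- bipartitions(t)
    if (!identical(s$universe, uni)) abort("consensus requires identical leaf sets")
    s
  })
  keys <- unlist(lapply(sets, function(s) names(s$splits)))
  counts <- table(keys)
  members <- list()
  for (s in sets) for (k in names(s$splits)) members[[k]] <- s$splits[[k]]$members
  list(universe = uni, counts = counts, members = members, n = length(trees))
}

#' Consensus trees
#'
#' `majority_consensus()` keeps exactly the bipartitions occurring in
#' more than `cutoff` of the input trees (cutoff in `[0.5, 1]`, so the
#' retained splits are mutually compatible by construction), annotating
#' each with its percentage frequency. `strict_consensus()` keeps only
#' the bipartitions present in every tree, collapsing all conflicts to
#' polytomies.
#'
#' @param trees A list of `phylo` trees (or `multiPhylo`, or a tree set
#'   from [mp_search()]) over a shared leaf set.
#' @param cutoff Fraction in `[0.5, 1]`; a split is kept when its
#'   frequency is strictly greater.
#' @return A `phylo` tree, frequencies as node labels.
#' @export
majority_consensus <- function(trees, cutoff = 0.5) {
  if (cutoff < 0.5 || cutoff > 1) abort("cutoff must be in [0.5, 1]")
  cs <- consensus_splits(trees)
  keep <- names(cs$counts)[as.numeric(cs$counts) / cs$n > cutoff]
  tree_from_splits(cs$universe, cs$members[keep],
                   round(100 * as.numeric(cs$counts[keep]) / cs$n, 1))
}

#' @rdname majority_consensus
#' @export
strict_consensus <- function(trees) {
  cs <- consensus_splits(trees)
  keep <- names(cs$counts)[as.numeric(cs$counts) == cs$n]
  tree_from_splits(cs$universe, cs$members[keep], rep(100, length(keep)))
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick I/O, so that trees, supports (as
#' internal node labels) and branch lengths round-trip through plain
#' text files.
#'
#' @param tree A `phylo` (or list of trees for `write_trees()`).
#' @param path File path.
#' @return `read_tree()` returns a `phylo`; `read_trees()` a list.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) ape::read.tree(path)

#' @rdname write_tree
#' @param trees A list of trees.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(do.call(c, lapply(as_tree_list(trees), identity)), file = path, digits = 6)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_trees <- function(path) {
  out <- ape::read.tree(path)
  if (inherits(out, "phylo")) list(out) else unclass(out)
}
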