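test_that("NJ reconstructs an additive matrix exactly", {
  D <- matrix(c(0, 3, 3, 5,
                3, 0, 4, 6,
                3, 4, 0, 4,
                5, 6, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  # path distances on the output tree equal the input matrix
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(pd, D, tolerance = 1e-12)
  # the AB|CD split is recovered
  expect_true("C\rD" %in% names(bipartitions(tr)$splits))
  # three taxa resolve by the three-point formulas
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  expect_equal(ape::cophenetic.phylo(tr3)[rownames(D3), colnames(D3)], D3,
               tolerance = 1e-12)
  # undefined entries are refused with the offending pair named
  Dna <- D; Dna["A", "D"] <- Dna["D", "A"] <- NA
  expect_error(nj_tree(Dna), "A~D")
})

test_that("negative NJ branch estimates are clamped without going negative", {
  # a non-additive matrix known to produce negative NJ branch estimates
  set.seed(2)
  n <- 8
  D <- matrix(runif(n * n, 0.01, 0.3), n, n)
  D <- (D + t(D)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  raw <- ape::nj(D)
  expect_true(any(raw$edge.length < 0))  # the fixture does exercise the clamp
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Fitch scores match the exhaustive-labeling oracle", {
  aln0 <- alignment(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA"))
  t4 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_score(t4, aln0), 0L)
  one <- alignment(c(t1 = "A", t2 = "A", t3 = "G", t4 = "G"))
  expect_equal(fitch_score(t4, one), 1L)
  for (case in 1:10) {
    aln <- random_alignment(6, 12, seed = 700 + case)
    tr <- random_topology(6, seed = 800 + case)
    expect_equal(fitch_score(tr, aln), oracle_fitch(tr, aln))
  }
  expect_error(fitch_score(ape::read.tree(text = "((t1,t2),(t3,tX));"), one), "tX")
})

test_that("parsimony search finds the supported quartet and is deterministic", {
  # site patterns supporting AB|CD
  aln <- alignment(c(A = "AAAATTTT", B = "AAAATTTC", C = "GGGGTTTT", D = "GGGGTTTC"))
  res <- mp_search(aln)
  expect_equal(res$provenance, "mp-exact")
  expect_equal(length(res$trees), 1L)
  expect_true("C\rD" %in% names(bipartitions(res$trees[[1]])$splits))
  # heuristic mode: same best score from different seeds
  truth <- make_benchmark(simulation_config(n_taxa = 12, seed = 32))
  sub <- truth$alignment[, 1:800]
  s1 <- mp_search(sub, n_starts = 2, seed = 1, exact_limit = 4)
  s2 <- mp_search(sub, n_starts = 2, seed = 99, exact_limit = 4)
  expect_equal(s1$score, s2$score)
  expect_equal(s1$metadata$swap_set, "SPR")
})

test_that("heuristic parsimony equals exhaustive enumeration on small cases", {
  for (r in 1:5) {
    truth <- make_benchmark(simulation_config(n_taxa = 7, seed = 900 + r))
    sub <- truth$alignment[, 1:400]
    exact <- mp_search(sub)
    heur <- mp_search(sub, n_starts = 3, seed = r, exact_limit = 4)
    expect_equal(heur$score, exact$score)
  }
})

test_that("pruning likelihood matches closed forms and the exhaustive oracle", {
  # two identical single-site sequences at distance ~0 under JC
  two <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  alnA <- alignment(c(a = "A", b = "A"))
  expect_equal(felsenstein_loglik(two, alnA, model_spec("JC69")), log(1 / 4),
               tolerance = 1e-5)
  # saturated branch: joint probability approaches 1/16
  far <- ape::read.tree(text = "(a:50,b:50);")
  alnAC <- alignment(c(a = "A", b = "C"))
  expect_equal(felsenstein_loglik(far, alnAC, model_spec("JC69")), log(1 / 16),
               tolerance = 1e-4)
  # exhaustive-state oracle, GTR + gamma, 4 taxa
  for (r in 1:3) {
    aln <- random_alignment(4, 10, seed = 1000 + r)
    tr <- ape::rtree(4, tip.label = paste0("t", 1:4))
    tr <- ape::unroot(tr)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
    rates <- c(1, 4, 1, 1, 8, 1)
    freqs <- c(0.35, 0.15, 0.12, 0.38)
    model <- model_spec("GTR", freqs = freqs, rates = rates, gamma_alpha = 0.7)
    expect_equal(felsenstein_loglik(tr, aln, model),
                 oracle_loglik(tr, aln, rates, freqs, gamma_alpha = 0.7),
                 tolerance = 1e-9)
  }
})

test_that("ML search improves on its starting tree and is seed-reproducible", {
  tr <- sample_yule_tree(6, 1, seed = 41)
  tr$edge.length <- tr$edge.length * 0.4 / max(ape::node.depth.edgelength(tr))
  aln <- simulate_gene(tr, model_spec("HKY", freqs = c(0.3, 0.25, 0.2, 0.25),
                                      kappa = 6), 3000, seed = 42)
  fit1 <- ml_search(aln, seed = 1)
  expect_gte(attr(fit1, "logLik"), attr(fit1, "start_logLik"))
  fit2 <- ml_search(aln, seed = 1)
  expect_equal(ape::write.tree(fit1), ape::write.tree(fit2))
  expect_equal(rf_distance(fit1, tr), 0)
})

test_that("bootstrap supports count bipartition recovery", {
  tr <- sample_yule_tree(6, 1, seed = 51)
  tr$edge.length <- tr$edge.length * 0.3 / max(ape::node.depth.edgelength(tr))
  aln <- simulate_gene(tr, model_spec("K2P", kappa = 4), 2000, seed = 52)
  builder <- method_builder("nj", model_spec("K2P"))
  # a single replicate gives all-or-nothing supports
  b1 <- bootstrap_support(aln, builder, n_replicates = 1, seed = 1)
  sups <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sups[!is.na(sups)] %in% c(0, 100)))
  # same seed, same supports
  b2 <- bootstrap_support(aln, builder, n_replicates = 25, seed = 7)
  b3 <- bootstrap_support(aln, builder, n_replicates = 25, seed = 7)
  expect_equal(b2$node.label, b3$node.label)
  sup2 <- suppressWarnings(as.numeric(b2$node.label))
  expect_true(all(sup2[!is.na(sup2)] >= 0 & sup2[!is.na(sup2)] <= 100))
})

test_that("a strongly supported clade reaches near-certain support", {
  # one clade supported by many uncontradicted sites
  block <- function(x, n) paste(rep(x, n), collapse = "")
  aln <- alignment(c(
    a = paste0(block("G", 150), block("A", 50)),
    b = paste0(block("G", 150), block("A", 50)),
    c = paste0(block("G", 150), block("T", 50)),
    d = paste0(block("G", 150), block("T", 50)),
    e = paste0(block("G", 150), block("T", 50))
  ))
  bt <- bootstrap_support(aln, method_builder("nj", model_spec("JC69")),
                          n_replicates = 200, seed = 3)
  key <- paste(sort(c("c", "d", "e")), collapse = "\r")
  ss <- bipartitions(bt)
  expect_true(key %in% names(ss$splits))
  expect_gte(ss$splits[[key]]$support, 99)
})

test_that("consensus trees obey their definitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  # identical trees: consensus is that tree with full support
  mc <- majority_consensus(list(t1, t1, t1))
  expect_equal(rf_distance(mc, t1), 0)
  expect_true(all(tidy(bipartitions(mc))$support == 100))
  # no shared non-trivial bipartition: star tree
  s1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  s2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  s3 <- ape::read.tree(text = "((a,d),(b,c),e);")
  expect_equal(length(bipartitions(majority_consensus(list(s1, s2, s3)))$splits), 0L)
  # a 2-of-3 split appears at 66.7%
  u1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  u2 <- ape::read.tree(text = "((a,b),d,(c,e));")
  u3 <- ape::read.tree(text = "((a,c),b,(d,e));")
  mc2 <- majority_consensus(list(u1, u2, u3))
  tt <- tidy(bipartitions(mc2))
  expect_true(any(abs(tt$support - 66.7) < 0.1))
  # strict consensus collapses the conflicting edge only
  st <- strict_consensus(list(u1, u3))
  expect_equal(length(bipartitions(st)$splits), 1L)  # d,e retained
  # strict splits are a subset of majority splits
  expect_true(all(names(bipartitions(st)$splits) %in%
                  names(bipartitions(majority_consensus(list(u1, u3)))$splits)))
  # agreement with ape on random tree sets
  set.seed(61)
  trees <- lapply(1:5, function(i) {
    t <- ape::rtree(7, tip.label = paste0("t", 1:7)); t$edge.length <- NULL; ape::unroot(t)
  })
  mine <- strict_consensus(trees)
  ref <- ape::consensus(trees, p = 1)
  expect_equal(rf_distance(mine, ref), 0)
  mine50 <- majority_consensus(trees, 0.5)
  ref50 <- ape::consensus(trees, p = 0.5)
  expect_equal(rf_distance(mine50, ref50), 0)
})

test_that("scores are invariant to leaf reordering and site permutation", {
  aln <- random_alignment(6, 40, seed = 71)
  tr <- random_topology(6, seed = 72)
  base_fitch <- fitch_score(tr, aln)
  perm_sites <- alignment(unclass(aln)[, sample(40)])
  perm_taxa <- alignment(unclass(aln)[sample(6), ])
  expect_equal(fitch_score(tr, perm_sites), base_fitch)
  expect_equal(fitch_score(tr, perm_taxa), base_fitch)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  m <- model_spec("K2P", kappa = 3)
  expect_equal(felsenstein_loglik(tr, perm_sites, m),
               felsenstein_loglik(tr, aln, m), tolerance = 1e-9)
})

test_that("newick round trips preserve topology, lengths and supports", {
  tr <- sample_yule_tree(8, 1, seed = 81)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, path)
  back <- read_tree(path)
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-5)
  trees <- list(tr, sample_yule_tree(8, 1, seed = 82))
  write_trees(trees, path)
  expect_equal(length(read_trees(path)), 2L)
})
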