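test_that("pair counts apply pairwise deletion and partition substitutions", {
  aln <- alignment(c(x = "ACGT", y = "ACGT"))
  pc <- pair_counts(aln, "x", "y")
  expect_equal(pc$n_compared, 4L)
  expect_equal(c(pc$p1, pc$p2, pc$q), c(0, 0, 0))
  expect_equal(pc$identity, 1)

  pc2 <- pair_counts(alignment(c(x = "ACGT", y = "GCGT")), "x", "y")
  expect_equal(pc2$p1, 0.25)  # A<->G purine transition
  expect_equal(pc2$p2, 0)
  expect_equal(pc2$q, 0)

  # only sites where BOTH taxa have an unambiguous base are compared
  pc3 <- pair_counts(alignment(c(x = "ANGT", y = "G-GT")), "x", "y")
  expect_equal(pc3$n_compared, 3L)
  expect_equal(pc3$p1, 1 / 3)

  expect_error(pair_counts(alignment(c(x = "NN", y = "AC")), "x", "y"), "no unambiguous")
  # invariant: proportions always partition unity
  for (s in 1:10) {
    a <- random_alignment(2, 30, seed = 100 + s)
    p <- pair_counts(a, "t1", "t2")
    expect_equal(p$p1 + p$p2 + p$q + p$identity, 1, tolerance = 1e-12)
  }
})

test_that("closed-form distances match their formulas and domain limits", {
  expect_equal(jc69_distance(0), 0)
  expect_equal(jc69_distance(0.3), 0.3831, tolerance = 1e-4)
  expect_true(is.na(jc69_distance(0.75)))

  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05), 0.1702, tolerance = 1e-3)
  expect_true(is.na(k2p_distance(0.5, 0)))

  # TN93 reduces to K2P at equal frequencies and p1 = p2
  cnt <- list(p1 = 0.05, p2 = 0.05, q = 0.1)
  expect_equal(tn93_distance(cnt, freqs = rep(0.25, 4)),
               k2p_distance(0.1, 0.1), tolerance = 1e-9)
  expect_equal(tn93_distance(list(p1 = 0, p2 = 0, q = 0), freqs = rep(0.25, 4)), 0)
  expect_error(tn93_distance(cnt, freqs = c(0.5, 0.5, 0, 0)), "positive")

  expect_equal(logdet_distance(diag(4) / 4), 0)
  # identical sequences of skewed composition still give distance zero
  expect_equal(logdet_distance(diag(c(0.4, 0.3, 0.2, 0.1))), 0, tolerance = 1e-12)
  # degenerate (rank-deficient) divergence matrix is undefined
  F <- matrix(0, 4, 4); F[1, 1] <- 0.5; F[1, 2] <- 0.5
  expect_true(is.na(logdet_distance(F)))
})

test_that("log-det on an observed pattern table matches direct determinant evaluation", {
  pc <- pair_counts(alignment(c(x = "ACGT", y = "GCGT")), "x", "y")
  F <- pc$divergence_matrix
  manual <- -0.25 * (log(det(F)) - 0.5 * sum(log(rowSums(F) * colSums(F))))
  expect_equal(logdet_distance(F), manual, tolerance = 1e-12)
})

test_that("gamma and invariant-site corrections behave as transforms of the log terms", {
  # alpha -> infinity recovers the uncorrected distance
  expect_equal(k2p_distance(0.1, 0.05, gamma_alpha = 1e8),
               k2p_distance(0.1, 0.05), tolerance = 1e-6)
  # gamma-K2P closed form evaluated independently
  a <- 0.5
  expected <- 0.5 * a * ((1 - 2 * 0.1 - 0.05)^(-1 / a) - 1) +
    0.25 * a * ((1 - 2 * 0.05)^(-1 / a) - 1)
  expect_equal(k2p_distance(0.1, 0.05, gamma_alpha = a), expected, tolerance = 1e-12)
  # p_invariant = 0 is the identity transform
  expect_equal(jc69_distance(0.2, p_invariant = 0), jc69_distance(0.2))
  # rescaling by 1/(1 - p_inv) before the formula
  expect_equal(jc69_distance(0.2, p_invariant = 0.5), jc69_distance(0.4))
})

test_that("distances agree with ape's reference implementations", {
  set.seed(42)
  tr <- sample_yule_tree(6, 1)
  tr$edge.length <- tr$edge.length * 0.3
  aln <- simulate_gene(tr, model_spec("HKY", freqs = c(0.3, 0.25, 0.2, 0.25), kappa = 6), 2000)
  bin <- ape::as.DNAbin(unclass(aln))
  for (spec in list(list(m = model_spec("JC69"), ape = "JC69"),
                    list(m = model_spec("K2P"), ape = "K80"))) {
    mine <- unclass(distance_matrix(aln, spec$m))
    ref <- as.matrix(ape::dist.dna(bin, model = spec$ape, pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # TN93 with alignment-wide frequencies matches ape's TN93
  labs <- taxa(aln)
  fr <- as.numeric(base_composition(aln)[1, c("A", "C", "G", "T")])
  mine <- outer(seq_along(labs), seq_along(labs), Vectorize(function(i, j) {
    if (i == j) return(0)
    tn93_distance(pair_counts(aln, labs[i], labs[j]), freqs = fr)
  }))
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  expect_equal(unname(mine), unname(ref[labs, labs]), tolerance = 1e-6)
})

test_that("distance matrices flag saturation instead of silently imputing", {
  # deliberately randomized rows push (p, q) outside the K2P log domain
  set.seed(9)
  m <- matrix(sample(c("A", "C", "G", "T"), 4 * 200, replace = TRUE), 4)
  rownames(m) <- paste0("t", 1:4)
  dm <- suppressWarnings(distance_matrix(alignment(m), model_spec("K2P")))
  expect_gte(attr(dm, "n_undefined"), 1)
  expect_error(nj_tree(dm), "undefined")

  # identical taxa give the zero matrix
  dm0 <- distance_matrix(alignment(c(a = "ACGTACGT", b = "ACGTACGT")), model_spec("JC69"))
  expect_equal(unclass(dm0), matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
})

test_that("distances increase with divergence and are statistically consistent", {
  # monotone in p within the domain
  ps <- seq(0, 0.6, by = 0.05)
  ds <- vapply(ps, jc69_distance, numeric(1))
  expect_true(all(diff(ds) > 0))
  # simulated two-taxon JC: estimated distance near the true path length
  two <- ape::read.tree(text = "(a:0.1,b:0.1);")
  sim <- simulate_gene(two, model_spec("JC69"), 10000, seed = 77)
  pc <- pair_counts(sim, "a", "b")
  est <- jc69_distance(pc$p1 + pc$p2 + pc$q)
  expect_lt(abs(est - 0.2) / 0.2, 0.10)
})

test_that("PHYLIP distance matrices round-trip including NA entries", {
  dm <- matrix(c(0, 0.1, NA, 0.1, 0, 0.3, NA, 0.3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(dm, path)
  back <- read_phylip_dist(path)
  expect_equal(back, dm, tolerance = 1e-8)
})
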