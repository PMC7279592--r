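# Independent brute-force oracles used by the unit and acceptance tests.
# They share no code with the package's computation paths.

# matrix exponential by scaling and squaring of the truncated series
mat_exp <- function(M) {
  k <- 20L
  A <- M / 2^k
  S <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:12) {
    term <- term %*% A / i
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# GTR rate matrix built from first principles (rows/cols A,C,G,T),
# normalized to one expected substitution per unit time
oracle_Q <- function(rates, freqs) {
  b <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(freqs * -diag(Q))
}

# exhaustive-labeling Fitch oracle: minimum changes over all assignments
# of states to internal nodes, summed over sites
oracle_fitch <- function(tree, aln) {
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  nt <- nrow(m)
  n_int <- tree$Nnode
  edges <- tree$edge
  states <- c("A", "C", "G", "T")
  combos <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0L
  for (site in seq_len(ncol(m))) {
    tip_states <- match(m[, site], states)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      lab <- c(tip_states, combos[r, ])
      changes <- sum(lab[edges[, 1]] != lab[edges[, 2]])
      if (changes < best) best <- changes
    }
    total <- total + best
  }
  total
}

# exhaustive-state pruning oracle: likelihood summed explicitly over all
# internal-node state combinations and gamma categories
oracle_loglik <- function(tree, aln, rates, freqs, gamma_alpha = NULL, k = 4L) {
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  states <- c("A", "C", "G", "T")
  Q <- oracle_Q(rates, freqs)
  cat_rates <- if (is.null(gamma_alpha)) 1 else
    as.numeric(phangorn::discrete.gamma(gamma_alpha, k))
  nt <- nrow(m)
  n_int <- tree$Nnode
  edges <- tree$edge
  elen <- tree$edge.length
  combos <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  ll <- 0
  for (site in seq_len(ncol(m))) {
    tip_states <- match(m[, site], states)
    lik <- 0
    for (r in cat_rates) {
      P <- lapply(elen, function(t) mat_exp(Q * t * r))
      lik_r <- 0
      for (row in seq_len(nrow(combos))) {
        lab <- c(tip_states, combos[row, ])
        pr <- freqs[lab[nt + 1L]]  # root = first internal node
        for (e in seq_along(elen)) {
          pr <- pr * P[[e]][lab[edges[e, 1]], lab[edges[e, 2]]]
        }
        lik_r <- lik_r + pr
      }
      lik <- lik + lik_r / length(cat_rates)
    }
    ll <- ll + log(lik)
  }
  unname(ll)
}

# random pure-ACGT alignment for oracle comparisons
random_alignment <- function(n_taxa, n_sites, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE),
              nrow = n_taxa)
  rownames(m) <- paste0("t", seq_len(n_taxa))
  alignment(m)
}

# random unrooted binary topology
random_topology <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- NULL
  ape::unroot(tr)
}
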