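#' Pairwise site-pattern counts
#'
#' Counts, for one pair of taxa, the proportions of purine transitions
#' (A<->G, `p1`), pyrimidine transitions (C<->T, `p2`), transversions
#' (`q`) and identical sites, over the sites where both sequences carry an
#' unambiguous base (pairwise deletion of gaps/ambiguities). Also returns
#' the 4x4 joint frequency (divergence) matrix used by the log-det
#' distance.
#'
#' @param aln An alignment.
#' @param taxon_i,taxon_j Taxon labels.
#' @return A list of class `pair_counts`: `n_compared`, `p1`, `p2`, `q`,
#'   `identity`, `divergence_matrix` (rows = `taxon_i` state, columns =
#'   `taxon_j` state), `freqs` (mean base frequencies of the two
#'   sequences).
#' @export
pair_counts <- function(aln, taxon_i, taxon_j) {
  aln <- as_alignment(aln)
  for (t in c(taxon_i, taxon_j)) {
    if (!t %in% rownames(aln)) abort(sprintf("unknown taxon: '%s'", t))
  }
  x <- unclass(aln)[taxon_i, ]
  y <- unclass(aln)[taxon_j, ]
  xi <- match(x, .bases)
  yi <- match(y, .bases)
  ok <- !is.na(xi) & !is.na(yi)
  n <- sum(ok)
  if (n == 0L) {
    abort(sprintf("taxa '%s' and '%s' share no unambiguous sites", taxon_i, taxon_j))
  }
  xi <- xi[ok]; yi <- yi[ok]
  F <- matrix(tabulate((xi - 1L) * 4L + yi, nbins = 16L), 4, 4, byrow = TRUE,
              dimnames = list(.bases, .bases)) / n
  p1 <- F["A", "G"] + F["G", "A"]
  p2 <- F["C", "T"] + F["T", "C"]
  id <- sum(diag(F))
  q <- max(0, 1 - p1 - p2 - id)  # guard against cancellation at q = 0
  structure(
    list(n_compared = n, p1 = p1, p2 = p2, q = q, identity = id,
         divergence_matrix = F,
         freqs = (rowSums(F) + colSums(F)) / 2),
    class = "pair_counts"
  )
}

# -ln(x) term, optionally gamma-distorted: alpha * (x^(-1/alpha) - 1)
ln_term <- function(x, gamma_alpha = NULL) {
  out <- ifelse(x > 0,
                if (is.null(gamma_alpha)) -log(x)
                else gamma_alpha * (x^(-1 / gamma_alpha) - 1),
                NA_real_)
  out
}

# invariant-site correction: observed proportions rescaled to the
# variable fraction of sites
rescale_pinv <- function(p, p_invariant) {
  if (p_invariant > 0) p / (1 - p_invariant) else p
}

#' Closed-form evolutionary distances
#'
#' `jc69_distance()`, `k2p_distance()`, `tn93_distance()` and
#' `logdet_distance()` implement the standard closed-form estimators.
#' Outside the log domain (substitution saturation) the value is
#' `NA_real_`: undefined is a value state, not an error, and downstream
#' consumers must handle it explicitly.
#'
#' Rate heterogeneity: with `gamma_alpha` each `-log(x)` term is replaced
#' by `alpha * (x^(-1/alpha) - 1)` (the gamma-rates distance transform);
#' with `p_invariant > 0` the observed proportions are first rescaled by
#' `1/(1 - p_invariant)`. These corrections apply to JC69/K2P/TN93 only.
#'
#' @param p_different Proportion of differing sites.
#' @param gamma_alpha Optional positive gamma shape.
#' @param p_invariant Proportion of invariant sites in `[0, 1)`.
#' @return A non-negative distance, or `NA_real_` when undefined.
#' @examples
#' jc69_distance(0.3)
#' k2p_distance(0.1, 0.05)
#' @export
jc69_distance <- function(p_different, gamma_alpha = NULL, p_invariant = 0) {
  if (p_different < 0 || p_different > 1) abort("p_different must be in [0,1]")
  p <- rescale_pinv(p_different, p_invariant)
  if (p > 1) return(NA_real_)  # invariant-sites correction out of domain
  d <- 0.75 * ln_term(1 - 4 * p / 3, gamma_alpha)
  unname(d)
}

#' @rdname jc69_distance
#' @param p Proportion of transition sites.
#' @param q Proportion of transversion sites.
#' @export
k2p_distance <- function(p, q, gamma_alpha = NULL, p_invariant = 0) {
  if (p < 0 || q < 0 || p + q > 1 + 1e-12) abort("need p, q >= 0 and p + q <= 1")
  p <- rescale_pinv(p, p_invariant)
  q <- rescale_pinv(q, p_invariant)
  if (p + q > 1) return(NA_real_)  # invariant-sites correction out of domain
  d <- 0.5 * ln_term(1 - 2 * p - q, gamma_alpha) +
    0.25 * ln_term(1 - 2 * q, gamma_alpha)
  unname(d)
}

#' @rdname jc69_distance
#' @param counts A [pair_counts()] object (or a list with `p1`, `p2`, `q`).
#' @param freqs Base frequencies (A, C, G, T) to use; defaults to the mean
#'   composition of the pair, the standard practice robust to
#'   compositional drift.
#' @export
tn93_distance <- function(counts, freqs = counts$freqs,
                          gamma_alpha = NULL, p_invariant = 0) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6) {
    abort("freqs must be 4 positive numbers summing to 1")
  }
  names(freqs) <- .bases
  p1 <- rescale_pinv(counts$p1, p_invariant)
  p2 <- rescale_pinv(counts$p2, p_invariant)
  q <- rescale_pinv(counts$q, p_invariant)
  gR <- freqs["A"] + freqs["G"]
  gY <- freqs["C"] + freqs["T"]
  k1 <- 2 * freqs["A"] * freqs["G"] / gR
  k2 <- 2 * freqs["C"] * freqs["T"] / gY
  k3 <- 2 * (gR * gY - freqs["A"] * freqs["G"] * gY / gR -
               freqs["C"] * freqs["T"] * gR / gY)
  d <- k1 * ln_term(1 - p1 / k1 - q / (2 * gR), gamma_alpha) +
    k2 * ln_term(1 - p2 / k2 - q / (2 * gY), gamma_alpha) +
    k3 * ln_term(1 - q / (2 * gR * gY), gamma_alpha)
  unname(d)
}

#' @rdname jc69_distance
#' @param divergence_matrix 4x4 joint frequency matrix (entries >= 0,
#'   summing to 1), as produced by [pair_counts()].
#' @export
logdet_distance <- function(divergence_matrix) {
  F <- unname(as.matrix(divergence_matrix))
  if (any(F < 0) || abs(sum(F) - 1) > 1e-6) {
    abort("divergence_matrix must be non-negative and sum to 1")
  }
  f <- rowSums(F)
  g <- colSums(F)
  detF <- det(F)
  if (detF <= 0 || any(f <= 0) || any(g <= 0)) return(NA_real_)
  # paralinear distance: zero for diagonal F with matching marginals
  -0.25 * (log(detF) - 0.5 * sum(log(f * g)))
}

# model-dispatched distance for one pair
pair_distance <- function(counts, model) {
  switch(model$name,
         JC69 = jc69_distance(counts$p1 + counts$p2 + counts$q,
                              model$gamma_alpha, model$p_invariant),
         K2P = ,
         HKY = k2p_distance(counts$p1 + counts$p2, counts$q,
                            model$gamma_alpha, model$p_invariant),
         TN93 = tn93_distance(counts, gamma_alpha = model$gamma_alpha,
                              p_invariant = model$p_invariant),
         GTR = ,
         LOGDET = logdet_distance(counts$divergence_matrix))
}

#' Model-based distance matrix
#'
#' Computes all pairwise distances of an alignment under a model
#' specification. K2P/HKY pairs use the Kimura two-parameter form, TN93
#' pairs the Tamura-Nei form with pair-averaged frequencies, and
#' GTR-class pairs the log-det distance. Undefined (saturated) entries
#' are `NA` and flagged; when more than 25% of pairs are undefined a
#' saturation-overflow warning is attached to the result.
#'
#' @param aln An alignment with at least two taxa.
#' @param model A [model_spec()].
#' @return A symmetric numeric matrix with zero diagonal, class
#'   `phylosat_dist`, with attributes `model`, `n_undefined` and
#'   `warning` (character, possibly empty).
#' @export
distance_matrix <- function(aln, model = default_model()) {
  aln <- as_alignment(aln)
  labs <- rownames(aln)
  nt <- length(labs)
  if (nt < 2L) abort("need at least two taxa")
  D <- matrix(0, nt, nt, dimnames = list(labs, labs))
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      cnt <- pair_counts(aln, labs[i], labs[j])
      d <- pair_distance(cnt, model)
      if (!is.na(d) && d < 0) d <- 0  # tiny negatives from sampling noise
      D[i, j] <- D[j, i] <- d
    }
  }
  n_undef <- sum(is.na(D[upper.tri(D)]))
  warn_msg <- character(0)
  if (n_undef > 0.25 * choose(nt, 2)) {
    warn_msg <- sprintf("saturation overflow: %d of %d pairwise distances undefined",
                        n_undef, choose(nt, 2))
    warn(warn_msg)
  }
  structure(D, class = c("phylosat_dist", "matrix", "array"),
            model = format_model_token(model),
            n_undefined = n_undef, warning = warn_msg)
}

#' Write / read a distance matrix in PHYLIP square format
#'
#' Undefined entries are serialized as `NA`.
#'
#' @param dm A distance matrix (as from [distance_matrix()]).
#' @param path File path.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_phylip_dist <- function(dm, path) {
  labs <- rownames(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-10s", labs[i]),
                       ifelse(is.na(dm[i, ]), "NA", sprintf("%.8f", dm[i, ]))),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  rows <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[[`, character(1), 1L)
  D <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])), numeric(n)))
  dimnames(D) <- list(labs, labs)
  D
}
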