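#' Substitution model specifications
#'
#' A `model_spec` names a nucleotide substitution model and carries the
#' parameters the pipeline needs for distances, likelihood and
#' simulation. Recognised families:
#'
#' * `JC69` — equal rates, equal frequencies.
#' * `K2P` — one transition/transversion ratio (`kappa`), equal
#'   frequencies.
#' * `HKY` — `kappa` plus unequal base frequencies.
#' * `TN93` — separate purine (`kappa1`, A<->G) and pyrimidine (`kappa2`,
#'   C<->T) transition ratios plus frequencies.
#' * `GTR` — six exchangeability rates (`rates`, order AC, AG, AT, CG,
#'   CT, GT) plus frequencies. Pairwise distances for GTR-class genes use
#'   the log-det (paralinear) distance, the standard closed-form
#'   surrogate, since GTR has no closed-form pairwise distance.
#' * `LOGDET` — log-det distance directly.
#'
#' Optional among-site rate heterogeneity: `gamma_alpha` (shape of a
#' discrete gamma with 4 categories; smaller = more heterogeneous) and
#' `p_invariant` (proportion of invariant sites in `[0, 1)`). Gamma and
#' invariant-site corrections are applied to JC69/K2P/HKY/TN93 distances;
#' the log-det distance is used uncorrected.
#'
#' @param name Model family name (see above).
#' @param freqs Base frequencies (A, C, G, T); must be positive and sum
#'   to 1. Ignored by JC69/K2P.
#' @param kappa Transition/transversion rate ratio for K2P/HKY.
#' @param kappa1,kappa2 Purine / pyrimidine transition ratios for TN93.
#' @param rates Six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param gamma_alpha Positive gamma shape, or `NULL` for rate homogeneity.
#' @param p_invariant Proportion of invariant sites in `[0, 1)`.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("TN93", freqs = c(0.33, 0.27, 0.13, 0.27),
#'            kappa1 = 8, kappa2 = 16, gamma_alpha = 0.5, p_invariant = 0.3)
#' @export
model_spec <- function(name = c("JC69", "K2P", "HKY", "TN93", "GTR", "LOGDET"),
                       freqs = c(0.25, 0.25, 0.25, 0.25),
                       kappa = 2, kappa1 = kappa, kappa2 = kappa,
                       rates = rep(1, 6),
                       gamma_alpha = NULL, p_invariant = 0) {
  name <- match.arg(name)
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8) {
    abort("freqs must be 4 positive numbers summing to 1")
  }
  if (name %in% c("JC69", "K2P")) freqs <- rep(0.25, 4)
  if (!is.null(gamma_alpha) && gamma_alpha <= 0) abort("gamma_alpha must be > 0")
  if (p_invariant < 0 || p_invariant >= 1) abort("p_invariant must be in [0, 1)")
  if (length(rates) != 6L || any(rates <= 0)) abort("rates must be 6 positive numbers")
  structure(
    list(name = name, freqs = setNames(freqs, c("A", "C", "G", "T")),
         kappa = kappa, kappa1 = kappa1, kappa2 = kappa2,
         rates = as.numeric(rates),
         gamma_alpha = gamma_alpha, p_invariant = p_invariant),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s%s%s>\n", x$name,
              if (!is.null(x$gamma_alpha)) sprintf("+G(%.3g)", x$gamma_alpha) else "",
              if (x$p_invariant > 0) sprintf("+I(%.3g)", x$p_invariant) else ""))
  invisible(x)
}

# "TN93+G+I" etc. from a partition file; parameters take package defaults
# (alpha 0.5 when +G, no invariant correction unless +I: then 0.3)
parse_model_token <- function(tok) {
  parts <- strsplit(toupper(trimws(tok)), "+", fixed = TRUE)[[1]]
  base <- parts[1L]
  base <- switch(base, K80 = "K2P", GTR = "GTR", HKY = "HKY", HKY85 = "HKY",
                 TN93 = "TN93", TRN = "TN93", JC = "JC69", JC69 = "JC69",
                 K2P = "K2P", LOGDET = "LOGDET",
                 abort(sprintf("unrecognised model name: '%s'", parts[1L])))
  has_g <- any(parts[-1L] %in% c("G", "G4"))
  has_i <- any(parts[-1L] %in% c("I", "T"))  # "+T" occurs in published tables as a misprint of "+I"
  model_spec(base,
             gamma_alpha = if (has_g) 0.5 else NULL,
             p_invariant = if (has_i) 0.3 else 0)
}

format_model_token <- function(m) {
  paste0(m$name,
         if (!is.null(m$gamma_alpha)) "+G" else "",
         if (m$p_invariant > 0) "+I" else "")
}

# default model for genes without a token: GTR-class with gamma
default_model <- function() model_spec("GTR", gamma_alpha = 0.5)

# --- rate matrices -----------------------------------------------------

# GTR exchangeabilities implied by each family (order AC, AG, AT, CG, CT, GT)
model_exchange <- function(m) {
  switch(m$name,
         JC69 = rep(1, 6),
         K2P = c(1, m$kappa, 1, 1, m$kappa, 1),
         HKY = c(1, m$kappa, 1, 1, m$kappa, 1),
         TN93 = c(1, m$kappa1, 1, 1, m$kappa2, 1),
         GTR = m$rates,
         LOGDET = rep(1, 6))
}

# reversible rate matrix Q with rows/cols A,C,G,T, scaled to one expected
# substitution per unit time at stationarity
rate_matrix <- function(m) {
  r <- model_exchange(m)
  pi <- m$freqs
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  Q["A", "C"] <- r[1] * pi["C"]; Q["C", "A"] <- r[1] * pi["A"]
  Q["A", "G"] <- r[2] * pi["G"]; Q["G", "A"] <- r[2] * pi["A"]
  Q["A", "T"] <- r[3] * pi["T"]; Q["T", "A"] <- r[3] * pi["A"]
  Q["C", "G"] <- r[4] * pi["G"]; Q["G", "C"] <- r[4] * pi["C"]
  Q["C", "T"] <- r[5] * pi["T"]; Q["T", "C"] <- r[5] * pi["C"]
  Q["G", "T"] <- r[6] * pi["T"]; Q["T", "G"] <- r[6] * pi["G"]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# eigendecomposition of the pi-symmetrised Q; exact P(t) for any t
rate_matrix_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values,
       left = diag(1 / s) %*% e$vectors,
       right = t(e$vectors) %*% diag(s))
}

transition_probs <- function(eig, t) {
  P <- eig$left %*% diag(exp(eig$values * t), 4, 4) %*% eig$right
  P[P < 0] <- 0
  P / rowSums(P)
}

# mean-one rates of the k-category discrete gamma (equal-probability
# categories, category means), via phangorn
gamma_category_rates <- function(alpha, k = 4L) {
  as.numeric(phangorn::discrete.gamma(alpha, k))
}
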