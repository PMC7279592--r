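---
title: "Ranking mitochondrial genes by phylogenetic informativeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking mitochondrial genes by phylogenetic informativeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosat)
```

## The problem

Complete mitochondrial genomes resolve species-level phylogenies well,
but most studies sequence only one or two mitochondrial markers. Which
genes, alone or in combination, come closest to the whole-mitogenome
topology? And can a gene's *substitution saturation* — the erosion of
signal by multiple hits at the same site — predict how far its tree will
deviate?

`phylosat` implements a complete, testable pipeline for this question:

1. **Saturation profiling.** For every taxon pair of a gene alignment we
   record the observed proportion of transitions (`s`) and transversions
   (`v`) over the compared sites, alongside a model-based distance. The
   gene's *saturation index* is the Pearson correlation of `s` and `v`
   across pairs. At low divergence both proportions grow nearly linearly
   with path length, so the correlation is close to 1. Transitions
   accumulate much faster (mitochondrial transition/transversion rate
   ratios are large) and hit their ceiling first; once they plateau
   while transversions keep growing, the correlation drops. A *low*
   index therefore means a *saturated* gene.
2. **Tree inference.** Neighbor joining on model-based distances,
   maximum parsimony (equal weights, Fitch criterion) and maximum
   likelihood, each with nonparametric bootstrap supports, plus strict
   and majority-rule consensus trees.
3. **Node congruence.** Every non-trivial bipartition of the reference
   (whole-matrix) tree is classified against a gene's tree as
   *coinciding*, *conflicting*, or *unresolved*, after collapsing edges
   with bootstrap support below a cutoff (default 51 on the 0–100 scale)
   into polytomies. The per-gene `deviation` is the count of
   conflicting plus unresolved reference nodes.
4. **Pruning experiment.** Drop the *k* most saturated genes (default
   4) and the designated distant outgroup taxa, rebuild the per-method
   trees, and ask whether the method ensemble became fully congruent
   (all pairwise Robinson–Foulds distances zero).
5. **Ground-truth simulation.** A Yule species tree with per-gene
   GTR/TN93/HKY+Γ+I models and graded rate multipliers generates
   benchmarks on which every step above can be validated against a
   known answer.

## The saturation index, precisely

For a gene alignment and taxon set \(T\), let \(s_{ij}\) and
\(v_{ij}\) be the proportions of transition- and transversion-type
differences between taxa \(i\) and \(j\), computed over the sites where
both sequences carry an unambiguous base (pairwise deletion). The index
is

\[ r = \mathrm{cor}\big( \{s_{ij}\}, \{v_{ij}\} \big), \qquad (i<j), \]

the ordinary Pearson product–moment correlation over the
\(|T|(|T|-1)/2\) pairs. Two deliberate choices:

* **Proportions, not rates.** The quantities plotted in classic
  saturation diagnostics are observed proportions against distance;
  correlating them is the only self-consistent reading of a
  "transition–transversion correlation", and it is what the per-gene
  profile exports (`tidy()` on a `saturation_profile` gives one row per
  pair with `d`, `s`, `v`).
* **Saturated pairs stay in.** A pair whose model distance overflows
  the log domain is exactly a saturated pair; the index needs only
  `(s, v)`, and removing such pairs would bias the index upward. They
  are excluded only from distance-dependent output.

The index is undefined (`NA`, never 0) when either variable is constant
— e.g. for identical sequences.

## Distances and their corrections

Closed forms are used throughout: Jukes–Cantor, Kimura two-parameter,
Tamura–Nei (with base frequencies averaged over the two sequences of
each pair, which is robust to compositional drift), and the log-det
(paralinear) distance \(d = -\tfrac14\big[\ln\det F - \tfrac12\sum_i
\ln(f_i g_i)\big]\) for GTR-class genes, since a true GTR pairwise
distance has no closed form. Gamma rate heterogeneity replaces each
\(-\ln x\) term by \(\alpha(x^{-1/\alpha} - 1)\); an invariant-sites
proportion \(p_{inv}\) rescales the observed proportions by
\(1/(1-p_{inv})\) first. The gamma/invariant corrections apply to the
JC/K2P/TN93 families only; the log-det distance is used as is.
Saturation can push a pair outside the log domain; the result is then a
flagged `NA`. Neighbor joining refuses matrices containing `NA` — the
caller must prune taxa or change model — because silently imputing a
distance would fabricate topology.

## Tree inference

* **NJ**: Saitou–Nei agglomeration (via ape) on the model's distance
  matrix; negative branch-length estimates are clamped to zero with the
  deficit moved to the adjacent branch.
* **MP**: for nine or fewer taxa the search is exact (all unrooted
  topologies are enumerated and Fitch-scored); above that, several
  random-addition starts are each improved by SPR rearrangements to a
  local optimum, and all distinct minimum-score topologies are
  retained. The swap set is recorded in the result metadata. The MP
  point estimate used in benchmarks is the strict consensus of the tied
  optima, mirroring common practice.
* **ML**: hill climbing that starts from the NJ tree on the model's
  distance surrogate and alternates branch-length optimization with
  nearest-neighbor-interchange sweeps until no move improves the
  likelihood (phangorn's `optim.pml` drives this). The default model is
  HKY with empirical base frequencies, a transition/transversion ratio
  estimated by counting, and 4-category gamma rates whose shape is
  optimized along with the branch lengths; following the package's
  scope, no further model parameters are optimized jointly with the
  topology.
* **Bootstrap**: columns resampled with replacement; the support of an
  internal edge of the point tree is the percentage of replicate trees
  containing that bipartition. Replicate \(r\) uses seed `seed + r`, so
  any run is bit-reproducible. Failed replicates (e.g. saturated
  distance matrices) are skipped and counted; more than 10% skips
  attaches a warning.

## Congruence classification

Splits are stored canonically (the side not containing the
lexicographically smallest leaf). For a reference split \(A|B\) and the
test tree's split set \(S\):

* *coinciding* if \(A|B \in S\);
* *conflicting* if absent and incompatible with at least one member of
  \(S\) (two splits are compatible iff one of the four side
  intersections is empty);
* *unresolved* otherwise — the test tree neither confirms nor
  contradicts the node, typically because low-support edges were
  collapsed.

Classification is reference-centric (deviation *from* the
whole-mitogenome topology); `rf_distance()` provides the symmetric
companion. By default both trees are collapsed at the support cutoff
before classification; `collapse = "test"` collapses only the test
tree. Raising the cutoff can only move splits from coinciding or
conflicting into unresolved, a monotonicity the test suite checks. The
three raw counts are always retained alongside `deviation =
conflicting + unresolved`, so any other weighting can be recomputed.

## The synthetic benchmark

`make_benchmark()` draws one Yule species tree (waiting time
\(\mathrm{Exp}(k\lambda)\) while \(k\) lineages exist, plus a final
\(\mathrm{Exp}(n\lambda)\) stretch, giving expected root height
\(\sum_{k=2}^{n} 1/(k\lambda)\)), rescales it to a target root-to-tip
depth, stretches the stem branch of the outgroup clade (the smaller
side of the root split), and simulates each gene on that shared tree.
Per-branch evolution uses the exact transition probabilities
\(P(t)=e^{Qt}\) from an eigendecomposition of the reversible rate
matrix, normalized to one expected substitution per unit branch
length; site rates mix a 4-category discrete gamma with invariant
sites, rescaled to mean one so branch lengths keep their
substitutions-per-site meaning.

Default study conditions (chosen once to emulate a realistic
mitogenome experiment, and used by the acceptance checks):

* 20 taxa, Yule birth rate 1, root-to-tip depth 0.2
  substitutions/site at rate multiplier 1;
* species-tree draws are rejected until every internal edge is at
  least 0.003 expected substitutions/site after rescaling (roughly 80
  expected substitutions on the full concatenation). A congruence
  benchmark needs a resolvable truth: an edge below this floor carries
  too little signal for *any* method at these alignment lengths, so an
  unconditioned draw would measure tree-shape luck, not method
  behavior. Real mitogenome reference topologies are, likewise, fully
  resolved. The pure Yule sampler `sample_yule_tree()` is left
  unconditioned (its closed-form height expectation is tested as is);
* 15 genes with realistic mitochondrial lengths (161–1823 bp; the 13
  protein-coding genes plus the two rRNAs), each under a GTR, TN93 or
  HKY model with Γ(α = 2) rate heterogeneity and 10% invariant sites;
* A+T-rich composition (60% A+T) and transition bias (purine /
  pyrimidine transition rate ratios 2.5 / 5), which makes transitions
  saturate well before transversions;
* graded gene rate multipliers 0.5–8×: the rRNA-like genes evolve
  slowly and stay unsaturated while the fastest genes (an ATP8-like
  161 bp gene and a NADH2-like 1 kb gene at 8×) saturate —
  reproducing in simulation the spread of saturation indices seen in
  real mitogenome data (mean index about 0.96 for the 16S-like gene
  down to about 0.35 for the ATP8-like gene over 20 replicates);
* an outgroup stem stretched 4×, so outgroup pairs dominate the
  saturated tail of every distance distribution, as a genetically
  distant outgroup genus does in real data.

What the generator deliberately does **not** emulate: indels and
alignment error, the control region's length polymorphism (excluded
from real analyses anyway), compositional heterogeneity across
lineages, codon structure within protein-coding genes, and nuclear
copies of mitochondrial genes. Passing the simulation-based checks
therefore validates the pipeline's correctness and its behavior under
saturation, not robustness to these additional real-data complications.

## Numerical and design choices

* Coordinates: partition files are 1-based inclusive (GenBank style),
  internal storage is 0-based half-open. Intervals of different genes
  may overlap (mitochondrial genes do); intervals within a gene may
  not.
* Gaps, `N` and IUPAC ambiguity codes are kept in storage but treated
  as missing by all counting (pairwise deletion), matching how
  low-coverage positions are handled in practice.
* Model tokens in partition files (`TN93+G+I`, …) set the family and
  switch on gamma (α = 0.5) and invariant sites (0.3) with package
  defaults; explicit parameters can be given programmatically via
  `model_spec()`. A `+T` suffix in published model tables is read as
  `+I` (a recurring misprint).
* Ties in the saturation ranking break alphabetically; genes with an
  undefined index sort last and are flagged.
* The pruning count `k` is a configuration parameter (no automatic
  threshold on the index): real studies choose it by inspection.
* Saturation profiles for the pruning experiment are computed on the
  ingroup only when an outgroup is configured, since the question is
  saturation within the focal clade.
* Bootstrap replicates default to 100 in benchmark mode; the count is
  recorded in every report. Entropy-based saturation tests (information
  content against a randomized alignment) are out of scope; the index
  here is the transition–transversion correlation itself.
* Problem sizes in the test suite: oracle equivalences run at 6–8 taxa
  and tens of sites where exhaustive enumeration is exact; the
  simulation studies use 20 seeds of the default 20-taxon benchmark.
  These sizes were chosen so the full suite runs on a laptop in
  minutes while keeping every estimate's Monte-Carlo error well inside
  the asserted margins.

## Known limitations

* The BI (Bayesian) column of a real study has no direct counterpart
  here; the method ensemble is NJ/MP/ML, and deviation columns are
  produced per implemented method.
* Heuristic MP uses SPR (not TBR) rearrangements; the contract is
  "local optimum under the recorded swap set", and equality with the
  exact search is asserted only at enumerable sizes.
* The log-det distance carries no gamma correction, and GTR model
  parameters are not estimated by maximum likelihood — both are
  standard simplifications for distance-based steps.
* `collapse_low_support()` returns a topology with supports; branch
  lengths are not preserved through collapsing (congruence counting
  never uses them).

## A worked example

```{r example, eval = FALSE}
library(phylosat)

truth <- make_benchmark(simulation_config(seed = 42))
config <- benchmark_config(methods = c("nj", "mp"), boot_replicates = 100,
                           outgroup = truth$outgroup, seed = 42)

bm <- gene_benchmark(truth$alignment, truth$partition_map, config)
tidy(bm)                                   # the per-gene ranking table
saturation_deviation_correlation(bm, "nj") # index vs deviation
autoplot(bm$profiles$ATP8)                 # saturation plot of one gene

px <- pruning_experiment(truth$alignment, truth$partition_map, config)
px$congruent_before
px$congruent_after
```
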