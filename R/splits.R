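#' Bipartition (split) sets of unrooted trees
#'
#' Every internal edge of an unrooted tree induces a bipartition of the
#' leaves. Splits are stored canonically as the side *not* containing the
#' lexicographically smallest leaf, with any per-edge support carried
#' over from the tree's node labels. Trivial splits (one leaf against the
#' rest) are excluded. Trees with fewer than 4 leaves have no non-trivial
#' split and yield an empty set.
#'
#' @param tree An [ape::phylo] tree (rooted trees are unrooted first;
#'   rooting does not change the split set).
#' @return An object of class `split_set`: list with `universe` (sorted
#'   leaf labels) and `splits` (named list; each element has `members`
#'   and `support`, `NA` if absent).
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- sort(tree$tip.label)
  nt <- length(tree$tip.label)
  if (nt >= 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  splits <- list()
  if (nt >= 4L) {
    n <- nt
    root <- n + 1L
    internal <- setdiff(unique(tree$edge[, 2L][tree$edge[, 2L] > n]), root)
    anchor <- labs[1L]
    for (v in internal) {
      tips <- tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1]]]
      if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
      if (length(tips) <= 1L || length(tips) >= nt - 1L) next
      sup <- NA_real_
      if (!is.null(tree$node.label)) {
        lab <- tree$node.label[v - n]
        if (!is.na(lab) && nzchar(lab)) sup <- suppressWarnings(as.numeric(lab))
      }
      key <- paste(sort(tips), collapse = "\r")
      splits[[key]] <- list(members = sort(tips), support = sup)
    }
  }
  structure(list(universe = labs, splits = splits), class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set: %d non-trivial splits over %d leaves>\n",
              length(x$splits), length(x$universe)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.split_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$splits, function(s) {
    tibble(split = paste(s$members, collapse = "|"),
           size = length(s$members), support = s$support)
  }))
}

# rebuild a (possibly multifurcating) tree from a compatible split set;
# supports become node labels
tree_from_splits <- function(universe, splits, supports = NULL) {
  universe <- sort(universe)
  if (length(splits) == 0L) {
    return(ape::read.tree(text = paste0("(", paste(universe, collapse = ","), ");")))
  }
  ord <- order(vapply(splits, length, integer(1)), decreasing = TRUE)
  splits <- splits[ord]
  supports <- if (is.null(supports)) rep(NA_real_, length(splits)) else supports[ord]
  # parent of each clade = smallest strictly-enclosing clade (or the root)
  n <- length(splits)
  parent <- integer(n)  # 0 = root
  for (i in seq_len(n)) {
    parent[i] <- 0L
    if (i > 1L) for (j in rev(seq_len(i - 1L))) {
      if (all(splits[[i]] %in% splits[[j]])) { parent[i] <- j; break }
    }
  }
  children_of <- lapply(0:n, function(j) which(parent == j))
  newick <- function(j, members) {
    kids <- children_of[[j + 1L]]
    covered <- if (length(kids)) unlist(splits[kids]) else character(0)
    bare <- setdiff(members, covered)
    parts <- c(
      vapply(kids, function(k) {
        lab <- if (is.na(supports[k])) "" else format(supports[k])
        paste0(newick(k, splits[[k]]), lab)
      }, character(1)),
      bare
    )
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(newick(0L, universe), ";")
  ape::read.tree(text = txt)
}

#' Collapse poorly supported edges into polytomies
#'
#' Contracts every internal edge whose support value is below `cutoff`,
#' mirroring the convention of displaying nodes with bootstrap support
#' below a threshold (typically 51) as unresolved. Leaves and
#' well-supported edges are untouched; branch lengths are not preserved
#' (the result is a topology with supports).
#'
#' @param tree A support-annotated [ape::phylo] tree (supports as node
#'   labels, percentages in `[0, 100]`).
#' @param cutoff Support threshold; edges with `support < cutoff` are
#'   collapsed.
#' @return A `phylo` topology whose remaining internal edges all have
#'   support `>= cutoff`.
#' @export
collapse_low_support <- function(tree, cutoff = 51) {
  ss <- bipartitions(tree)
  if (length(ss$splits)) {
    sup <- vapply(ss$splits, function(s) s$support, numeric(1))
    if (all(is.na(sup))) {
      abort("tree has no support values on its internal edges")
    }
    keep <- is.na(sup) | sup >= cutoff
    ss$splits <- ss$splits[keep]
  }
  tree_from_splits(ss$universe,
                   lapply(ss$splits, `[[`, "members"),
                   vapply(ss$splits, `[[`, "support", FUN.VALUE = numeric(1)))
}

# TRUE when two splits over the same universe are compatible: at least one
# of the four side-intersections is empty
splits_compatible <- function(a, b, universe) {
  ac <- setdiff(universe, a)
  bc <- setdiff(universe, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' non-trivial split
#' sets.
#'
#' @param tree_a,tree_b Trees over the same leaf set.
#' @return A non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  sa <- bipartitions(tree_a)
  sb <- bipartitions(tree_b)
  if (!identical(sa$universe, sb$universe)) {
    abort("trees are incomparable: different leaf sets")
  }
  length(setdiff(names(sa$splits), names(sb$splits))) +
    length(setdiff(names(sb$splits), names(sa$splits)))
}

#' Node congruence of a test tree against a reference tree
#'
#' Classifies every non-trivial split of the reference tree as
#' *coinciding* (present in the test tree), *conflicting* (absent and
#' incompatible with at least one test split) or *unresolved* (absent but
#' compatible with every test split — the test tree neither confirms nor
#' contradicts it). The scalar `deviation = n_conflicting + n_unresolved`
#' is the per-gene dissimilarity used to rank genes against the
#' whole-mitogenome topology.
#'
#' When `cutoff` is given, support-annotated trees are first collapsed
#' with [collapse_low_support()]: both trees by default, or only the test
#' tree with `collapse = "test"`.
#'
#' @param reference,test Trees. Same leaf set required unless
#'   `prune_to_common = TRUE`, in which case both are pruned to the
#'   shared leaves first (an explicit opt-in, because silent pruning
#'   hides data errors).
#' @param cutoff Optional support threshold (percentage scale).
#' @param collapse `"both"` (default), `"test"`, or `"none"`.
#' @param prune_to_common Prune to the common leaf set before comparing.
#' @param reference_id,test_id Labels stored in the report.
#' @return An object of class `congruence_report`; see Details. Use
#'   [tidy()] for the per-split classification and [glance()] for the
#'   count summary.
#' @export
classify_splits <- function(reference, test, cutoff = NULL,
                            collapse = c("both", "test", "none"),
                            prune_to_common = FALSE,
                            reference_id = "reference", test_id = "test") {
  collapse <- match.arg(collapse)
  common <- intersect(reference$tip.label, test$tip.label)
  if (!setequal(reference$tip.label, test$tip.label)) {
    if (!prune_to_common) {
      abort("trees are incomparable: leaf sets differ (set prune_to_common = TRUE to compare on the shared leaves)")
    }
    if (length(common) < 4L) abort("fewer than 4 shared leaves")
    reference <- ape::keep.tip(reference, common)
    test <- ape::keep.tip(test, common)
  }
  if (!is.null(cutoff) && collapse != "none") {
    if (collapse == "both") reference <- collapse_low_support(reference, cutoff)
    test <- collapse_low_support(test, cutoff)
  }
  rs <- bipartitions(reference)
  ts <- bipartitions(test)
  uni <- rs$universe
  rows <- lapply(names(rs$splits), function(key) {
    mem <- rs$splits[[key]]$members
    if (key %in% names(ts$splits)) {
      tibble(split = paste(mem, collapse = "|"),
             classification = "coinciding",
             test_support = ts$splits[[key]]$support)
    } else {
      conflict <- any(vapply(ts$splits, function(t2) {
        !splits_compatible(mem, t2$members, uni)
      }, logical(1)))
      tibble(split = paste(mem, collapse = "|"),
             classification = if (conflict) "conflicting" else "unresolved",
             test_support = NA_real_)
    }
  })
  tab <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(split = character(0), classification = character(0),
           test_support = numeric(0))
  }
  n_co <- sum(tab$classification == "coinciding")
  n_cf <- sum(tab$classification == "conflicting")
  n_un <- sum(tab$classification == "unresolved")
  structure(
    list(reference_id = reference_id, test_id = test_id,
         support_cutoff = if (is.null(cutoff)) NA_real_ else cutoff,
         n_coinciding = n_co, n_conflicting = n_cf, n_unresolved = n_un,
         deviation = n_cf + n_un, splits = tab),
    class = "congruence_report"
  )
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf(
    "<congruence_report %s vs %s (cutoff %s): %d coinciding, %d conflicting, %d unresolved; deviation %d>\n",
    x$test_id, x$reference_id,
    ifelse(is.na(x$support_cutoff), "none", format(x$support_cutoff)),
    x$n_coinciding, x$n_conflicting, x$n_unresolved, x$deviation))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.congruence_report <- function(x, ...) x$splits

#' @exportS3Method generics::glance
glance.congruence_report <- function(x, ...) {
  tibble(reference = x$reference_id, test = x$test_id,
         support_cutoff = x$support_cutoff,
         n_coinciding = x$n_coinciding, n_conflicting = x$n_conflicting,
         n_unresolved = x$n_unresolved, deviation = x$deviation)
}

#' Write a congruence report to disk
#'
#' Emits `<prefix>.tsv` (one row per reference split: the smaller side's
#' leaves, its classification, and the matching test split's support)
#' and `<prefix>.json` (the count summary).
#'
#' @param report A [classify_splits()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_congruence_report <- function(report, prefix) {
  stopifnot(inherits(report, "congruence_report"))
  write.table(as.data.frame(report$splits), paste0(prefix, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(glance(report)), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
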