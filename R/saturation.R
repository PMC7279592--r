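#' Substitution-saturation profile of a gene
#'
#' For every unordered taxon pair the profile records the model distance
#' `d`, the observed transition proportion `s = p1 + p2` and the observed
#' transversion proportion `v = q` — the data behind a classic
#' saturation plot (s and v against genetic distance). The scalar
#' saturation index is the Pearson correlation between `s` and `v` across
#' pairs: at low divergence both grow roughly linearly with path length
#' and the correlation is near 1; when transitions saturate (multiple
#' hits) `s` plateaus while `v` keeps growing and the correlation drops.
#' Lower index = more saturated.
#'
#' Pairs whose model distance is undefined (saturation overflow) keep
#' their `(s, v)` record — the index needs only the observed proportions,
#' and those pairs are exactly the saturated ones — but are excluded from
#' any distance-dependent use.
#'
#' @param aln An alignment (or a gene extracted from one).
#' @param model A [model_spec()] used for the distance axis.
#' @param taxon_subset Optional character vector restricting the profile
#'   to a subset of taxa (e.g. the ingroup with the distant outgroup
#'   excluded); at least 3 taxa.
#' @param gene_name Label stored in the profile.
#' @param subset_label Label describing the taxon subset (e.g. `"all"`,
#'   `"ingroup-only"`).
#' @return An object of class `saturation_profile`: list with
#'   `gene_name`, `records` (tibble: `taxon_i`, `taxon_j`, `d`, `s`,
#'   `v`), `index_r`, `n_pairs`, `taxon_subset_label`, `model`.
#' @export
saturation_profile <- function(aln, model = default_model(),
                               taxon_subset = NULL,
                               gene_name = "gene",
                               subset_label = if (is.null(taxon_subset)) "all" else "subset") {
  aln <- as_alignment(aln)
  labs <- rownames(aln)
  if (!is.null(taxon_subset)) {
    missing <- setdiff(taxon_subset, labs)
    if (length(missing)) abort(sprintf("unknown taxa: %s", paste(missing, collapse = ", ")))
    labs <- labs[labs %in% taxon_subset]
  }
  if (length(labs) < 3L) abort("need at least 3 taxa in the subset")
  prs <- combn(labs, 2L)
  records <- dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(k) {
    cnt <- pair_counts(aln, prs[1L, k], prs[2L, k])
    tibble(taxon_i = prs[1L, k], taxon_j = prs[2L, k],
           d = pair_distance(cnt, model),
           s = cnt$p1 + cnt$p2, v = cnt$q)
  }))
  structure(
    list(gene_name = gene_name, records = records,
         index_r = saturation_index_from_records(records),
         n_pairs = nrow(records),
         taxon_subset_label = subset_label,
         model = format_model_token(model)),
    class = "saturation_profile"
  )
}

saturation_index_from_records <- function(records) {
  s <- records$s
  v <- records$v
  if (length(s) < 3L) return(NA_real_)
  if (var(s) == 0 || var(v) == 0) return(NA_real_)
  cor(s, v)
}

#' Scalar saturation index of a profile
#'
#' The Pearson product-moment correlation of transition vs transversion
#' proportions over taxon pairs. Undefined (`NA`, not 0) when either
#' variable is constant or fewer than 3 pairs exist.
#'
#' @param profile A [saturation_profile()].
#' @return A correlation in `[-1, 1]`, or `NA_real_`.
#' @export
saturation_index <- function(profile) {
  stopifnot(inherits(profile, "saturation_profile"))
  saturation_index_from_records(profile$records)
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat(sprintf("<saturation_profile '%s' (%s, %s): %d pairs, index_r = %s>\n",
              x$gene_name, x$model, x$taxon_subset_label, x$n_pairs,
              if (is.na(x$index_r)) "NA" else sprintf("%.3f", x$index_r)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.saturation_profile <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.saturation_profile <- function(x, ...) {
  tibble(gene = x$gene_name, n_pairs = x$n_pairs, index_r = x$index_r,
         n_undefined_d = sum(is.na(x$records$d)),
         taxon_subset = x$taxon_subset_label, model = x$model)
}

#' @exportS3Method ggplot2::autoplot
autoplot.saturation_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$records, c("s", "v"),
                              names_to = "type", values_to = "proportion")
  long <- dplyr::filter(long, !is.na(.data$d))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$proportion,
                                     colour = .data$type, shape = .data$type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("genetic distance (%s)", object$model),
      y = "observed proportion",
      colour = NULL, shape = NULL,
      title = sprintf("%s: transitions (s) and transversions (v)", object$gene_name),
      subtitle = sprintf("saturation index r = %s, %s taxa",
                         ifelse(is.na(object$index_r), "NA", sprintf("%.2f", object$index_r)),
                         object$taxon_subset_label)
    ) +
    ggplot2::theme_minimal()
}

#' Export a saturation profile as TSV
#'
#' One row per taxon pair with `d`, `s`, `v` — the exact data behind a
#' saturation plot.
#'
#' @param profile A [saturation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank genes from most to least saturated
#'
#' Ascending order of the saturation index (lowest correlation = most
#' saturated first); ties broken alphabetically by gene name; genes with
#' an undefined index are listed last and flagged.
#'
#' @param profiles A list of [saturation_profile()] objects, or a tibble
#'   with columns `gene` and `index_r`.
#' @return A tibble with columns `gene`, `index_r`, `rank`,
#'   `index_defined`.
#' @export
rank_genes_by_saturation <- function(profiles) {
  tab <- if (inherits(profiles, "data.frame")) {
    tibble(gene = profiles$gene, index_r = profiles$index_r)
  } else {
    dplyr::bind_rows(lapply(profiles, function(p) {
      tibble(gene = p$gene_name, index_r = p$index_r)
    }))
  }
  if (!any(!is.na(tab$index_r))) abort("no profile has a defined saturation index")
  tab <- dplyr::arrange(tab, is.na(.data$index_r), .data$index_r, .data$gene)
  dplyr::mutate(tab, rank = dplyr::row_number(),
                index_defined = !is.na(.data$index_r))
}

#' Drop the k most saturated genes
#'
#' Deterministic given the profiles: removes the `k` genes ranked most
#' saturated by [rank_genes_by_saturation()] and returns the surviving
#' gene names in their original partition-map order.
#'
#' @param pm A [partition_map()].
#' @param profiles As in [rank_genes_by_saturation()]; must cover the
#'   map's genes.
#' @param k Number of genes to remove; must be smaller than the number of
#'   genes in the map.
#' @return Character vector of retained gene names.
#' @export
prune_saturated <- function(pm, profiles, k) {
  genes <- gene_names(pm)
  if (k < 0 || k >= length(genes)) {
    abort(sprintf("k must be in 0..%d (got %s)", length(genes) - 1L, k))
  }
  if (k == 0L) return(genes)
  ranking <- rank_genes_by_saturation(profiles)
  drop <- ranking$gene[seq_len(k)]
  setdiff(genes, drop)
}
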