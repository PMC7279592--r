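#' Gene partition maps
#'
#' A partition map assigns named genes to column intervals of an
#' alignment, each with an attached substitution model. External partition
#' files use 1-based inclusive coordinates (GenBank style); internally
#' intervals are stored 0-based half-open. Intervals of *different* genes
#' may overlap — mitochondrial protein-coding genes do (e.g. ATP6/COX3) —
#' but intervals within one gene must be disjoint and sorted.
#'
#' @param genes A named list: for each gene, a list with `intervals` (an
#'   n x 2 integer matrix of 0-based half-open `[start, end)` ranges) and
#'   `model` (a [model_spec()] or `NULL` for the pipeline default).
#' @param total_length Number of columns of the alignment the map refers to.
#' @return An object of class `partition_map`.
#' @export
partition_map <- function(genes, total_length) {
  if (anyDuplicated(names(genes))) {
    abort(sprintf("duplicate gene name: '%s'",
                  names(genes)[duplicated(names(genes))][1L]))
  }
  for (g in names(genes)) {
    iv <- genes[[g]]$intervals
    if (!is.matrix(iv) || ncol(iv) != 2L) abort(sprintf("gene '%s': intervals must be an n x 2 matrix", g))
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > total_length)) {
      abort(sprintf("gene '%s': interval outside [0, %d)", g, total_length))
    }
    if (any(iv[, 2L] <= iv[, 1L])) abort(sprintf("gene '%s': empty or reversed interval", g))
    if (nrow(iv) > 1L) {
      o <- order(iv[, 1L])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
        abort(sprintf("gene '%s': overlapping intervals within one gene", g))
      }
      genes[[g]]$intervals <- iv
    }
  }
  structure(list(genes = genes, total_length = as.integer(total_length)),
            class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  cat(sprintf("<partition_map: %d genes over %d columns>\n",
              length(x$genes), x$total_length))
  for (g in head(names(x$genes), 20L)) {
    iv <- x$genes[[g]]$intervals
    rng <- paste(sprintf("%d-%d", iv[, 1L] + 1L, iv[, 2L]), collapse = ",")
    mod <- x$genes[[g]]$model
    cat(sprintf("  %-10s %s%s\n", g, rng,
                if (is.null(mod)) "" else paste0("  [", mod$name, "]")))
  }
  invisible(x)
}

#' @rdname partition_map
#' @param pm A partition map.
#' @export
gene_names <- function(pm) names(pm$genes)

#' @rdname partition_map
#' @param gene A gene name.
#' @export
gene_length <- function(pm, gene) {
  iv <- pm$genes[[gene]]$intervals
  if (is.null(iv)) abort(sprintf("unknown gene: '%s'", gene))
  sum(iv[, 2L] - iv[, 1L])
}

#' Read a partition file
#'
#' Parses RAxML-style partition lines, one gene per line:
#' `name = start-end[,start-end ...] [, model]` with 1-based inclusive
#' coordinates, e.g. `16S = 2001-3554, TN93+G+I`. A missing model token
#' gives the pipeline default model (`NULL`). A `\3` codon-stride suffix
#' on a range is accepted and ignored. Blank lines and `#` comments are
#' skipped.
#'
#' @param path Path to the partition file.
#' @param total_length Alignment length the coordinates must fit in.
#' @return A [partition_map()].
#' @export
read_partitions <- function(path, total_length) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- list()
  for (ln in lines) {
    halves <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(halves) != 2L) abort(sprintf("cannot parse partition line: '%s'", ln))
    name <- trimws(halves[1L])
    if (name %in% names(genes)) abort(sprintf("duplicate gene name: '%s'", name))
    tokens <- trimws(strsplit(halves[2L], ",", fixed = TRUE)[[1]])
    is_range <- grepl("^[0-9]+\\s*-\\s*[0-9]+(\\\\3)?$", tokens)
    model_tok <- tokens[!is_range]
    if (length(model_tok) > 1L) abort(sprintf("gene '%s': more than one model token", name))
    iv <- t(vapply(tokens[is_range], function(tok) {
      tok <- sub("\\\\3$", "", tok)
      ab <- as.integer(strsplit(tok, "-")[[1]])
      if (ab[1L] < 1L || ab[2L] > total_length || ab[2L] < ab[1L]) {
        abort(sprintf("gene '%s': range %s outside 1..%d", name, tok, total_length))
      }
      c(ab[1L] - 1L, ab[2L])  # to 0-based half-open
    }, integer(2)))
    dimnames(iv) <- NULL
    model <- if (length(model_tok) == 1L) parse_model_token(model_tok) else NULL
    genes[[name]] <- list(intervals = iv, model = model)
  }
  if (length(genes) == 0L) abort(sprintf("no partitions in %s", path))
  partition_map(genes, total_length)
}

#' Write a partition map to a file
#'
#' Inverse of [read_partitions()]; coordinates are written 1-based
#' inclusive.
#'
#' @param pm A partition map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(pm, path) {
  lines <- vapply(names(pm$genes), function(g) {
    iv <- pm$genes[[g]]$intervals
    rng <- paste(sprintf("%d-%d", iv[, 1L] + 1L, iv[, 2L]), collapse = ", ")
    mod <- pm$genes[[g]]$model
    if (is.null(mod)) sprintf("%s = %s", g, rng)
    else sprintf("%s = %s, %s", g, rng, format_model_token(mod))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

gene_columns <- function(pm, gene) {
  iv <- pm$genes[[gene]]$intervals
  if (is.null(iv)) abort(sprintf("unknown gene: '%s'", gene))
  unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv[i, 1L] + 1L, iv[i, 2L])))
}

#' Extract one gene from an alignment
#'
#' @param aln An alignment whose columns the partition map indexes.
#' @param pm A [partition_map()].
#' @param gene Gene name.
#' @return A `phylosat_alignment` restricted to the gene's columns (its
#'   intervals concatenated in order); taxa unchanged.
#' @export
extract_gene <- function(aln, pm, gene) {
  aln <- as_alignment(aln)
  if (ncol(aln) != pm$total_length) {
    abort(sprintf("alignment has %d columns but partition map covers %d",
                  ncol(aln), pm$total_length))
  }
  aln[, gene_columns(pm, gene)]
}

#' Concatenate gene alignments
#'
#' Appends the column blocks of the named genes in the order given. When
#' two requested genes overlap on the source alignment the shared columns
#' are duplicated, mirroring how overlapping mitochondrial reading frames
#' are handled in per-gene supermatrices.
#'
#' @inheritParams extract_gene
#' @param genes Character vector of gene names (non-empty).
#' @return A `phylosat_alignment` of length `sum(gene lengths)`.
#' @export
concatenate_genes <- function(aln, pm, genes) {
  if (length(genes) == 0L) abort("at least one gene name is required")
  aln <- as_alignment(aln)
  cols <- unlist(lapply(genes, function(g) gene_columns(pm, g)))
  aln[, cols]
}

#' Per-gene alignment summary
#'
#' One row per gene: length, variable sites and A+T content — the shape of
#' a per-gene informativeness table.
#'
#' @inheritParams extract_gene
#' @param taxon_subset Optional taxa to restrict variable-site counting to.
#' @return A tibble with columns `gene`, `bp`, `n_variable_sites`,
#'   `at_fraction`.
#' @export
partition_summary <- function(aln, pm, taxon_subset = NULL) {
  dplyr::bind_rows(lapply(gene_names(pm), function(g) {
    sub <- extract_gene(aln, pm, g)
    tibble(
      gene = g,
      bp = ncol(sub),
      n_variable_sites = variable_sites(sub, taxon_subset),
      at_fraction = base_composition(sub)$at_fraction
    )
  }))
}
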