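#' Multiple sequence alignments
#'
#' An alignment is stored as an uppercase character matrix with one row per
#' taxon (rownames are the taxon labels) and one column per site. The
#' alphabet is `A C G T N -` plus the IUPAC ambiguity codes; `U` is mapped
#' to `T` on construction. All counting operations in the package treat
#' gaps and ambiguity codes as missing data.
#'
#' @param x A character matrix (rows = taxa, columns = sites), or a named
#'   character vector of equal-length sequence strings.
#' @return An object of class `phylosat_alignment` (a character matrix).
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "AC-T"))
#' n_taxa(aln)
#' n_sites(aln)
#' @export
alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("sequences must be named by taxon")
    }
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      abort(sprintf(
        "alignment rows must have equal length; record '%s' has %d characters, expected %d",
        bad, nchar(x[[bad]]), lens[1L]
      ))
    }
    x <- do.call(rbind, lapply(strsplit(x, ""), identity))
    rownames(x) <- names(lens)
  }
  if (!is.matrix(x) || !is.character(x)) abort("expected a character matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) abort("alignment must have at least one taxon and one site")
  if (is.null(rownames(x))) abort("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) {
    abort(sprintf(
      "duplicate taxon label: '%s'",
      rownames(x)[duplicated(rownames(x))][1L]
    ))
  }
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  structure(x, class = c("phylosat_alignment", "matrix", "array"))
}

#' @rdname alignment
#' @param aln An alignment.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname alignment
#' @export
n_sites <- function(aln) ncol(aln)

#' @rdname alignment
#' @export
taxa <- function(aln) rownames(aln)

#' @export
print.phylosat_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d taxa x %d sites>\n", nrow(x), ncol(x)))
  shown <- head(rownames(x), 6L)
  for (t in shown) {
    s <- paste(x[t, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more taxa\n", nrow(x) - 6L))
  invisible(x)
}

# column subsetting keeps the class; used heavily by the bootstrap
#' @export
`[.phylosat_alignment` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = c("phylosat_alignment", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) into an
#' [alignment()]. Records must all have the same length; sequences are
#' uppercased and `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A `phylosat_alignment`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))  # label = first token
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' Writes unwrapped FASTA in taxon order; `read_fasta()` round-trips the
#' result exactly.
#'
#' @param aln An alignment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  aln <- as_alignment(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

as_alignment <- function(x) {
  if (inherits(x, "phylosat_alignment")) x else alignment(x)
}

# symbols treated as observed states by every counting operation
.bases <- c("A", "C", "G", "T")

#' Count variable sites
#'
#' A site is variable when at least two distinct unambiguous bases
#' (`A`, `C`, `G`, `T`) occur in its column; gaps and ambiguity codes are
#' ignored when assessing distinctness.
#'
#' @param aln An alignment.
#' @param taxon_subset Optional character vector of taxa to restrict to
#'   (e.g. the ingroup only, as when counting variable sites within one
#'   genus).
#' @return Integer count of variable columns.
#' @export
variable_sites <- function(aln, taxon_subset = NULL) {
  aln <- as_alignment(aln)
  m <- unclass(aln)
  if (!is.null(taxon_subset)) {
    missing <- setdiff(taxon_subset, rownames(m))
    if (length(missing)) abort(sprintf("unknown taxa: %s", paste(missing, collapse = ", ")))
    m <- m[taxon_subset, , drop = FALSE]
  }
  sum(apply(m, 2L, function(col) {
    obs <- unique(col[col %in% .bases])
    length(obs) >= 2L
  }))
}

#' Base composition of an alignment
#'
#' Frequencies of `A`, `C`, `G`, `T` over unambiguous sites, overall or per
#' taxon, together with the A+T fraction. A taxon with no unambiguous site
#' is reported with `NA` frequencies.
#'
#' @param aln An alignment.
#' @param per_taxon If `TRUE`, one row per taxon; otherwise a single
#'   pooled row.
#' @return A tibble with columns `taxon` (if per taxon), `A`, `C`, `G`,
#'   `T`, `at_fraction`, `n_sites_used`.
#' @export
base_composition <- function(aln, per_taxon = FALSE) {
  aln <- as_alignment(aln)
  m <- unclass(aln)
  comp_row <- function(chars) {
    chars <- chars[chars %in% .bases]
    n <- length(chars)
    if (n == 0L) {
      return(tibble(A = NA_real_, C = NA_real_, G = NA_real_, T = NA_real_,
                    at_fraction = NA_real_, n_sites_used = 0L))
    }
    f <- table(factor(chars, levels = .bases)) / n
    tibble(A = f[["A"]], C = f[["C"]], G = f[["G"]], T = f[["T"]],
           at_fraction = f[["A"]] + f[["T"]], n_sites_used = n)
  }
  if (per_taxon) {
    dplyr::bind_cols(
      tibble(taxon = rownames(m)),
      dplyr::bind_rows(lapply(seq_len(nrow(m)), function(i) comp_row(m[i, ])))
    )
  } else {
    comp_row(as.vector(m))
  }
}

#' Summarise whole mitogenome FASTA files
#'
#' Computes, for a set of (unaligned) complete mitogenome sequences, the
#' per-genome length and A+T fraction plus their summary statistics. This
#' is the calculation behind reported genome-organisation figures such as
#' the range of mitogenome lengths and the average A+T content of a set of
#' deposited accessions.
#'
#' @param paths Character vector of FASTA file paths (one or more records
#'   each).
#' @return A list with `per_genome` (tibble: label, length_bp,
#'   at_fraction) and `summary` (tibble: n, min_length, max_length,
#'   mean_at_percent).
#' @export
mitogenome_summary <- function(paths) {
  recs <- unlist(lapply(paths, function(p) {
    set <- Biostrings::readBStringSet(p)
    setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }))
  if (length(recs) == 0L) abort("no sequences found")
  per <- dplyr::bind_rows(lapply(names(recs), function(lab) {
    chars <- strsplit(toupper(recs[[lab]]), "")[[1]]
    chars[chars == "U"] <- "T"
    obs <- chars[chars %in% .bases]
    tibble(label = lab, length_bp = length(chars),
           at_fraction = mean(obs %in% c("A", "T")))
  }))
  list(
    per_genome = per,
    summary = tibble(
      n = nrow(per),
      min_length = min(per$length_bp),
      max_length = max(per$length_bp),
      mean_at_percent = 100 * mean(per$at_fraction)
    )
  )
}
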