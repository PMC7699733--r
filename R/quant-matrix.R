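#' Protein quantification matrix
#'
#' `quant_matrix()` constructs the central container of the package: a dense
#' proteins-by-samples matrix of non-negative iBAQ intensities in which a
#' value of 0 means "protein not identified in that sample".  Rows carry a
#' protein (isoform) accession and an aligned gene symbol; rows flagged as
#' reverse-database hits or common contaminants at read time are kept but
#' marked, so downstream filtering is explicit and auditable.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; all
#'   values must be finite and >= 0.
#' @param protein_ids character vector of unique protein/isoform accessions,
#'   one per row.
#' @param gene_symbols character vector of gene symbols aligned to
#'   `protein_ids` (a symbol may repeat across isoforms).
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column.
#' @param flagged logical vector, one per row; `TRUE` marks reverse/decoy or
#'   contaminant entries destined for removal by [remove_contaminants()].
#' @return An object of class `quant_matrix`: a list with elements `values`
#'   (dimnamed matrix), `protein_ids`, `gene_symbols`, `sample_ids`,
#'   `flagged`.
#' @seealso [read_quant_table()], [collapse_to_genes()]
#' @export
quant_matrix <- function(values, protein_ids, gene_symbols, sample_ids,
                         flagged = rep(FALSE, length(protein_ids))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  protein_ids <- as.character(protein_ids)
  gene_symbols <- as.character(gene_symbols)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(protein_ids))
    stop("row count (", nrow(values), ") != number of protein ids (",
         length(protein_ids), ")", call. = FALSE)
  if (length(gene_symbols) != length(protein_ids))
    stop("gene_symbols must align with protein_ids", call. = FALSE)
  if (ncol(values) != length(sample_ids))
    stop("column count (", ncol(values), ") != number of sample ids (",
         length(sample_ids), ")", call. = FALSE)
  if (length(flagged) != length(protein_ids))
    stop("flagged must align with protein_ids", call. = FALSE)
  dup <- unique(protein_ids[duplicated(protein_ids)])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("intensities must be finite (use 0 for 'not identified')",
         call. = FALSE)
  if (any(values < 0))
    stop("negative intensities are not a valid iBAQ value", call. = FALSE)
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(
    list(values = values, protein_ids = protein_ids,
         gene_symbols = gene_symbols, sample_ids = sample_ids,
         flagged = as.logical(flagged)),
    class = "quant_matrix"
  )
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
print.quant_matrix <- function(x, ...) {
  nz <- mean(x$values > 0)
  cat(sprintf("quant_matrix: %d proteins (%d genes) x %d samples\n",
              nrow(x$values), length(unique(x$gene_symbols)),
              ncol(x$values)))
  cat(sprintf("  identified cells: %.1f%%; flagged rows: %d\n",
              100 * nz, sum(x$flagged)))
  invisible(x)
}

#' Subset a quant_matrix by row and/or column index
#'
#' @param x a `quant_matrix`.
#' @param i,j row and column indices (logical, integer or character), as for
#'   a matrix.
#' @param ... ignored.
#' @return A `quant_matrix` restricted to the selected rows/columns.
#' @export
`[.quant_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$protein_ids)
  v <- x$values[i, j, drop = FALSE]
  quant_matrix(v,
               protein_ids = x$protein_ids[i],
               gene_symbols = x$gene_symbols[i],
               sample_ids = colnames(v),
               flagged = x$flagged[i])
}

#' Collapse protein isoforms to gene level
#'
#' Gene-level analyses treat the dominant isoform as the representative
#' signal: by default each gene's per-sample intensity is the maximum over
#' its isoforms (iBAQ of the dominant isoform dominates the gene total).
#' Summation over isoforms is available as an alternative.
#'
#' @param m a `quant_matrix` at isoform level.
#' @param method `"max"` (default) or `"sum"`.
#' @return A `quant_matrix` with one row per gene symbol; `protein_ids` are
#'   the gene symbols themselves.
#' @export
collapse_to_genes <- function(m, method = c("max", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "quant_matrix"))
  g <- factor(m$gene_symbols, levels = unique(m$gene_symbols))
  if (method == "sum") {
    v <- rowsum(m$values, g, reorder = FALSE)
  } else {
    idx <- split(seq_len(nrow(m$values)), g)
    v <- do.call(rbind, lapply(idx, function(ii) {
      if (length(ii) == 1L) m$values[ii, , drop = TRUE]
      else apply(m$values[ii, , drop = FALSE], 2, max)
    }))
  }
  genes <- levels(g)
  quant_matrix(v, protein_ids = genes, gene_symbols = genes,
               sample_ids = m$sample_ids)
}

#' Detection indicator
#'
#' @param m a `quant_matrix`.
#' @return Logical matrix of the same shape; `TRUE` where the protein was
#'   identified (intensity > 0).
#' @export
is_detected <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  m$values > 0
}
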