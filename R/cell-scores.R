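#' Marker-based immune and stromal population scores
#'
#' Estimates the relative abundance of immune and stromal cell populations
#' in each sample from protein quantification, as the arithmetic mean of
#' the log2 abundances of the population's marker proteins that are present
#' in the matrix.  Markers absent from the matrix (never identified in the
#' cohort) are excluded from the mean rather than imputed as zero, since a
#' zero encodes non-identification, not absence.  Scores are abundance
#' scores, not proportions: they support between-sample comparison per
#' population, not composition estimates.
#'
#' @param m a [quant_matrix()] on the log2 scale (typically
#'   quantile-normalized).
#' @param panel a `marker_panel` whose cell-population panels are used;
#'   symbol matching against the matrix is case-insensitive and exact.
#' @return An object of class `population_scores`: list with `scores`
#'   (populations x samples matrix; NA when no marker of the population is
#'   in the matrix) and `n_markers_detected` (named integer vector).
#' @export
population_scores <- function(m, panel) {
  stopifnot(inherits(m, "quant_matrix"), inherits(panel, "marker_panel"))
  pops <- panel$panels[setdiff(names(panel$panels), c("EV", "non-EV"))]
  if (!length(pops)) stop("panel has no cell populations", call. = FALSE)
  sym <- tolower(m$gene_symbols)
  score_rows <- t(vapply(pops, function(markers) {
    idx <- match(tolower(markers), sym)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(rep(NA_real_, length(m$sample_ids)))
    colMeans(m$values[idx, , drop = FALSE])
  }, numeric(length(m$sample_ids))))
  colnames(score_rows) <- m$sample_ids
  n_det <- vapply(pops, function(markers)
    sum(!is.na(match(tolower(markers), sym))), integer(1))
  structure(list(scores = score_rows, n_markers_detected = n_det),
            class = "population_scores")
}

#' @export
print.population_scores <- function(x, ...) {
  cat(sprintf("population_scores: %d populations x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  markers found: %s\n",
              paste(names(x$n_markers_detected), x$n_markers_detected,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Group summary and sample clustering of population scores
#'
#' Per-group mean scores per population, plus average-linkage hierarchical
#' clustering of samples on the Euclidean distance between their population
#' score vectors (populations with undefined scores are dropped from the
#' distance).
#'
#' @param scores a `population_scores` object.
#' @param meta `sample_metadata` covering the score columns.
#' @param grouping metadata column to average over (default
#'   `"cancer_status"`).
#' @return List with `group_means` (populations x groups), `hclust` (the
#'   clustering object), `leaf_order` (sample ids in dendrogram order).
#' @export
score_group_summary <- function(scores, meta, grouping = "cancer_status") {
  stopifnot(inherits(scores, "population_scores"))
  s <- scores$scores
  defined <- rowSums(is.na(s)) == 0
  if (!any(defined))
    stop("no population has a defined score", call. = FALSE)
  meta <- meta[match(colnames(s), meta$sample_id), , drop = FALSE]
  g <- factor(meta[[grouping]])
  gm <- t(rowsum(t(s[defined, , drop = FALSE]), g, reorder = TRUE) /
            as.vector(table(g)))
  hc <- stats::hclust(stats::dist(t(s[defined, , drop = FALSE])),
                      method = "average")
  list(group_means = gm, hclust = hc,
       leaf_order = colnames(s)[hc$order])
}
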