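#' Run the full analysis pipeline
#'
#' Chains every stage on one cohort: preprocessing, covariate-corrected
#' differential expression, proteome-complexity association,
#' EV purity scoring, functional-regulation analysis, population scores and
#' the baseline table, writing one TSV per stage (each with a provenance
#' comment line) plus a JSON run log.
#'
#' @param quant a [quant_matrix()] of raw iBAQ intensities, or a path to a
#'   quantification TSV.
#' @param metadata a `sample_metadata` data.frame, or a CSV path.
#' @param out_dir output directory (created if missing).
#' @param sets optional `gene_set_collection` or GMT path.
#' @param panel optional `marker_panel` or YAML path.
#' @param nta optional list of `size_distribution` objects.
#' @param strategy preprocessing strategy (see [preprocess()]).
#' @param contaminants contaminant id list.
#' @param covariates covariates for the differential model.
#' @param contrast complexity contrast (see [complexity_association()]).
#' @param alpha,fc_threshold functional-regulation filters.
#' @return Invisibly, a list with every stage result and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(quant, metadata, out_dir,
                         sets = NULL, panel = NULL, nta = NULL,
                         strategy = "log_quantile",
                         contaminants = character(),
                         covariates = c("gender", "smoking"),
                         contrast = "stage4_or_dead",
                         alpha = 0.05, fc_threshold = 2) {
  if (is.character(quant)) {
    if (!file.exists(quant))
      stop("quantification file not found: ", quant, call. = FALSE)
    quant <- read_quant_table(quant)
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata))
      stop("metadata file not found: ", metadata, call. = FALSE)
    metadata <- read_sample_metadata(metadata)
  }
  if (is.character(sets)) sets <- read_gene_sets(sets)
  if (is.character(panel)) panel <- read_marker_panels(panel)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  res <- list()
  params <- c(strategy = strategy, contrast = contrast, alpha = alpha,
              fc_threshold = fc_threshold)

  pp <- preprocess(quant, strategy = strategy, contaminants = contaminants)
  norm <- pp$quant
  f <- file.path(out_dir, "normalized.tsv")
  write_quant_table(norm, f); files <- c(files, f)
  res$preprocess <- pp

  de <- fit_moderated_model(norm, metadata, covariates = covariates)
  f <- file.path(out_dir, "diffexpr.tsv")
  write_tsv_provenance(as.data.frame(de), f, params)
  files <- c(files, f)
  f <- file.path(out_dir, "volcano.tsv")
  write_tsv_provenance(volcano_table(de), f, params)
  files <- c(files, f)
  res$de <- de

  counts <- unique_protein_counts(quant)
  cx <- complexity_association(counts, metadata, contrast = contrast)
  f <- file.path(out_dir, "complexity.tsv")
  write_tsv_provenance(
    data.frame(sample_id = names(counts), unique_proteins = counts,
               poor_outcome = cx$group), f,
    c(params, W = cx$W, p_value = cx$p_value))
  files <- c(files, f)
  res$complexity <- cx

  if (!is.null(panel)) {
    ev_markers <- c(panel$panels$EV, panel$panels$`non-EV`)
    gm <- marker_group_means(
      norm, ev_markers,
      groups = stats::setNames(
        as.character(metadata$cancer_status[match(norm$sample_ids,
                                                  metadata$sample_id)]),
        norm$sample_ids))
    scaled <- scale_marker_matrix(gm)
    pur <- purity_scores(scaled, panel)
    f <- file.path(out_dir, "ev_quality.tsv")
    write_tsv_provenance(pur, f, params); files <- c(files, f)
    res$purity <- pur

    ps <- population_scores(norm, panel)
    sc <- as.data.frame(ps$scores)
    sc <- cbind(population = rownames(ps$scores),
                n_markers = ps$n_markers_detected, sc)
    f <- file.path(out_dir, "cell_scores.tsv")
    write_tsv_provenance(sc, f, params); files <- c(files, f)
    res$cell_scores <- ps
  }

  if (!is.null(sets)) {
    ratios <- group_log_ratios(norm, metadata)
    cf <- category_regulation(ratios, sets, alpha = alpha,
                              fc_threshold = fc_threshold)
    f <- file.path(out_dir, "cfra.tsv")
    write_tsv_provenance(cfra_matrix(list(cancer_vs_control = cf)), f,
                         params)
    files <- c(files, f)
    res$cfra <- cf
  }

  if (!is.null(nta)) {
    grp <- metadata$cancer_status[match(
      vapply(nta, function(d) attr(d, "sample_id"), character(1)),
      metadata$sample_id)]
    nt <- nta_normalize_and_test(nta, grp)
    f <- file.path(out_dir, "nta_comparison.tsv")
    write_tsv_provenance(nt$per_bin, f, params); files <- c(files, f)
    res$nta <- nt
  }

  bl <- baseline_table(metadata)
  f <- file.path(out_dir, "baseline.tsv")
  write_tsv_provenance(merge(bl$cells, bl$tests, by = "variable",
                             sort = FALSE), f, params)
  files <- c(files, f)
  res$baseline <- bl

  log <- list(package = "evbal",
              version = as.character(utils::packageVersion("evbal")),
              parameters = as.list(params),
              n_samples = length(quant$sample_ids),
              n_proteins = length(quant$protein_ids),
              outputs = basename(files))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$files <- c(files, file.path(out_dir, "run_log.json"))
  invisible(res)
}

#' Path to a file shipped with the package
#'
#' Convenience accessor for the bundled default marker panels and the
#' 24-sample cohort metadata.
#'
#' @param name file name under the package's `extdata` directory; empty
#'   lists the available files.
#' @return Full path(s).
#' @export
evbal_example <- function(name = "") {
  if (!nzchar(name))
    return(list.files(system.file("extdata", package = "evbal")))
  f <- system.file("extdata", name, package = "evbal")
  if (!nzchar(f)) stop("no shipped file '", name, "'", call. = FALSE)
  f
}
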