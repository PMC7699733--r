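#' Rank-scale a marker abundance matrix to [0, 1]
#'
#' Scales each marker row of (typically group-averaged) iBAQ values across
#' columns to the unit interval for heatmap display and purity scoring.
#' The default is per-row min-max scaling, `(v - min) / (max - min)`,
#' matching a display of continuous shades between 0 and 1; a rank-based
#' alternative `(rank - 1) / (n - 1)` is available.  Constant rows carry no
#' ordering information and map to 0.5.
#'
#' @param m numeric matrix (markers x columns) or a [quant_matrix()]
#'   restricted to panel markers.
#' @param method `"minmax"` (default) or `"rank"` (mid-ranks).
#' @return Numeric matrix of the same shape with values in `[0, 1]`.
#' @export
scale_marker_matrix <- function(m, method = c("minmax", "rank")) {
  method <- match.arg(method)
  v <- if (inherits(m, "quant_matrix")) m$values else as.matrix(m)
  if (ncol(v) < 2)
    stop("need at least 2 columns to scale across", call. = FALSE)
  t(apply(v, 1, function(row) {
    if (max(row) == min(row)) return(rep(0.5, length(row)))
    if (method == "minmax") (row - min(row)) / (max(row) - min(row))
    else (rank(row) - 1) / (length(row) - 1)
  }))
}

#' Averaged marker matrix over sample groups
#'
#' Restricts a quantification matrix to panel markers (matching gene
#' symbols case-insensitively) and averages per group of samples, the input
#' expected by [scale_marker_matrix()] / [purity_scores()].
#'
#' @param m a [quant_matrix()] (raw or log scale).
#' @param markers character vector of marker symbols.
#' @param groups named factor/character: sample id -> group (defaults to one
#'   group per sample).
#' @return Numeric matrix markers x groups of mean intensities.
#' @export
marker_group_means <- function(m, markers,
                               groups = stats::setNames(m$sample_ids,
                                                        m$sample_ids)) {
  stopifnot(inherits(m, "quant_matrix"))
  idx <- match(tolower(markers), tolower(m$gene_symbols))
  if (all(is.na(idx)))
    stop("no panel marker found in matrix; missing: ",
         paste(markers, collapse = ", "), call. = FALSE)
  found <- markers[!is.na(idx)]
  v <- m$values[idx[!is.na(idx)], , drop = FALSE]
  rownames(v) <- found
  g <- factor(groups[m$sample_ids])
  means <- t(rowsum(t(v), g, reorder = TRUE) / as.vector(table(g)))
  means
}

#' EV purity report from a scaled marker matrix
#'
#' Summarizes a 0-1 scaled marker matrix into per-column scores: the
#' `ev_score` is the mean scaled value over EV-flagged markers and the
#' `contamination_score` the mean over non-EV (organelle) markers.  A clean
#' vesicle preparation shows a high EV score and a low contamination score
#' relative to the reference columns.
#'
#' @param scaled matrix from [scale_marker_matrix()]; row names are marker
#'   symbols.
#' @param panel a `marker_panel` flagging each marker as EV or non-EV.
#' @return data.frame (class `purity_report`) with one row per column:
#'   `column`, `ev_score`, `contamination_score` (NA when a flag class has
#'   no marker present).
#' @export
purity_scores <- function(scaled, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  markers <- rownames(scaled)
  flags <- panel$flags[markers]
  if (anyNA(flags))
    stop("no panel flag for marker(s): ",
         paste(markers[is.na(flags)], collapse = ", "), call. = FALSE)
  mean_over <- function(cls) {
    rows <- which(flags == cls)
    if (!length(rows)) return(rep(NA_real_, ncol(scaled)))
    colMeans(scaled[rows, , drop = FALSE])
  }
  structure(data.frame(
    column = colnames(scaled) %||% as.character(seq_len(ncol(scaled))),
    ev_score = as.numeric(mean_over("EV")),
    contamination_score = as.numeric(mean_over("non-EV")),
    stringsAsFactors = FALSE
  ), class = c("purity_report", "data.frame"))
}

#' Classify an EV preparation by its particle-to-protein ratio
#'
#' Vesicular purity heuristic on the ratio of particle count to protein
#' mass: ratios above 3e10 particles per microgram indicate high purity;
#' 2e9 to 2e10 indicate low purity; the literature scheme leaves the band
#' between 2e10 and 3e10 unclassified ("indeterminate"), and anything below
#' 2e9 is reported as "below-low".
#'
#' @param particles particle count.
#' @param protein_ug protein mass in micrograms; must be > 0.
#' @return One of `"high"`, `"indeterminate"`, `"low"`, `"below-low"`, with
#'   the ratio as attribute `"ratio"`.
#' @export
classify_particle_protein_ratio <- function(particles, protein_ug) {
  if (protein_ug <= 0)
    stop("protein mass must be positive", call. = FALSE)
  if (particles < 0) stop("particle count must be >= 0", call. = FALSE)
  r <- particles / protein_ug
  cls <- if (r > 3e10) "high"
         else if (r > 2e10) "indeterminate"
         else if (r >= 2e9) "low"
         else "below-low"
  structure(cls, ratio = r)
}

#' Normalize NTA size distributions and compare groups per bin
#'
#' Each sample's particle counts are divided by its total count so samples
#' with different particle yields are comparable; per 0.5 nm bin, a Welch
#' (unequal-variance) two-sample t-test compares the normalized counts
#' between the two groups, with BH adjustment across bins.  Bins where both
#' groups are constant are reported with t = 0 and p = 1 when means agree;
#' bins with zero counts in every sample carry no information and get
#' p = NA.
#'
#' @param dists list of `size_distribution` objects (see
#'   [read_size_distribution()]); distributions on different grids are cut
#'   to the common (intersection) grid.
#' @param groups factor/character vector aligned with `dists` with exactly
#'   2 levels, each with >= 2 samples.
#' @return An object of class `nta_comparison`: list with `bins` (left
#'   edges), `per_bin` (data.frame: size, mean per group, t, p_value,
#'   adj_p_value), `per_sample` (data.frame: sample_id, group, modal_size,
#'   total_count), `normalized` (bins x samples matrix, columns sum to 1).
#' @export
nta_normalize_and_test <- function(dists, groups) {
  if (length(dists) != length(groups))
    stop("groups must align with distributions", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)

  grids <- lapply(dists, function(d) d$size)
  common <- Reduce(intersect, grids)
  if (!length(common))
    stop("distributions share no common size bins", call. = FALSE)
  common <- sort(common)

  norm <- vapply(dists, function(d) {
    cnt <- d$count[match(common, d$size)]
    tot <- sum(d$count)
    if (tot <= 0) stop("distribution with zero total count", call. = FALSE)
    cnt / tot
  }, numeric(length(common)))
  ids <- vapply(dists, function(d) attr(d, "sample_id"), character(1))
  colnames(norm) <- ids

  g2 <- groups == levels(groups)[2]
  welch <- function(a, b) {
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
      if (mean(a) == mean(b)) return(c(t = 0, p = 1))
      return(c(t = Inf * sign(mean(a) - mean(b)), p = 0))
    }
    se2 <- va / length(a) + vb / length(b)
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                     vb^2 / (length(b)^2 * (length(b) - 1)))
    c(t = t, p = 2 * stats::pt(-abs(t), df))
  }
  res <- t(apply(norm, 1, function(row) {
    if (all(row == 0)) return(c(t = NA_real_, p = NA_real_))
    welch(row[!g2], row[g2])
  }))
  p_adj <- rep(NA_real_, nrow(res))
  ok <- !is.na(res[, "p"])
  p_adj[ok] <- adjust_bh(res[ok, "p"])

  per_sample <- data.frame(
    sample_id = ids,
    group = as.character(groups),
    modal_size = common[apply(norm, 2, which.max)],
    total_count = vapply(dists, function(d) sum(d$count), numeric(1)),
    stringsAsFactors = FALSE
  )
  per_bin <- data.frame(
    size = common,
    mean_group1 = rowMeans(norm[, !g2, drop = FALSE]),
    mean_group2 = rowMeans(norm[, g2, drop = FALSE]),
    t = res[, "t"],
    p_value = res[, "p"],
    adj_p_value = p_adj
  )
  structure(list(bins = common, per_bin = per_bin,
                 per_sample = per_sample, normalized = norm,
                 groups = groups),
            class = "nta_comparison")
}

#' @export
print.nta_comparison <- function(x, ...) {
  informative <- !is.na(x$per_bin$p_value)
  cat(sprintf("nta_comparison: %d bins (%d informative), %d + %d samples\n",
              length(x$bins), sum(informative), sum(x$groups == levels(x$groups)[1]),
              sum(x$groups == levels(x$groups)[2])))
  cat(sprintf("  bins with raw p < 0.05: %d; min adjusted p: %.3g\n",
              sum(x$per_bin$p_value < 0.05, na.rm = TRUE),
              suppressWarnings(min(x$per_bin$adj_p_value, na.rm = TRUE))))
  cat(sprintf("  modal sizes: %.1f-%.1f nm\n",
              min(x$per_sample$modal_size), max(x$per_sample$modal_size)))
  invisible(x)
}
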