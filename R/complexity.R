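#' Per-sample unique-protein counts
#'
#' The proteome-complexity statistic: for each sample, the number of
#' proteins identified in that sample and in no other sample of the cohort.
#' Uniqueness is defined cohort-wide, so the counts sum to the number of
#' proteins detected in exactly one sample.  Only the zero/non-zero pattern
#' matters; any monotone transform of the intensities leaves the counts
#' unchanged.
#'
#' @param m a [quant_matrix()].
#' @param level `"isoform"` (default: count isoform accessions) or `"gene"`
#'   (collapse detection to gene symbols first: a gene is detected in a
#'   sample if any of its isoforms is).
#' @return Named integer vector of unique-protein counts per sample.
#' @export
unique_protein_counts <- function(m, level = c("isoform", "gene")) {
  level <- match.arg(level)
  stopifnot(inherits(m, "quant_matrix"))
  if (!nrow(m$values)) stop("empty quantification matrix", call. = FALSE)
  det <- is_detected(m)
  if (level == "gene") {
    g <- factor(m$gene_symbols, levels = unique(m$gene_symbols))
    det <- rowsum(det + 0, g, reorder = FALSE) > 0
  }
  in_one <- rowSums(det) == 1L
  counts <- colSums(det[in_one, , drop = FALSE])
  stats::setNames(as.integer(counts), m$sample_ids)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test.  In exact mode the
#' permutation null of the rank sum is enumerated over all
#' \eqn{\binom{n+m}{n}} group assignments of the observed values, so the p
#' value is exact; the two-sided p doubles the smaller tail (each tail
#' includes the observed statistic) and is capped at 1.  With ties, or for
#' larger samples, a normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction is used.  `mode = "auto"` (default)
#' picks exact enumeration when `length(x) + length(y) <= 12` and there are
#' no ties.
#'
#' @param x,y numeric vectors of the two groups' values (e.g. unique-protein
#'   counts); both non-empty.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `W` (rank-sum statistic of `x`, i.e. the sum of the
#'   mid-ranks of `x` in the pooled sample), `U` (Mann-Whitney form),
#'   `p_value`, `mode` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  if (mode == "auto")
    mode <- if (n + m <= 12 && !ties) "exact" else "approx"

  if (mode == "exact") {
    # full enumeration of the permutation null of the rank sum,
    # conditional on the observed values (valid with or without ties)
    combos <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[combos], nrow = n))
    eps <- 1e-9
    lo <- mean(sums <= W + eps)
    hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n * (n + 1) / 2 + n * m / 2
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(W = W, U = U, p_value = p, mode = mode)
}

#' Association of proteome complexity with outcome
#'
#' Tests whether one side of a sample partition (by default the
#' poor-outcome side: stage-IV disease or death) carries more sample-unique
#' proteins, by a two-sided Wilcoxon rank-sum test on the per-sample counts
#' with no outlier removal.
#'
#' @param counts named per-sample counts from [unique_protein_counts()].
#' @param meta `sample_metadata` covering all count names.
#' @param contrast `"stage4_or_dead"` (default), `"stage4"`, `"dead"`,
#'   `"cancer"`, or a logical vector aligned with `counts` giving the
#'   "positive" side of the partition.
#' @param mode passed to [wilcoxon_rank_sum()].
#' @return An object of class `complexity_result`: list with `counts`,
#'   `group` (logical), `W`, `p_value`, `mode`, `direction` (which side has
#'   the larger median), `median_in`, `median_out`.
#' @export
complexity_association <- function(counts, meta,
                                   contrast = "stage4_or_dead",
                                   mode = "auto") {
  if (is.logical(contrast)) {
    if (length(contrast) != length(counts))
      stop("logical contrast must align with counts", call. = FALSE)
    grp <- contrast
  } else {
    meta <- meta[match(names(counts), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id))
      stop("samples absent from metadata", call. = FALSE)
    grp <- switch(contrast,
      stage4_or_dead = meta$stage == "4" | meta$vital_status == "dead",
      stage4 = meta$stage == "4",
      dead = meta$vital_status == "dead",
      cancer = meta$cancer_status == "YES",
      stop("unknown contrast '", contrast, "'", call. = FALSE))
  }
  if (!any(grp) || all(grp))
    stop("contrast partition has an empty side", call. = FALSE)
  wt <- wilcoxon_rank_sum(counts[grp], counts[!grp], mode = mode)
  med_in <- stats::median(counts[grp])
  med_out <- stats::median(counts[!grp])
  structure(list(
    counts = counts, group = grp, W = wt$W, p_value = wt$p_value,
    mode = wt$mode,
    direction = if (med_in > med_out) "higher_in_group"
                else if (med_in < med_out) "lower_in_group" else "equal",
    median_in = med_in, median_out = med_out
  ), class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf(
    "complexity_result: %d vs %d samples, W = %g, p = %.4g (%s)\n",
    sum(x$group), sum(!x$group), x$W, x$p_value, x$mode))
  cat(sprintf("  median unique proteins: %g (group) vs %g (rest); %s\n",
              x$median_in, x$median_out, x$direction))
  invisible(x)
}
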