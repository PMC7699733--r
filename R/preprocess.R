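#' Remove contaminant and reverse-database entries
#'
#' Drops rows whose protein id or gene symbol is in the supplied
#' contaminant list, together with rows flagged as reverse/contaminant at
#' read time.  An empty list with no flagged rows is a no-op.
#'
#' @param m a [quant_matrix()].
#' @param contaminants character vector of protein ids or gene symbols.
#' @param verbose log the number of removed rows (default TRUE).
#' @return The filtered `quant_matrix`.
#' @export
remove_contaminants <- function(m, contaminants = character(),
                                verbose = TRUE) {
  stopifnot(inherits(m, "quant_matrix"))
  drop <- m$flagged | m$protein_ids %in% contaminants |
    m$gene_symbols %in% contaminants
  if (verbose && any(drop))
    message("remove_contaminants: dropped ", sum(drop), " of ",
            length(drop), " rows")
  m[!drop, ]
}

#' log2(x + 1) transformation
#'
#' The standard variance-stabilizing transform for iBAQ intensities in this
#' pipeline: zeros (non-identifications) map to zero, so the detection
#' pattern is preserved.
#'
#' @param m a [quant_matrix()] of raw non-negative intensities.
#' @return A `quant_matrix` of log2(x+1) values.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (any(m$values < 0)) stop("negative intensities", call. = FALSE)
  m$values[] <- log2(m$values + 1)
  m
}

#' Quantile normalization across samples
#'
#' Forces every sample column to share the same marginal distribution: the
#' per-rank mean across samples.  Ranks within each column are preserved;
#' tied values receive the mean of the reference over their tied ranks (the
#' convention of the standard microarray implementation, which backs this
#' function).  Ranks are computed over all cells, zeros included, since the
#' matrix is dense and zeros carry the non-identification pattern.
#'
#' @param m a [quant_matrix()], typically log2-transformed, with >= 2
#'   samples.
#' @return The quantile-normalized `quant_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (ncol(m$values) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  m$values[] <- limma::normalizeQuantiles(m$values, ties = TRUE)
  m
}

#' Abundance filtering that optimizes the Gaussian shape of the data
#'
#' Low-abundance iBAQ values sit near the detection limit and distort the
#' otherwise approximately Gaussian pooled distribution of log2
#' intensities.  This filter scans a grid of candidate minimum-abundance
#' thresholds, scores the pooled retained non-zero values for normality at
#' each, and keeps values above the threshold with the best score (values
#' at or below it are set to 0, i.e. treated as not identified).  Ties are
#' broken toward the smallest threshold, so perfectly Gaussian input is
#' left unfiltered.
#'
#' @param m a [quant_matrix()] on the log2 scale.
#' @param grid ascending numeric vector of candidate thresholds (log2
#'   units).
#' @param metric normality score: `"anderson_darling"` (default; the score
#'   is minus the A-D statistic) or `"shapiro"` (the Shapiro-Wilk W).
#'   Scoring thins to at most `max_points` evenly spaced order statistics,
#'   for speed and because Shapiro-Wilk is capped at n = 5000.
#' @param max_points cap on values entering the normality score
#'   (default 5000).
#' @return A list: `quant` (filtered matrix), `threshold` (chosen value),
#'   `trace` (data.frame of threshold, score, n_retained).
#' @export
gaussian_abundance_filter <- function(m, grid,
                                      metric = c("anderson_darling",
                                                 "shapiro"),
                                      max_points = 5000) {
  stopifnot(inherits(m, "quant_matrix"))
  metric <- match.arg(metric)
  grid <- sort(unique(as.numeric(grid)))
  if (!length(grid)) stop("threshold grid is empty", call. = FALSE)
  pooled <- m$values[m$values > 0]

  score_at <- function(thr) {
    x <- pooled[pooled > thr]
    if (length(x) < 8 || stats::sd(x) == 0) return(-Inf)
    if (length(x) > max_points) {
      # deterministic quantile thinning: the score must not depend on the
      # RNG state, and Shapiro-Wilk is capped at n = 5000
      x <- sort(x)
      x <- x[unique(round(seq(1, length(x), length.out = max_points)))]
    }
    if (metric == "anderson_darling")
      -unname(nortest::ad.test(x)$statistic)
    else
      unname(stats::shapiro.test(x)$statistic)
  }

  scores <- vapply(grid, score_at, numeric(1))
  n_ret <- vapply(grid, function(t) sum(pooled > t), numeric(1))
  best <- grid[which.max(scores)]  # which.max takes the first (smallest) max
  m$values[m$values <= best] <- 0
  list(quant = m,
       threshold = best,
       trace = data.frame(threshold = grid, score = scores,
                          n_retained = n_ret))
}

#' Apply one of the three iBAQ preprocessing strategies
#'
#' The three strategies used on iBAQ output, in increasing order of
#' processing: (1) contaminant removal + log2(x+1); (2) additionally
#' quantile normalization; (3) additionally abundance filtering that
#' optimizes the Gaussian shape of the pooled values.
#'
#' @param m a [quant_matrix()] of raw iBAQ intensities.
#' @param strategy one of `"log_only"`, `"log_quantile"`,
#'   `"log_quantile_gaussfilter"`.
#' @param contaminants contaminant id/symbol list for
#'   [remove_contaminants()].
#' @param gauss_grid threshold grid for [gaussian_abundance_filter()]
#'   (default: 15 equal steps across the central nonzero range).
#' @param metric normality metric for the filter.
#' @return A list: `quant` (processed matrix), `strategy`, and for strategy
#'   3 the chosen `threshold` and score `trace`.
#' @export
preprocess <- function(m, strategy = c("log_quantile", "log_only",
                                       "log_quantile_gaussfilter"),
                       contaminants = character(), gauss_grid = NULL,
                       metric = "anderson_darling") {
  strategy <- match.arg(strategy)
  m <- log_transform(remove_contaminants(m, contaminants))
  out <- list(strategy = strategy)
  if (strategy != "log_only") m <- quantile_normalize(m)
  if (strategy == "log_quantile_gaussfilter") {
    if (is.null(gauss_grid)) {
      nz <- m$values[m$values > 0]
      gauss_grid <- seq(stats::quantile(nz, 0.005), stats::median(nz),
                        length.out = 15)
    }
    f <- gaussian_abundance_filter(m, gauss_grid, metric = metric)
    m <- f$quant
    out$threshold <- f$threshold
    out$trace <- f$trace
  }
  out$quant <- m
  out
}
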