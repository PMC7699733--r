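#' Build a design matrix for covariate-corrected group comparison
#'
#' Constructs the fixed-effects design for the per-protein linear model:
#' intercept, a cancer-status indicator, and indicator columns for the
#' requested covariates (e.g. gender and smoking).  Unused factor levels
#' are dropped; "unknown"/"NA" levels are retained as explicit levels so no
#' sample is discarded.  A rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param meta a `sample_metadata` data.frame.
#' @param group_var column defining the contrast (default
#'   `"cancer_status"`); its second factor level is the tested condition.
#' @param covariates character vector of metadata columns to correct for
#'   (default `c("gender", "smoking")`).
#' @return A numeric design matrix with rows in metadata order; the tested
#'   coefficient is attribute `"coef"`.
#' @export
build_design <- function(meta, group_var = "cancer_status",
                         covariates = c("gender", "smoking")) {
  for (v in c(group_var, covariates))
    if (!v %in% names(meta))
      stop("metadata has no column '", v, "'", call. = FALSE)
  df <- as.data.frame(meta)[, c(group_var, covariates), drop = FALSE]
  for (v in names(df)) df[[v]] <- droplevels(factor(df[[v]]))
  if (nlevels(df[[group_var]]) < 2)
    stop("group variable '", group_var, "' has fewer than 2 levels",
         call. = FALSE)
  X <- stats::model.matrix(stats::reformulate(c(group_var, covariates)),
                           data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(X, "coef") <- paste0(group_var, levels(df[[group_var]])[2])
  X
}

# moment estimate of the inverse-gamma (scaled inverse chi-square) variance
# prior from per-protein log residual variances: solves
# trigamma(d0/2) = var(e) - trigamma(d/2) by Newton on the trigamma scale
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(df_prior = 0, s2_prior = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  v <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) -
    mean(trigamma(df[ok] / 2))
  if (v <= 0) {
    # no excess spread: variances are exchangeable, infinite prior df
    return(list(df_prior = Inf, s2_prior = exp(ebar)))
  }
  y <- v
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  d0 <- 2 * x
  s2_0 <- exp(ebar + digamma(x) - log(x))
  list(df_prior = d0, s2_prior = s2_0)
}

#' Moderated differential-expression analysis of log-iBAQ values
#'
#' Fits, per protein, an ordinary least-squares linear model of log2(x+1)
#' intensity on cancer status plus covariates, then stabilizes the residual
#' variances by empirical-Bayes moderation: an inverse-gamma prior is
#' fitted to the observed residual-variance distribution by matching
#' moments of the log variances, and each protein's variance is shrunk to
#' the posterior mean
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' giving a moderated t statistic on \eqn{d_0 + d} degrees of freedom.
#' With `prior_df = 0` the moderated t reduces exactly to the ordinary
#' OLS t.  Zeros are data on the log2(x+1) scale (non-identification is
#' informative), but proteins with fewer than `min_detections` non-zero
#' values are flagged, excluded from the prior fit, and reported with
#' `low_detection = TRUE`.
#'
#' @param m a [quant_matrix()] on the log2 scale.
#' @param meta matching `sample_metadata`.
#' @param group_var,covariates passed to [build_design()].
#' @param min_detections minimum total non-zero values for a protein to
#'   enter the prior fit (default 3).
#' @param prior_df `NULL` (default) estimates the prior df from the data;
#'   a number forces it (0 = no moderation).
#' @return An object of class `de_result`: a data.frame with one row per
#'   protein (`protein_id`, `gene_symbol`, `log2fc`, `sigma2`, `t`,
#'   `p_value`, `adj_p_value`, `df_total`, `n_detected_group1`,
#'   `n_detected_group2`, `low_detection`) and attributes `df_prior`,
#'   `s2_prior`, `coef`.
#' @export
fit_moderated_model <- function(m, meta, group_var = "cancer_status",
                                covariates = c("gender", "smoking"),
                                min_detections = 3, prior_df = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  meta <- align_metadata(m, meta)
  grp <- droplevels(factor(meta[[group_var]]))
  if (any(table(grp) < 2))
    stop("need at least 2 samples per '", group_var, "' level",
         call. = FALSE)
  X <- build_design(meta, group_var, covariates)
  coef_name <- attr(X, "coef")
  j <- match(coef_name, colnames(X))

  Y <- m$values                      # proteins x samples
  n <- ncol(Y); p <- ncol(X)
  df_resid <- n - p
  if (df_resid < 1)
    stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi              # proteins x coefficients
  fitted <- B %*% t(X)
  res <- Y - fitted
  s2 <- rowSums(res^2) / df_resid
  unscaled_se2 <- XtXi[j, j]

  detected <- Y > 0
  g2 <- grp == levels(grp)[2]
  n_det1 <- rowSums(detected[, !g2, drop = FALSE])
  n_det2 <- rowSums(detected[, g2, drop = FALSE])
  low <- (n_det1 + n_det2) < min_detections

  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2[!low], rep(df_resid, sum(!low)))
  } else {
    pr <- list(df_prior = prior_df,
               s2_prior = if (prior_df > 0)
                 fit_variance_prior(s2[!low],
                                    rep(df_resid, sum(!low)))$s2_prior
               else NA_real_)
  }
  d0 <- pr$df_prior
  s2_post <- if (is.infinite(d0)) rep(pr$s2_prior, length(s2))
             else if (d0 == 0) s2
             else (d0 * pr$s2_prior + df_resid * s2) / (d0 + df_resid)
  df_total <- if (is.infinite(d0)) Inf else d0 + df_resid

  tstat <- B[, j] / sqrt(s2_post * unscaled_se2)
  # constant protein (zero variance, zero effect): no evidence either way
  tstat[s2_post == 0 & B[, j] == 0] <- 0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(
    protein_id = m$protein_ids,
    gene_symbol = m$gene_symbols,
    log2fc = unname(B[, j]),
    sigma2 = unname(s2),
    t = unname(tstat),
    p_value = unname(pval),
    adj_p_value = adjust_bh(unname(pval)),
    df_total = df_total,
    n_detected_group1 = unname(n_det1),
    n_detected_group2 = unname(n_det2),
    low_detection = unname(low),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("de_result", "data.frame"),
            df_prior = d0, s2_prior = pr$s2_prior, coef = coef_name,
            df_residual = df_resid)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d proteins, coefficient '%s'\n", nrow(x),
              attr(x, "coef")))
  cat(sprintf("  prior df %.2f, prior variance %.3f, residual df %d\n",
              attr(x, "df_prior"), attr(x, "s2_prior"),
              attr(x, "df_residual")))
  cat(sprintf("  raw p < 0.05: %d; BH-adjusted p < 0.05: %d\n",
              sum(x$p_value < 0.05), sum(x$adj_p_value < 0.05)))
  invisible(x)
}

#' @export
summary.de_result <- function(object, alpha = 0.05, ...) {
  df <- as.data.frame(object)
  class(df) <- "data.frame"
  sig <- df[df$adj_p_value < alpha, ]
  sig[order(sig$p_value), ]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving and capped at
#' 1.  Thin validated wrapper around the standard implementation.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values of the same length.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Volcano-plot table
#'
#' Plotting-ready long table of log2 fold change against -log10 p with
#' significance flags at raw and BH-adjusted p < alpha.
#'
#' @param de a `de_result`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with `protein_id`, `gene_symbol`, `log2fc`,
#'   `neg_log10_p`, `significant_raw`, `significant_adjusted`.
#' @export
volcano_table <- function(de, alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  data.frame(
    protein_id = de$protein_id,
    gene_symbol = de$gene_symbol,
    log2fc = de$log2fc,
    neg_log10_p = -log10(de$p_value),
    significant_raw = de$p_value < alpha,
    significant_adjusted = de$adj_p_value < alpha,
    stringsAsFactors = FALSE
  )
}
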