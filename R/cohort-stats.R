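#' Association test for a contingency table
#'
#' Group-association test used by the baseline table: Pearson chi-square
#' without continuity correction, or Fisher's exact test (two-sided by the
#' conventional rule: sum of probabilities of tables, with the observed
#' margins, no more probable than the observed one).  `"auto"` selects
#' Fisher when any expected count is below 5, chi-square otherwise.
#'
#' @param tab a 2 x c (or r x c) contingency matrix of non-negative counts.
#' @param method `"auto"` (default), `"chi2"` or `"fisher"`.
#' @return List with `statistic` (chi-square statistic; NA for Fisher),
#'   `p_value`, `test_used`.
#' @export
association_test <- function(tab, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: empty row or column", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chi2"
  if (method == "chi2") {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         test_used = "chi2")
  } else {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p_value = ft$p.value, test_used = "fisher")
  }
}

#' Baseline characteristics table
#'
#' Publication-style baseline table: for each clinical variable, level
#' counts with one-decimal percentages per group and in total, plus a
#' group-association p value per variable.  "NA"/"unknown" levels are shown
#' as display rows; by default they are excluded from the association test
#' (`na_policy = "exclude"`), which matches the arithmetic of case-control
#' tables where missingness is reported but not tested.
#'
#' @param meta a `sample_metadata` data.frame.
#' @param group_var grouping column (default `"cancer_status"`), >= 2
#'   levels.
#' @param variables character vector of metadata columns to tabulate
#'   (default: the standard clinical variables present in `meta`).
#' @param method test selection per [association_test()] (default
#'   `"auto"`).
#' @param na_policy `"exclude"` (default) or `"include"`: whether
#'   NA/unknown levels enter the association test.
#' @return An object of class `baseline_table`: list with `cells` (long
#'   data.frame: variable, level, counts and percentages per group and
#'   total) and `tests` (data.frame: variable, statistic, p_value,
#'   test_used).
#' @export
baseline_table <- function(meta, group_var = "cancer_status",
                           variables = NULL,
                           method = "auto", na_policy = c("exclude",
                                                          "include")) {
  na_policy <- match.arg(na_policy)
  if (is.null(variables))   # default: the standard variables that exist
    variables <- intersect(c("age_group", "smoking", "gender", "batch",
                             "stage", "vital_status"), names(meta))
  if (!group_var %in% names(meta))
    stop("variable '", group_var, "' absent from metadata", call. = FALSE)
  g <- droplevels(factor(meta[[group_var]]))
  if (nlevels(g) < 2)
    stop("group variable needs >= 2 levels", call. = FALSE)
  na_levels <- c("NA", "unknown")

  cells <- list(); tests <- list()
  for (v in variables) {
    if (!v %in% names(meta))
      stop("variable '", v, "' absent from metadata", call. = FALSE)
    x <- factor(meta[[v]])
    tab <- table(x, g)
    tot <- rowSums(tab)
    pct <- function(cnt, denom)
      if (denom > 0) 100 * cnt / denom else rep(0, length(cnt))
    cdf <- data.frame(variable = v, level = rownames(tab),
                      stringsAsFactors = FALSE)
    for (lev in levels(g)) {
      cdf[[paste0("n_", lev)]] <- as.integer(tab[, lev])
      cdf[[paste0("pct_", lev)]] <-
        round(pct(tab[, lev], sum(tab[, lev])), 1)
    }
    cdf$n_total <- as.integer(tot)
    cdf$pct_total <- round(pct(tot, sum(tab)), 1)
    cells[[v]] <- cdf

    ttab <- tab
    if (na_policy == "exclude")
      ttab <- tab[!rownames(tab) %in% na_levels, , drop = FALSE]
    ttab <- ttab[rowSums(ttab) > 0, colSums(ttab) > 0, drop = FALSE]
    tst <- if (nrow(ttab) >= 2 && ncol(ttab) >= 2)
      association_test(ttab, method)
    else list(statistic = NA_real_, p_value = NA_real_, test_used = "none")
    tests[[v]] <- data.frame(variable = v, statistic = tst$statistic,
                             p_value = tst$p_value,
                             test_used = tst$test_used,
                             stringsAsFactors = FALSE)
  }
  structure(list(cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 group_var = group_var),
            class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("baseline_table by", x$group_var, "\n")
  for (v in unique(x$cells$variable)) {
    t <- x$tests[x$tests$variable == v, ]
    cat(sprintf("%s (p = %s, %s)\n", v,
                ifelse(is.na(t$p_value), "-", format(round(t$p_value, 3),
                                                     nsmall = 3)),
                t$test_used))
    sub <- x$cells[x$cells$variable == v, -1]
    print(sub, row.names = FALSE)
  }
  invisible(x)
}
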