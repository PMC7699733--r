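#' Hypergeometric over-representation test
#'
#' For each category of a gene-set collection, tests whether the query set
#' (e.g. the proteins identified in one sample fraction) over-represents
#' the category relative to the universe, by the upper-tail hypergeometric
#' probability \eqn{P(X \ge k)} with \eqn{X \sim
#' \mathrm{Hypergeom}(N, K, n)}: universe size N, category size K (after
#' intersection with the universe), query size n, overlap k.
#'
#' @param query character vector of gene symbols; must be a subset of
#'   `universe`.
#' @param universe character vector of gene symbols (non-empty, de-duplicated
#'   internally).
#' @param sets a `gene_set_collection` (named list of symbol vectors).
#' @return data.frame (class `enrichment_result`) with one row per category:
#'   `category`, `N`, `K`, `n`, `k`, `p_value`, `adj_p_value`.
#' @export
hypergeom_enrichment <- function(query, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  N <- length(universe); n <- length(query)
  K <- vapply(sets, function(s) length(intersect(unique(s), universe)),
              numeric(1))
  k <- vapply(sets, function(s) length(intersect(unique(s), query)),
              numeric(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(data.frame(
    category = names(sets), N = N, K = as.integer(K), n = n,
    k = as.integer(k), p_value = p, adj_p_value = adjust_bh(p),
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("enrichment_result", "data.frame"))
}

#' Per-protein log2 ratios between two groups
#'
#' The regulation input of [category_regulation()]: for unpaired designs,
#' the difference of group means of log2(x+1) values per protein; for
#' paired designs, the mean of per-pair differences.
#'
#' @param m a [quant_matrix()] on the log2 scale.
#' @param meta matching `sample_metadata`.
#' @param group_var metadata column with exactly 2 levels after dropping
#'   unused ones; ratios are level 2 minus level 1.
#' @param pairs optional vector identifying pairs (same length as samples);
#'   when given, each pair must contain one sample of each group.
#' @return Named numeric vector of log2 ratios, one per gene symbol
#'   (isoforms collapsed by maximum before the ratio).
#' @export
group_log_ratios <- function(m, meta, group_var = "cancer_status",
                             pairs = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  meta <- align_metadata(m, meta)
  g <- droplevels(factor(meta[[group_var]]))
  if (nlevels(g) != 2)
    stop("'", group_var, "' must have exactly 2 levels", call. = FALSE)
  mg <- collapse_to_genes(m)
  # only identified genes (detected in >= 1 sample) carry a usable ratio,
  # and they define the enrichment query downstream
  mg <- mg[rowSums(is_detected(mg)) > 0, ]
  v <- mg$values
  if (is.null(pairs)) {
    ratios <- rowMeans(v[, g == levels(g)[2], drop = FALSE]) -
      rowMeans(v[, g == levels(g)[1], drop = FALSE])
  } else {
    pr <- factor(pairs)
    diffs <- vapply(levels(pr), function(p) {
      j <- which(pr == p)
      if (length(j) != 2 || length(unique(g[j])) != 2)
        stop("pair '", p, "' must contain one sample of each group",
             call. = FALSE)
      v[, j[g[j] == levels(g)[2]]] - v[, j[g[j] == levels(g)[1]]]
    }, numeric(nrow(v)))
    ratios <- rowMeans(diffs)
  }
  stats::setNames(ratios, mg$gene_symbols)
}

#' Complete functional regulation analysis of one comparison
#'
#' Joint enrichment and regulation test per annotation category.  A
#' category is called regulated ("up" or "down") only if all three filters
#' hold simultaneously: hypergeometric enrichment p < `alpha`, mean
#' regulation of its identified members more than `fc_threshold`-fold, and
#' a regulation p < `alpha` (two-sided one-sample t-test of member log2
#' ratios against 0; a Wilcoxon signed-rank alternative is available).
#' Everything else is "unregulated".
#'
#' @param ratios named per-gene log2 ratios (see [group_log_ratios()]), for
#'   genes identified in the comparison.
#' @param sets a `gene_set_collection`.
#' @param universe annotation universe for the enrichment test; default is
#'   the collection's documented universe (attribute `"universe"`) when
#'   present, otherwise the union of all set members; the identified genes
#'   are always included.
#' @param alpha significance level for both filters (default 0.05).
#' @param fc_threshold fold-change filter on the linear scale (default 2,
#'   i.e. |mean log2 ratio| > 1).
#' @param test `"t"` (default) or `"wilcoxon"` signed-rank.
#' @param min_members categories with fewer identified members are excluded
#'   with a message (default 2; the regulation test is undefined below it).
#' @return data.frame (class `cfra_result`) with one row per retained
#'   category: `category`, `n_identified`, `n_annotated`, `mean_log2_ratio`,
#'   `fold_change`, `p_regulation`, `p_enrichment`, `adj_p_regulation`,
#'   `adj_p_enrichment`, `direction`, `stars_regulation`,
#'   `stars_enrichment`.
#' @export
category_regulation <- function(ratios, sets, universe = NULL,
                                alpha = 0.05, fc_threshold = 2,
                                test = c("t", "wilcoxon"),
                                min_members = 2) {
  test <- match.arg(test)
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  identified <- names(ratios)
  if (is.null(universe))
    universe <- attr(sets, "universe") %||%
      unique(c(unlist(sets, use.names = FALSE), identified))
  universe <- unique(c(universe, identified))
  enr <- hypergeom_enrichment(identified, universe, sets)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), identified)
    n_annot <- length(intersect(unique(sets[[nm]]), universe))
    if (length(members) < min_members) {
      message("category '", nm, "' has ", length(members),
              " identified member(s); excluded")
      return(NULL)
    }
    x <- ratios[members]
    mean_lr <- mean(x)
    p_reg <- if (stats::sd(x) == 0) {
      if (mean_lr == 0) 1 else 0   # all members identical and shifted
    } else if (test == "t") {
      stats::t.test(x, mu = 0)$p.value
    } else {
      stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value
    }
    p_enr <- enr$p_value[enr$category == nm]
    fc <- 2^mean_lr
    passes <- p_enr < alpha && p_reg < alpha &&
      (fc > fc_threshold || fc < 1 / fc_threshold)
    direction <- if (!passes) "unregulated"
                 else if (mean_lr > 0) "up" else "down"
    data.frame(category = nm, n_identified = length(members),
               n_annotated = n_annot, mean_log2_ratio = mean_lr,
               fold_change = fc, p_regulation = p_reg,
               p_enrichment = p_enr, direction = direction,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(category = character(), n_identified = integer(),
                       n_annotated = integer(), mean_log2_ratio = numeric(),
                       fold_change = numeric(), p_regulation = numeric(),
                       p_enrichment = numeric(), direction = character(),
                       stringsAsFactors = FALSE)
  rows$adj_p_regulation <- adjust_bh(rows$p_regulation)
  rows$adj_p_enrichment <- adjust_bh(rows$p_enrichment)
  rows$stars_regulation <- p_stars(rows$p_regulation)
  rows$stars_enrichment <- p_stars(rows$p_enrichment)
  structure(rows, class = c("cfra_result", "data.frame"),
            alpha = alpha, fc_threshold = fc_threshold, test = test)
}

#' Cross-comparison functional-regulation table
#'
#' Combines per-comparison [category_regulation()] results into one long
#' table for heatmap rendering: category x comparison with direction, member
#' counts and significance stars.  Categories are retained if called
#' regulated in at least one comparison; a category absent from a
#' comparison appears as "unregulated" with NA counts.
#'
#' @param results named list comparison_name -> `cfra_result`.
#' @return data.frame with columns `category`, `comparison`, `direction`,
#'   `n_identified`, `n_annotated`, `mean_log2_ratio`, `p_regulation`,
#'   `p_enrichment`, `stars_regulation`, `stars_enrichment`.
#' @export
cfra_matrix <- function(results) {
  if (!length(results)) stop("no comparisons given", call. = FALSE)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("comparisons must be named", call. = FALSE)
  keep <- unique(unlist(lapply(results, function(r)
    r$category[r$direction != "unregulated"])))
  if (!length(keep))
    return(data.frame(category = character(), comparison = character(),
                      direction = character(), n_identified = integer(),
                      n_annotated = integer(), mean_log2_ratio = numeric(),
                      p_regulation = numeric(), p_enrichment = numeric(),
                      stars_regulation = character(),
                      stars_enrichment = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(names(results), function(cmp) {
    r <- results[[cmp]]
    idx <- match(keep, r$category)
    data.frame(
      category = keep,
      comparison = cmp,
      direction = ifelse(is.na(idx), "unregulated", r$direction[idx]),
      n_identified = r$n_identified[idx],
      n_annotated = r$n_annotated[idx],
      mean_log2_ratio = r$mean_log2_ratio[idx],
      p_regulation = r$p_regulation[idx],
      p_enrichment = r$p_enrichment[idx],
      stars_regulation = ifelse(is.na(idx), "", r$stars_regulation[idx]),
      stars_enrichment = ifelse(is.na(idx), "", r$stars_enrichment[idx]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
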