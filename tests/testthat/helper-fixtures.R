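# shared fixture builders, constructed in code

toy_quant <- function(values, ids = NULL, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  ids <- ids %||% sprintf("P%d", seq_len(nrow(values)))
  quant_matrix(values,
               protein_ids = ids,
               gene_symbols = genes %||% ids,
               sample_ids = samples %||% sprintf("s%d", seq_len(ncol(values))))
}

toy_metadata <- function(n_control = 3, n_cancer = 3) {
  n <- n_control + n_cancer
  as_sample_metadata(data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    cancer_status = rep(c("NO", "YES"), c(n_control, n_cancer)),
    gender = rep_len(c("F", "M"), n),
    smoking = rep_len(c("current", "former", "non"), n),
    batch = rep_len(1:2, n),
    stage = rep(c("no", "NA"), c(n_control, n_cancer)),
    vital_status = "alive",
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sided Wilcoxon p by full enumeration of group assignments,
# independent of the package's implementation path
brute_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  sums <- colSums(matrix(r[utils::combn(length(pooled), n)], nrow = n))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
}

# hypergeometric upper-tail p by enumerating overlap probabilities with
# dhyper-free factorial arithmetic
brute_hyper_p <- function(N, K, n, k) {
  prob_k <- function(i) choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(vapply(k:min(K, n), prob_k, numeric(1)))
}

# Fisher two-sided p for a 2x2 table by enumeration over all tables with the
# observed margins (sum of table probabilities <= observed probability)
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1), numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
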