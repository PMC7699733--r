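#' Simulation configuration for synthetic BAL-EV cohorts
#'
#' Defines the statistical structure of a simulated case-control iBAQ
#' cohort: a log-normal base abundance distribution per gene, intensity-
#' dependent detection (zero inflation via a logistic link on log2
#' abundance, matching the missingness pattern of label-free MS), planted
#' differentially abundant proteins, planted sample-unique proteins in
#' poor-outcome (stage-IV/deceased) samples, and per-sample nuisance
#' offsets for gender, smoking and batch.
#'
#' Defaults emulate the scale of a 24-sample small-EV cohort: about 3000
#' genes, about 2.4 isoforms per gene, unimodal log2 intensities, and an
#' overall identification rate around 85%.
#'
#' @param n_control,n_cancer samples per group (default 12 + 12).
#' @param n_genes number of simulated genes (default 3000).
#' @param isoforms_per_gene_mean mean isoforms per gene; per-gene counts are
#'   1 + Poisson(mean - 1) (default 2.4, giving ~7200 isoform rows).
#' @param mu_log2,sigma_log2 mean and SD of the per-gene base log2
#'   abundance (default 25 and 3, an iBAQ-like dynamic range).
#' @param noise_sd per-measurement SD on the log2 scale (default 1).
#' @param detect_mid,detect_prob_slope logistic detection model: a value at
#'   log2 abundance `a` is identified with probability
#'   `plogis(detect_prob_slope * (a - detect_mid))` (defaults 19 and 2:
#'   abundances two SD above the midpoint are essentially always seen,
#'   low-abundance proteins drop out).
#' @param n_de number of planted differentially abundant genes (default 100).
#' @param de_log2fc planted log2 fold change, added in the cancer group
#'   (default 2; half the planted genes are shifted up, half down).
#' @param de_min_quantile planted DE genes are drawn from genes whose base
#'   abundance is above this quantile (default 0.35), since a planted marker
#'   below the detection limit carries no recoverable signal.
#' @param frac_stage4 fraction of cancer samples labelled stage-IV and
#'   deceased (default 5/12, the poor-outcome rate of a 12-case arm with 5
#'   deaths).
#' @param extra_unique_mean Poisson mean of planted sample-unique proteins
#'   added to every stage-IV/deceased sample (default 0; the complexity
#'   analyses plant 40).
#' @param batch_sd,covariate_effect_sd SD of per-sample batch and
#'   gender/smoking offsets on the log2 scale (defaults 0.3 and 0.2).
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly. Sub-generators derive child seeds from it deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 12, n_cancer = 12, n_genes = 3000,
                       isoforms_per_gene_mean = 2.4,
                       mu_log2 = 25, sigma_log2 = 3, noise_sd = 1,
                       detect_mid = 19, detect_prob_slope = 2,
                       n_de = 100, de_log2fc = 2, de_min_quantile = 0.35,
                       frac_stage4 = 5 / 12, extra_unique_mean = 0,
                       batch_sd = 0.3, covariate_effect_sd = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_control", "n_cancer", "n_genes", "n_de")
  for (f in counts)
    if (cfg[[f]] < 0) stop("config error: ", f, " must be >= 0",
                           call. = FALSE)
  if (n_control + n_cancer < 2)
    stop("config error: need at least 2 samples in total", call. = FALSE)
  if (frac_stage4 < 0 || frac_stage4 > 1)
    stop("config error: frac_stage4 must be in [0, 1]", call. = FALSE)
  if (isoforms_per_gene_mean < 1)
    stop("config error: isoforms_per_gene_mean must be >= 1", call. = FALSE)
  if (extra_unique_mean < 0 || batch_sd < 0 || covariate_effect_sd < 0 ||
      noise_sd < 0)
    stop("config error: dispersion/rate parameters must be >= 0",
         call. = FALSE)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic case-control iBAQ cohort
#'
#' Draws a full isoform-level quantification matrix, sample metadata and a
#' ground-truth record under the model of [sim_config()]:
#' \enumerate{
#'   \item per gene, a base log2 abundance ~ Normal(`mu_log2`,
#'     `sigma_log2`); isoforms of a gene scatter around it (minor isoforms
#'     are attenuated);
#'   \item per measurement, log2 intensity = base + planted DE shift (cancer
#'     only) + sample offset (gender/smoking/batch) + Normal(0, `noise_sd`)
#'     noise;
#'   \item detection is Bernoulli with probability
#'     `plogis(slope * (log2 intensity - detect_mid))`; undetected cells are
#'     recorded as 0;
#'   \item every stage-IV/deceased sample receives Poisson(`extra_unique_mean`)
#'     extra proteins detected only in that sample (the tumor-heterogeneity
#'     mechanism behind per-sample proteome complexity).
#' }
#'
#' @param config a [sim_config()].
#' @return A list with elements `quant` ([quant_matrix()] of raw-scale iBAQ
#'   values), `metadata` (a `sample_metadata` data.frame), and `truth` (list
#'   with `de_genes`, `de_direction`, `unique_proteins` (per sample),
#'   `sample_groups`, `poor_outcome` ids).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_control + config$n_cancer
  sample_ids <- sprintf("S%02d", seq_len(n))
  cancer <- rep(c("NO", "YES"), c(config$n_control, config$n_cancer))

  # covariates: roughly balanced, assigned independently of status
  gender <- sample(c("F", "M"), n, replace = TRUE)
  smoking <- sample(c("current", "former", "non", "unknown"), n,
                    replace = TRUE, prob = c(0.3, 0.35, 0.15, 0.2))
  batch <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.6, 0.1))

  # poor outcome: stage IV and deceased, cancer arm only
  n_stage4 <- round(config$frac_stage4 * config$n_cancer)
  cancer_idx <- which(cancer == "YES")
  stage4_idx <- if (n_stage4 > 0) sort(sample(cancer_idx, n_stage4))
                else integer()
  stage <- ifelse(cancer == "NO", "no", "NA")
  stage[stage4_idx] <- "4"
  vital <- rep("alive", n)
  vital[stage4_idx] <- "dead"

  meta <- as_sample_metadata(data.frame(
    sample_id = sample_ids, cancer_status = cancer, gender = gender,
    smoking = smoking, batch = batch, stage = stage, vital_status = vital,
    stringsAsFactors = FALSE))

  # gene-level base abundances and isoform layout
  base <- stats::rnorm(config$n_genes, config$mu_log2, config$sigma_log2)
  iso_n <- 1L + stats::rpois(config$n_genes,
                             max(config$isoforms_per_gene_mean - 1, 0))
  gene_of_iso <- rep(seq_len(config$n_genes), iso_n)
  n_iso <- length(gene_of_iso)
  # minor isoforms sit below the dominant one
  iso_rank <- unlist(lapply(iso_n, seq_len), use.names = FALSE)
  iso_base <- base[gene_of_iso] - (iso_rank - 1L) *
    stats::rexp(n_iso, rate = 1 / 1.5)

  # planted differential genes: drawn above the low-abundance tail, where a
  # shift is quantifiable at all
  eligible <- which(base >= stats::quantile(base, config$de_min_quantile))
  n_de <- min(config$n_de, length(eligible))
  de_genes <- if (n_de > 0) sort(sample(eligible, n_de)) else integer()
  de_dir <- rep_len(c(1, -1), n_de)
  shift_gene <- numeric(config$n_genes)
  shift_gene[de_genes] <- de_dir * config$de_log2fc

  # per-sample nuisance offsets
  gender_eff <- stats::rnorm(2, 0, config$covariate_effect_sd)
  smoke_eff <- stats::rnorm(4, 0, config$covariate_effect_sd)
  batch_eff <- stats::rnorm(3, 0, config$batch_sd)
  offset <- gender_eff[match(gender, c("F", "M"))] +
    smoke_eff[match(smoking, c("current", "former", "non", "unknown"))] +
    batch_eff[batch]

  is_cancer <- as.numeric(cancer == "YES")
  mu <- outer(iso_base, offset, `+`) +
    outer(shift_gene[gene_of_iso], is_cancer)
  log2_int <- mu + matrix(stats::rnorm(n_iso * n, 0, config$noise_sd),
                          n_iso, n)
  p_detect <- stats::plogis(config$detect_prob_slope *
                              (log2_int - config$detect_mid))
  detected <- matrix(stats::runif(n_iso * n), n_iso, n) < p_detect
  vals <- ifelse(detected, 2^log2_int, 0)

  gene_names <- sprintf("GENE%04d", seq_len(config$n_genes))
  protein_ids <- sprintf("%s-ISO%d", gene_names[gene_of_iso], iso_rank)

  # planted sample-unique proteins in poor-outcome samples
  uniq_ids <- character(); uniq_genes <- character()
  uniq_by_sample <- stats::setNames(vector("list", n), sample_ids)
  if (config$extra_unique_mean > 0 && length(stage4_idx)) {
    counts <- stats::rpois(length(stage4_idx), config$extra_unique_mean)
    k <- 0L
    extra_rows <- list()
    for (j in seq_along(stage4_idx)) {
      s <- stage4_idx[j]
      if (counts[j] == 0) { uniq_by_sample[[s]] <- character(); next }
      ids <- sprintf("UNIQ-%s-%03d", sample_ids[s], seq_len(counts[j]))
      lv <- stats::rnorm(counts[j], config$detect_mid + 2, 1)
      block <- matrix(0, counts[j], n)
      block[, s] <- 2^lv
      extra_rows[[length(extra_rows) + 1L]] <- block
      uniq_by_sample[[s]] <- ids
      uniq_ids <- c(uniq_ids, ids)
      k <- k + counts[j]
    }
    if (length(extra_rows)) {
      vals <- rbind(vals, do.call(rbind, extra_rows))
      protein_ids <- c(protein_ids, uniq_ids)
      uniq_genes <- uniq_ids   # unique proteins get their own symbols
      gene_names_all <- c(gene_names[gene_of_iso], uniq_genes)
    } else gene_names_all <- gene_names[gene_of_iso]
  } else gene_names_all <- gene_names[gene_of_iso]

  quant <- quant_matrix(vals, protein_ids = protein_ids,
                        gene_symbols = gene_names_all,
                        sample_ids = sample_ids)
  truth <- list(
    de_genes = gene_names[de_genes],
    de_direction = stats::setNames(de_dir, gene_names[de_genes]),
    unique_proteins = uniq_by_sample,
    sample_groups = stats::setNames(cancer, sample_ids),
    poor_outcome = sample_ids[stage4_idx],
    base_log2 = stats::setNames(base, gene_names)
  )
  list(quant = quant, metadata = meta, truth = truth)
}

#' Generate marker panels and spike them into a cohort matrix
#'
#' Creates an EV-marker panel (tetraspanin-like placeholders), a non-EV
#' contamination panel, and ten immune/stromal population panels, and
#' appends one isoform row per marker to the quantification matrix at
#' configurable abundance so purity scoring and population scoring are
#' exercisable on synthetic data.
#'
#' @param quant a [quant_matrix()] to spike into.
#' @param metadata matching `sample_metadata` (used for group-dependent
#'   shifts).
#' @param ev_level,pop_level log2 abundance at which EV and population
#'   markers are spiked (defaults 26 and 24: well above the detection
#'   limit).
#' @param contamination_level log2 abundance of non-EV markers; 0 leaves
#'   them entirely unidentified (default 0).
#' @param pop_shift named list population -> log2 shift added in the cancer
#'   group (default none), used to plant population-score differences.
#' @param noise_sd per-cell log2 noise of the spiked rows (default 0.5).
#' @param n_populations number of population panels (default 10),
#'   markers_per_population markers each (default 3).
#' @param markers_per_population markers per population panel.
#' @param seed integer seed.
#' @return List with `quant` (matrix with spiked rows appended), `panel`
#'   (a `marker_panel`), and `truth` (spiked levels per marker).
#' @export
simulate_marker_panels <- function(quant, metadata,
                                   ev_level = 26, pop_level = 24,
                                   contamination_level = 0,
                                   pop_shift = list(),
                                   noise_sd = 0.5,
                                   n_populations = 10,
                                   markers_per_population = 3,
                                   seed = 1L) {
  stopifnot(inherits(quant, "quant_matrix"))
  set.seed(child_seed(seed, 2L))
  n <- length(quant$sample_ids)
  pop_names <- c("T cells", "CD8 T cells", "Cytotoxic lymphocytes",
                 "B lineage", "NK cells", "Monocytic lineage",
                 "Myeloid dendritic cells", "Neutrophils",
                 "Endothelial cells", "Fibroblasts")[seq_len(n_populations)]
  ev_markers <- c("EVM-CD63", "EVM-CD9", "EVM-CD81", "EVM-TSG101",
                  "EVM-PDCD6IP", "EVM-SDCBP", "EVM-FLOT1", "EVM-ANXA2")
  nonev_markers <- c("CNT-BCL2", "CNT-GOLGA2", "CNT-NUP98", "CNT-CANX")
  pops <- stats::setNames(lapply(seq_along(pop_names), function(i)
    sprintf("POP%02d-M%d", i, seq_len(markers_per_population))), pop_names)
  panel <- marker_panel(ev = ev_markers, non_ev = nonev_markers,
                        populations = pops)

  is_cancer <- metadata$cancer_status[match(quant$sample_ids,
                                            metadata$sample_id)] == "YES"
  spike_row <- function(level, shift = 0) {
    lv <- level + shift * is_cancer +
      stats::rnorm(n, 0, noise_sd)
    out <- 2^lv
    out[level + shift * is_cancer == 0] <- 0
    out
  }
  markers <- c(ev_markers, nonev_markers, unlist(pops, use.names = FALSE))
  levels_of <- c(stats::setNames(rep(ev_level, length(ev_markers)),
                                 ev_markers),
                 stats::setNames(rep(contamination_level,
                                     length(nonev_markers)), nonev_markers))
  for (p in pop_names)
    levels_of[pops[[p]]] <- pop_level
  shifts <- stats::setNames(numeric(length(markers)), markers)
  for (p in names(pop_shift))
    shifts[pops[[p]]] <- pop_shift[[p]]

  rows <- t(vapply(markers, function(mk) {
    if (levels_of[[mk]] == 0 && shifts[[mk]] == 0) rep(0, n)
    else spike_row(levels_of[[mk]], shifts[[mk]])
  }, numeric(n)))

  quant2 <- quant_matrix(rbind(quant$values, rows),
                         protein_ids = c(quant$protein_ids, markers),
                         gene_symbols = c(quant$gene_symbols, markers),
                         sample_ids = quant$sample_ids,
                         flagged = c(quant$flagged,
                                     rep(FALSE, length(markers))))
  list(quant = quant2, panel = panel,
       truth = list(levels = levels_of, shifts = shifts))
}

#' Generate synthetic nanoparticle-tracking size distributions
#'
#' Particle diameters are drawn from a log-normal size law whose density
#' mode sits at `mode_nm` (i.e. `meanlog = log(mode_nm) + sdlog^2`), then
#' binned on the uniform 0.5 nm grid.  This reproduces the unimodal,
#' right-skewed size profile of small-EV preparations with a peak around
#' 100 nm.
#'
#' @param n_samples number of distributions to generate.
#' @param mode_nm modal particle diameter in nm (default 100).
#' @param spread `sdlog` of the log-normal (default 0.35).
#' @param n_particles particles tracked per sample (default 50000).
#' @param range_nm grid limits in nm (default c(40, 400)).
#' @param seed integer seed.
#' @return A list of `size_distribution` objects named `NTA01`, `NTA02`, ...
#' @export
simulate_size_distributions <- function(n_samples, mode_nm = 100,
                                        spread = 0.35, n_particles = 50000,
                                        range_nm = c(40, 400), seed = 1L) {
  if (mode_nm <= 0) stop("config error: mode_nm must be > 0", call. = FALSE)
  if (n_particles <= 0)
    stop("config error: n_particles must be > 0", call. = FALSE)
  set.seed(child_seed(seed, 3L))
  meanlog <- log(mode_nm) + spread^2   # mode of a log-normal density
  edges <- seq(range_nm[1], range_nm[2], by = 0.5)
  lapply(seq_len(n_samples), function(i) {
    d <- stats::rlnorm(n_particles, meanlog, spread)
    d <- d[d >= range_nm[1] & d < range_nm[2]]
    counts <- tabulate(findInterval(d, edges), nbins = length(edges) - 1L)
    as_size_distribution(edges[-length(edges)], counts,
                         sprintf("NTA%02d", i))
  })
}

#' Generate a synthetic gene-set collection with planted regulation
#'
#' Builds an annotation collection over a universe larger than the measured
#' proteome (as curated pathway databases are): each background category
#' draws members from measured and annotation-only genes alike.  One
#' optional planted category is composed entirely of well-measured genes
#' whose abundance is shifted between groups, for recovery tests of the
#' functional-regulation analysis.
#'
#' @param measured_genes character vector of gene symbols present in the
#'   cohort matrix.
#' @param n_background number of background categories (default 50).
#' @param set_size members per category (default 30).
#' @param n_unmeasured annotation-only genes added to the universe
#'   (default equal to `length(measured_genes)`).
#' @param planted_members symbols forming a planted category, or `NULL`.
#' @param seed integer seed.
#' @return A `gene_set_collection`; the planted category (if any) is named
#'   `"PLANTED"`.
#' @export
simulate_gene_sets <- function(measured_genes, n_background = 50,
                               set_size = 30,
                               n_unmeasured = length(measured_genes),
                               planted_members = NULL, seed = 1L) {
  set.seed(child_seed(seed, 4L))
  universe <- c(measured_genes,
                sprintf("ANNOT%05d", seq_len(n_unmeasured)))
  sets <- lapply(seq_len(n_background), function(i)
    structure(sample(universe, set_size),
              description = sprintf("background category %d", i)))
  names(sets) <- sprintf("CAT%03d", seq_len(n_background))
  if (!is.null(planted_members))
    sets$PLANTED <- structure(unique(planted_members),
                              description = "planted regulated category")
  # the full annotation universe (measured + annotation-only genes) rides
  # along, the way a curated collection documents its gene space
  structure(sets, class = "gene_set_collection", universe = universe)
}
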