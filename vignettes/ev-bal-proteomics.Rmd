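---
title: "Methods: proteomic and particle-based characterization of BAL extracellular vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic and particle-based characterization of BAL extracellular vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evbal)
```

# Scope and data model

`evbal` implements the downstream computational analysis of a label-free
(iBAQ) proteomic characterization of small extracellular vesicles (sEVs)
isolated from bronchoalveolar lavage (BAL) in a case-control design:
preprocessing of protein-level intensities, covariate-corrected moderated
differential expression, a per-sample proteome-complexity statistic, an
MS-based EV purity assessment, comparison of nanoparticle-tracking (NTA)
size distributions, a joint enrichment-plus-regulation analysis of
annotation categories, marker-based immune/stromal population scores, and a
baseline cohort table.

The central container is the `quant_matrix`: a dense proteins-by-samples
matrix of non-negative iBAQ intensities. A value of 0 encodes "not
identified in that sample" — throughout the package zeros are *data*
(informative non-identification), never missing values, and no imputation is
performed. Protein rows carry isoform accessions plus aligned gene symbols;
gene-level operations collapse isoforms by the per-sample maximum, on the
reasoning that the iBAQ of the dominant isoform dominates the gene signal
(summation is available via `collapse_to_genes(method = "sum")`).

# The synthetic cohort generator

Raw mass-spectrometry data are not required anywhere: `simulate_cohort()`
draws cohorts with the statistical structure the analyses assume, together
with a ground-truth record that downstream recovery tests consume.

The generative model, per gene $g$ and sample $j$:

$$
y_{gj} = \beta_g + \delta_g\,[\text{cancer}_j] + u_j + \varepsilon_{gj},
\qquad \varepsilon_{gj} \sim N(0, \sigma^2),
$$

on the log2 scale, where $\beta_g \sim N(\mu, \tau^2)$ is the gene's base
abundance, $\delta_g$ is a planted differential shift (0 for null genes),
and $u_j$ collects per-sample gender/smoking/batch offsets. A measurement is
*identified* with probability $\mathrm{logit}^{-1}\{s\,(y_{gj} - m)\}$ and
recorded as $2^{y_{gj}}$, otherwise as 0. This logistic-detection mechanism
reproduces the intensity-dependent missingness of label-free MS:
high-abundance proteins are essentially always identified while
low-abundance proteins drop out stochastically.

Default parameters and why:

* `n_control = n_cancer = 12`, `n_genes = 3000`,
  `isoforms_per_gene_mean = 2.4` — the scale of the motivating cohort
  (24 samples, ~3000 genes, ~7200–7500 isoforms).
* `mu_log2 = 25`, `sigma_log2 = 3` — an iBAQ-like dynamic range of roughly
  5–6 orders of magnitude.
* `noise_sd = 1` — per-measurement log2 SD; the value the differential
  recovery analyses are specified at.
* `detect_mid = 19`, `detect_prob_slope = 2` — calibrated so that overall
  identification is ~85–88% and missingness concentrates in the
  low-abundance tail. A shallower curve spreads isolated dropout zeros
  across well-quantified proteins; on the log2(x+1) scale, where zeros are
  data, a single dropout at abundance ~25 inflates a protein's residual
  variance by two orders of magnitude, a pattern not seen in real
  label-free data for abundant proteins.
* `n_de = 100`, `de_log2fc = 2` (half up, half down),
  `de_min_quantile = 0.35` — planted markers are drawn above the low-
  abundance tail because a shift planted below the detection limit carries
  no recoverable signal in any pipeline and would only dilute sensitivity
  estimates with undetectable instances.
* `frac_stage4 = 5/12` — five of twelve cancer cases are stage-IV and
  deceased, the poor-outcome rate of the motivating cohort.
* `extra_unique_mean` — Poisson mean of proteins detected *only* in one
  designated poor-outcome sample; the tumor-heterogeneity mechanism behind
  the proteome-complexity signal. Default 0 (null); the complexity analyses
  plant 40.

All sub-generators (`simulate_marker_panels()`,
`simulate_size_distributions()`, `simulate_gene_sets()`) derive child seeds
deterministically from one global seed, so any stage reproduces in
isolation and a fixed seed gives byte-identical outputs end to end.

What the generator does **not** emulate: correlated protein modules
(co-regulation), peptide-level effects, retention-time or batch-specific
intensity drifts beyond additive offsets, heavy-tailed contaminant spikes,
or realistic sequence content. Passing recovery tests therefore demonstrate
that the statistical machinery is correct under the stated model, not that
the pipeline is robust to every artifact of real MS data.

# Preprocessing strategies

Three nested strategies mirror common practice for iBAQ output:

1. `log_only` — contaminant/reverse removal, then $\log_2(x+1)$ (zeros stay
   zero, the detection pattern is preserved);
2. `log_quantile` — additionally quantile normalization;
3. `log_quantile_gaussfilter` — additionally an abundance filter chosen to
   optimize the Gaussian shape of the pooled values.

Quantile normalization forces every sample column onto the per-rank mean
distribution; ties receive the mean of the reference over their tied ranks
(the convention of the dominant microarray implementation, which backs the
function). Ranks are computed over all cells, zeros included, since the
matrix is dense. One consequence worth knowing: the "all sorted columns
identical" identity is exact only outside the tied zero block — each
column's zeros form one tie group whose averaged reference value depends on
that column's zero count. On tie-free data the identity is exact and the
operation is idempotent to numerical tolerance.

The Gaussian abundance filter scans an ascending grid of candidate minimum-
abundance thresholds and retains values above the candidate that maximizes
a normality score of the pooled retained non-zero values. The default score
is the negative Anderson–Darling statistic (Shapiro–Wilk available), with
zeros excluded — they encode missingness, not abundance. For speed, and
because Shapiro–Wilk caps at n = 5000, scoring thins large pools to at most
5000 evenly spaced order statistics, a deterministic reduction that leaves
the score independent of RNG state. Ties in the score break toward the
smallest threshold, so already-Gaussian input is left unfiltered. On data
with a planted low-abundance spike the chosen threshold lands within one
grid step of the true cutoff.

# Covariate-corrected moderated differential expression

`fit_moderated_model()` fits, per protein, an ordinary least-squares model
of log2(x+1) intensity on cancer status plus covariates (default gender and
smoking; "unknown"/"NA" are retained as explicit factor levels so no sample
is dropped), then moderates the residual variances with an empirical-Bayes
inverse-gamma prior. The prior is fitted by matching moments of the log
residual variances ($e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$; the excess
of $\mathrm{Var}(e)$ over $\psi'(d/2)$ determines the prior degrees of
freedom $d_0$ via the trigamma inverse, and $\bar e$ determines the prior
variance $s_0^2$). Each protein's variance is shrunk to the posterior mean

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

giving a moderated t on $d_0 + d$ degrees of freedom. Forcing `prior_df = 0`
recovers the ordinary OLS t exactly — the limiting case the tests pin down.
No intensity-trend or robust variants are offered. Proteins with fewer than
`min_detections` (default 3) non-zero values are flagged, excluded from the
prior fit, and still reported. Multiple testing uses Benjamini–Hochberg
(`adjust_bh()`).

Degenerate inputs: a rank-deficient design is an error naming the collinear
columns; an all-constant protein (zero variance, zero effect) reports t = 0,
p = 1 rather than 0/0.

# Proteome complexity

`unique_protein_counts()` counts, per sample, the proteins identified in
that sample and in no other sample of the cohort (cohort-wide uniqueness;
the counts sum to the number of proteins seen in exactly one sample). Only
the zero/non-zero pattern matters, so the statistic is invariant to any
monotone intensity transform. The default level is the isoform; gene-level
collapse is available because published per-sample counts do not always say
which level they use.

`wilcoxon_rank_sum()` compares the counts between outcome groups. For
$n+m \le 12$ without ties the permutation null of the rank sum is fully
enumerated (exact p); otherwise a normal approximation with mid-ranks,
tie-corrected variance and continuity correction is used. Two-sided p values
double the smaller tail (observed value included in both tails) and cap at
1 — stated explicitly because tie and rounding conventions differ between
implementations. The default outcome partition is "stage-IV disease or
death versus the rest", with stage-only, death-only and cancer-status
contrasts exposed, since the published contrast wording admits more than
one reading.

Type-I calibration is assessed under the complete null (no planted unique
excess *and* no planted differential genes), because planted differential
shifts also shift detection rates in the cancer arm and the poor-outcome
samples are a subset of it.

# EV quality

*Marker heatmap scaling.* "Ranked from 0 to 1" is implemented as per-marker
min–max scaling of group-averaged iBAQ across columns, matching a display
of continuous shades; a mid-rank alternative `(rank-1)/(n-1)` sits behind
`method = "rank"`. Constant rows carry no ordering information and map to
0.5. Note the scaling is per row across columns: rescaling one column's raw
intensities moves row minima/maxima, so full invariance does not hold — only
the ordering of the other columns within rows where the rescaled column was
neither min nor max.

*Purity scores.* The EV score is the mean scaled value over EV-flagged
markers (tetraspanins and other frequently reported exosome proteins), the
contamination score the mean over non-EV organelle markers (BCL2
mitochondrial, GOLGA2 Golgi, NUP98 nuclear, CANX endoplasmic reticulum). A
clean vesicle preparation shows high EV and low contamination scores
relative to reference columns. The shipped panels
(`inst/extdata/default_panels.yaml`) are data, not code: the canonical
marker list is not fixed in the literature, so the defaults are editable.

*Particle-to-protein ratio.* Ratios above 3×10^10 particles/µg indicate
high vesicular purity, 2×10^9–2×10^10 low purity; the literature scheme
leaves (2×10^10, 3×10^10] unclassified, which the function reports as
"indeterminate", and anything below 2×10^9 as "below-low", making the
classifier total on positive ratios.

*NTA comparison.* Each sample's 0.5 nm-binned particle counts are divided
by the sample total (so samples with different particle yields are
comparable), then each bin is tested with a Welch unequal-variance t-test
between groups — the unequal-variance form chosen deliberately since
normalized counts need not share variances across groups. BH-adjusted p
values are reported alongside the raw ones (the raw values are what a
no-difference claim rests on). Bins with zero counts in every sample carry
no information and return p = NA; bins constant within both groups with
equal means return t = 0, p = 1. Input on a finer uniform grid is rebinned
to 0.5 nm by summing; distributions on different grids are cut to the
common bins.

# Complete functional regulation analysis

`hypergeom_enrichment()` computes the upper-tail hypergeometric probability
$P(X \ge k)$ for each category: universe size $N$, category size $K$ (after
intersection with the universe), query size $n$, overlap $k$.
`category_regulation()` then calls a category regulated only if three
filters hold simultaneously: enrichment p < α, mean member regulation more
than `fc_threshold`-fold (default 2), and regulation p < α (default 0.05).
The regulation test is a two-sided one-sample t-test of member log2 ratios
against 0; a Wilcoxon signed-rank alternative is available because the
original description does not pin the test down. Ratios for unpaired
comparisons are differences of group means of log2(x+1) per gene
(per-pair differences averaged for paired designs), restricted to genes
identified in at least one sample.

The enrichment universe is the annotation collection's gene space united
with the identified genes. This choice is what makes identification
enrichment testable at all: curated collections annotate more genes than
any one cohort quantifies, so "category members are identified more often
than expected" is a statement about the cohort against the annotation
space. `simulate_gene_sets()` mirrors this by building its background
categories over measured plus annotation-only genes and documenting the
full universe as an attribute. No multiple-testing correction is applied to
the retention filters (they operate on raw p, as the original scheme does);
BH-adjusted values are reported alongside. Categories with fewer than 2
identified members have no defined regulation test and are excluded with a
message. `cfra_matrix()` assembles per-comparison results into a long
category × comparison table, keeping categories called in at least one
comparison; a category absent from a comparison renders as unregulated with
NA counts. Significance stars follow the usual convention (* < 0.05,
** < 0.01, *** < 0.001).

# Population scores

`population_scores()` estimates the relative abundance of eight immune and
two stromal cell populations as the arithmetic mean of the log2 abundances
of each population's marker proteins present in the matrix — the
marker-mean convention of expression-based microenvironment scoring,
transplanted to protein iBAQ. Markers never identified in the cohort are
excluded from the mean rather than imputed as zero (zeros encode
non-identification); a population with no detected marker is reported as
undefined with `n_markers_detected = 0`. Scores are abundance scores, not
proportions: they shift equivariantly under global log2 offsets and support
between-sample comparison per population, never composition claims.
`score_group_summary()` adds per-group means and average-linkage
hierarchical clustering of samples on the Euclidean distance between score
profiles. The default computes on the quantile-normalized log scale; the
original analysis does not state which scale it used.

# Baseline cohort table

`baseline_table()` tabulates level counts with one-decimal percentages per
group and overall, plus a per-variable association test.
`association_test()` offers the uncorrected Pearson chi-square and the
two-sided Fisher exact test (conventional rule: sum of probabilities of
fixed-margin tables no more probable than the observed), with `"auto"`
selecting Fisher when any expected count is below 5. Both are exposed
because published baseline tables of this kind demonstrably mix
conventions: in the motivating cohort the vital-status p (0.012) matches
the uncorrected chi-square while the gender p (0.100) matches Fisher on
the 2×2 after excluding the one unknown-gender case. NA/unknown levels are
shown as display rows and excluded from the tests by default
(`na_policy = "exclude"`), which is the arithmetic that reproduces those
values. The shipped `cohort_metadata_synthetic.csv` carries the cohort's
per-variable margins; the joint assignment of covariates to individual
samples is synthetic (not printed anywhere), with deaths co-assigned to the
stage-IV cases.

# Problem sizes used in the tests

The test suite and the acceptance script run the recovery analyses at the
study's sample size (12 + 12) with 3000 genes: 100 seeds for differential
and category recovery and for complexity power, 500 seeds for the
complexity type-I error, 200 replicate cohorts for the NTA null
false-positive rate. These sizes give Monte-Carlo standard errors of ~1–3
percentage points on the reported rates. Unit tests use smaller cohorts
(60–800 genes) where the property under test does not depend on scale.

# Known limitations

* The moderated-variance prior uses the method of moments on log residual
  variances; very small cohorts (residual df < 4) make the trigamma
  inversion noisy.
* Quantile normalization treats zeros as ordinary low values within one tie
  block; with very unequal per-sample identification rates this leaks small
  positive values into non-identified cells of the emptier columns.
* The exact Wilcoxon path enumerates all group assignments and is meant for
  the small per-sample-count comparisons it serves (n + m ≤ ~14); larger
  inputs use the tie-corrected normal approximation automatically.
* Purity and population scores depend entirely on the supplied marker
  panels; the shipped defaults are plausible, editable placeholders, not a
  canonical list.
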