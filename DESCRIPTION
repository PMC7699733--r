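Package: evbal
Title: Proteomic and Particle-Based Characterization of Bronchoalveolar
    Lavage Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of label-free (iBAQ) proteomics of
    extracellular vesicles isolated from bronchoalveolar lavage, in a
    case-control design. Implements three iBAQ preprocessing strategies
    (log2(x+1), quantile normalization, Gaussian abundance filtering),
    covariate-corrected moderated differential expression, per-sample
    proteome-complexity statistics with exact Wilcoxon rank-sum tests,
    rank-scaled extracellular-vesicle marker purity assessment,
    particle-to-protein purity classification, nanoparticle-tracking
    size-distribution comparison, joint enrichment-plus-regulation
    ("complete functional regulation") analysis of gene-set collections,
    marker-based immune and stromal population scores, and baseline
    cohort characteristic tables. A synthetic-cohort generator with known
    ground truth supports end-to-end testing without raw mass-spectrometry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    nortest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
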