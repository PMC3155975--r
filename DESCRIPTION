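Package: ceindex
Title: Consistent Expression Indices Across Analogous Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised extraction of consistent principal components (CPCs)
    from multiple analogous gene-expression cohorts and their distillation into
    sign-weighted consistent expression indices (CEIs). Per-cohort processing
    filters probes by coefficient of variation on the anti-log scale, performs
    PCA, selects the number of components by a Gaussian-residual BIC, and
    distills each component to its significantly correlated features. Components
    are pooled across cohorts, compared with a Jaccard-cosine dissimilarity, and
    clustered by average linkage; genes representative in at least two members
    of a cluster form the CPC gene set. Varimax factor analysis of merged
    per-cohort z-scores yields thresholded least-squares coefficients whose
    signs define each CEI. Scoring of independent cohorts and association of
    scores with binary treatment response (trapezoidal ROC/AUC, Wilcoxon
    rank-sum) and survival (Kaplan-Meier, median-split Cox, log-rank) are
    included, along with a synthetic-cohort generator with planted shared and
    cohort-private latent factors and linked outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
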