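Package: gutbalance
Title: Gut Microbiome and Plasma Metabolome Balance Indices for
    Neurocognitive Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to derive and evaluate log-ratio balance indices that
    link gut microbiome composition and the plasma metabolome to
    neurocognitive performance in small longitudinal cohorts.  Implements
    composite neuropsychological (NPZ-6) scoring and group classification,
    exact rank-sum inference for tiny unbalanced groups, LEfSe-style
    discriminant taxon analysis, sparse PLS-DA metabolite selection with a
    rank-sum filter, PCA-based shortlisting, log-ratio-of-geometric-means
    indices frozen at baseline and tracked over time, Spearman/BH
    association testing, Bray-Curtis PERMANOVA, hypergeometric metabolite
    set enrichment, and a fully synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    vegan,
    jsonlite,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
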