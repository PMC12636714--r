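Package: thermoshift
Title: Organ-Resolved Aging Metabolome Analysis with Cardiolipin Remodeling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for organ-resolved aging metabolomics studies of
    old versus young mice: ingestion and validation of post-annotation intensity
    tables, cross-platform duplicate resolution, presence filtering, minimum-based
    imputation, median normalization and log/Pareto scaling, nonparametric
    differential abundance with Benjamini-Hochberg false discovery control and
    two-way age-by-sex ANOVA, cardiolipin maturity classification with a
    nascent-CL/PG cardiolipin-synthase proxy, acyl chain-length remodeling
    summaries for neutral lipids, fatty acids and acylcarnitines, named metabolite
    panels and product/precursor stress ratios, virtual peptide digestion into
    residue regulation profiles, and a fully parameterised synthetic multi-organ
    atlas generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Lipidomics, DifferentialExpression, Preprocessing
RoxygenNote: 7.3.3
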