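Package: sigrev
Title: Transcriptomic Signature Reversal Screening and Drug Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds tumor-versus-normal differential expression signatures
    with empirical-Bayes moderated t-statistics, screens drug perturbation
    libraries for signature reversal using Kolmogorov-Smirnov connectivity
    scores and genome-wide weighted Spearman (GWC) correlation with
    permutation significance, performs preranked and single-sample gene set
    enrichment analysis with PCA embedding for cross-dataset clustering, and
    quantifies drug combination synergy by the median-effect (Chou-Talalay)
    combination index. Ships synthetic-data generators with planted ground
    truth so every stage of the pipeline can be validated end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
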