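Package: crossorgan
Title: Cross-Organ Surrogate Biomarker Discovery from Paired Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for discovering peripheral (spleen) surrogate
    transcriptome markers of central nervous system disease state in paired
    two-organ, two-strain case/control expression studies, as used in
    progressive experimental autoimmune encephalomyelitis (EAE) mouse models.
    Provides per-organ, per-strain differential screening (fold change and
    Student t test with volcano classification), k-means clustering of
    condition log-ratio profiles with Davies-Bouldin model selection,
    principal component analysis with factor-loading ranking, and
    correlation-based pattern matching of spleen genes against brain PC1
    sample scores, together with a calibrated synthetic-study generator with
    known ground truth for end-to-end validation, readers for tab-delimited
    and GEO series-matrix expression data, and a config-driven orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
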