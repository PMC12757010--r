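Package: kadaif
Title: Subspace-Ordination Isolation Forests for Compositional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anomaly detection for high-dimensional, sparse, compositional
    abundance tables such as microbiome taxon profiles. Generalizes the
    isolation-forest algorithm by splitting each tree node on a randomly
    chosen ordination axis (PCoA of Bray-Curtis distances, or PCA) of a
    random feature subset, so that splits reflect community-level structure
    rather than single taxa. Includes a zero-inflated log-normal community
    simulator with mislabeling, mixture-contamination and taxon-inflation
    anomaly-injection scenarios, pooled ROC-AUC benchmarking, and a
    sliding-window mode for real-time dysbiosis scoring of longitudinal
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
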