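Package: tnmapper
Title: Topological Network Modules in Perturbed Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects topological network modules (TNMs) in perturbed
    protein-interaction networks measured by affinity purification and
    mass spectrometry (AP-MS). Spectral counts are converted to distributed
    normalized spectral abundance factors (dNSAF), per-contrast
    perturbation statistics (log2 fold change, Z score, FDR) are computed
    with a Poisson/Wald contrast and filtered with control-specificity and
    depletion or Z-score rules, and the filtered protein feature matrix is
    fed to a Mapper-style topological engine (correlation metrics, metric
    SVD or neighborhood-graph lenses, overlapping covers with resolution
    and gain, per-bin single-linkage clustering). Raising the cover
    resolution fragments the network into TNMs, which are superimposed
    back onto the base network. Includes a ground-truth-labelled synthetic
    AP-MS generator for deletion and drug perturbation designs, baseline
    clustering comparisons, and GraphML/JSON/TSV import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    mclust,
    cluster,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
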