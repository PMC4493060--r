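Package: netreconfig
Title: Task-Related Reconfiguration of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying how functional brain-network topology
    reorganises under increasing task demand. Builds subject-by-condition
    networks from ROI time series (Pearson correlation with Bonferroni
    edge thresholding), computes global and nodal graph parameters
    (degree, clustering, path length, local/global/nodal efficiency,
    wiring cost, modularity), small-worldness against degree-preserving
    rewired null models, and targeted-attack robustness, and runs
    within-subject repeated-measures statistics with post-hoc and FDR
    correction. Includes a modular factor-model simulator that generates
    synthetic multi-condition cohorts with condition-dependent coupling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
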