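Package: ahrnet
Title: AHR Interactor Network Assembly, Expression Consensus and Survival
    Screening in ccRCC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds an aryl hydrocarbon receptor (AHR)-centred
    protein-protein interaction network from multi-database edge exports
    under per-source confidence filters, calls differential-expression
    direction by a k-of-n consensus over two-group log2 fold changes,
    screens each gene for survival association in a clear cell renal cell
    carcinoma cohort (median split, log-rank test, Cox hazard ratio,
    Benjamini-Hochberg FDR), and selects genes whose disease expression
    direction concords with the expression level associated with worse
    survival. Includes seed-deterministic generators for synthetic network,
    expression and survival inputs with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
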