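Package: tcmrules
Title: Constitution Classification from Clinical Records by Partitioned
    FP-Growth Association Rule Mining
Version: 0.1.0
Authors@R:
    person("The tcmrules authors", role = c("aut", "cre"),
           email = "maintainer@tcmrules.invalid")
Description: Mines association rules from tokenized clinical records with a
    partitioned (shard-and-merge) FP-growth algorithm, learns a two-stage rule
    base linking symptoms to the nine traditional Chinese medicine (TCM)
    constitutions and constitutions to health-conditioning regimens, classifies
    new symptom sets into constitutions, and evaluates the classifier with
    precision, recall and F1 under stratified k-fold cross-validation. Includes
    a seeded generator of synthetic clinical-record corpora with planted
    symptom-constitution-regimen structure, shared-symptom noise and stop-word
    contamination, so the whole pipeline is testable without access to
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
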