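Package: famturn
Title: Gene Family Turnover on Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of gene family (hierarchical orthologous group) gain and
    loss on time-calibrated species trees. Implements Wagner parsimony mapping
    of gains, duplications and losses onto branches; maximum-likelihood fitting
    of linear birth-death models of family size with one or more branch rate
    classes, tied or free gain/loss rates, and a +/-1 annotation-error channel
    with likelihood-based error estimation; simulation-based likelihood-ratio
    tests and per-family/per-branch acceleration tests with multiple-testing
    correction; term enrichment of expanding and contracting families by
    Fisher's exact test; and phylogenetically corrected correlation of turnover
    with genome size via independent contrasts. Includes an exact birth-death
    simulator for generating complete synthetic studies along a bundled
    18-taxon laurasiatherian chronogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
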