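Package: drtsim
Title: Monte Carlo Simulation of RNA-Based Protocells with Direct RNA
    Template Peptide Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based Monte Carlo simulator of RNA-based protocells on
    a two-dimensional lattice. RNA genes encode functional dipeptides through
    the direct RNA template (DRT) mechanism: RNAs bind specific amino acids at
    characteristic five-nucleotide sites and promote their ligation into
    dipeptides. The model couples template-directed RNA replication with
    mutation, vesicle membrane dynamics (amphiphile exchange, division,
    fusion, breaking), selective permeation, and monomer chemistry under an
    exact material-conservation ledger. Shipped scenario presets reproduce
    the spread of protocells carrying a membrane-stabilizing-peptide gene,
    its de novo emergence, cooperation with a nucleotide synthetase ribozyme,
    and the functional takeover of the ribozyme by a peptide gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
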