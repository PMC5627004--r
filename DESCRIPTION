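Package: sipcall
Title: DNA Stable-Isotope Probing Simulation, Fold-Enrichment Calling,
    Hydrocarbon Oxidation Kinetics and Functional-Gene Read Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-centric and DNA stable-isotope probing (SIP)
    analysis of hydrocarbon-degrading microbial communities. Simulates
    microbial communities, CsCl buoyant-density gradients, fraction-resolved
    16S rRNA amplicon tables, diverged metagenomic reads and closed-vessel
    substrate-depletion time series with known ground truth; models DNA
    buoyant density as a function of G+C content and 13C atom fraction and
    calls 13C-assimilating taxa with a two-control fold-enrichment rule;
    estimates zero-order oxidation rates by linear regression, partitions
    volatile substrates between liquid and headspace by Henry's law, and
    balances biomass-coupled oxidation reactions (C5H7O2N convention);
    recruits reads to curated functional-gene reference sets with an
    end-gap-free affine alignment under joint identity and length
    thresholds, quantifies genes as RPKM, assigns taxonomy by a minimal
    lowest-common-ancestor rule and summarises multi-gene prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
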