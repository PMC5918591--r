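Package: divscan
Title: Selection-Signature and QTL Scans for Divergent Selection Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical machinery for short-term divergent-selection
    experiments genotyped on a medium-density SNP chip: single-SNP FLK and
    haplotype-based hapFLK selection-signature scans against a drift kinship
    null, a local haplotype-cluster hidden Markov model fitted by EM on
    unphased genotypes, Bayes C-pi multi-marker QTL mapping with Bayes
    factors, neutral Wright-Fisher forward simulations for allele-frequency
    trajectory tests, linkage-disequilibrium and enrichment summaries, and a
    breeding-scheme simulator emulating two-line divergent sib selection that
    provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
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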