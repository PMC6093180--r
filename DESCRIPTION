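Package: acceptorscape
Title: 3' Splice-Site Architecture and RNA Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the 3' splice-site architecture of
    groups of internal exons (for example splicing-factor-activated,
    -repressed and control sets): AG-dinucleotide exclusion zone (AGEZ)
    lengths, polypyrimidine-tract composition metrics, PWM-based
    branch-point candidate scoring, and RNA single-strandedness profiles
    computed as constrained Boltzmann partition-function "probability
    unpaired" (PU) values averaged over 10/20/30-nt symmetric sequence
    contexts. Includes dinucleotide-preserving shuffled flank controls
    (Euler-path construction), positional nucleotide composition with
    Bayesian confidence intervals, k-mer enrichment scans, the group
    statistics used in splice-site studies (Wilcoxon-Mann-Whitney,
    correlation, chi-squared, Benjamini-Hochberg FDR), and a synthetic
    exon-group generator that plants every analysed feature so the full
    pipeline can be validated against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
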