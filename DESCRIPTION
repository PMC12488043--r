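Package: pipecho
Title: FDR-Controlled Peptide-Identity Propagation for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-identity propagation (match-between-runs) for
    data-dependent label-free quantification with rigorous control of the
    false-discovery rate among propagated identifications. Donor peptides
    from a target-decoy database search are matched to MS1 peak traces in
    acceptor runs at both a predicted and a deliberately randomized
    retention time; the resulting hybrid competition (target vs. decoy,
    predicted vs. randomized anchor) yields an estimate of the combined
    peak-matching and peptide-identification error that is controlled
    run by run. Also provides the two-proteome entrapment protocol for
    estimating the realized false-discovery proportion of any propagation
    tool, a spike-in fold-change window sensitivity analysis, and a
    synthetic LC-MS experiment generator with ground-truth labels for
    validating both.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
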