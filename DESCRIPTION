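Package: ccdtime
Title: Cumulative Cell Divisions as a Timescale for Adaptive Laboratory Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial-passage adaptive laboratory evolution
    (ALE) experiments on the cumulative-cell-divisions (CCD) timescale.
    Provides the passage-record calculus (per-flask generations and divisions,
    cumulative totals, OD600-to-cell-count calibration), log-linear growth-rate
    estimation, a trailing-window stabilization rule, and condition-level
    summary tables; a lineage-structured simulator of serial-dilution evolution
    in which beneficial mutations arise in proportion to cell divisions, with a
    mutagen rate multiplier; a short-read resequencing toolkit (read curation,
    iterative mismatch-capped ungapped alignment, nucleotide-resolution pileup
    profiles, threshold-based SNP calling, and spike-in false-negative
    estimation); and mutation classification (synonymous, nonsynonymous,
    intergenic) with cross-strain overlap partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
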