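Package: paleomapr
Title: Identifying Genuine Ancient DNA Reads in Shotgun Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating ancient DNA (aDNA) in shotgun sequencing
    experiments. Models the read-length-dependent maximum edit distance used by
    seed-and-extend aligners and emits platform-specific alignment parameter
    recommendations; classifies high-quality endogenous hits and filters
    contamination against a second reference genome by strict and best-hit
    criteria; profiles position-specific nucleotide misincorporation, indel and
    soft-clip rates at read termini to detect post-mortem cytosine deamination;
    selectively trims likely-damaged 5' bases and reports recovery gains by
    mismatch class; estimates sample-to-reference divergence from damage-robust
    substitution classes stratified by base quality; and simulates
    platform-specific sequencing reads (indel-dominated single-molecule
    profiles and substitution-dominated short-read profiles) with truth
    alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
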