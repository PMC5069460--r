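Package: hmoglyco
Title: Label-Free Glycoprofiling of Human Milk Oligosaccharide Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for structure-resolved quantification of human milk
    oligosaccharide (HMO) pools before and after bacterial fermentation or
    enzymatic digestion, from LC-MS feature tables. Features are annotated by
    accurate-mass monosaccharide composition within a ppm tolerance and by
    retention-time matching against a structure library; co-eluting isomers
    are grouped; runs are aligned into a structure-by-sample abundance matrix
    against an uninoculated external standard; and percent consumption or
    digestion is computed per structure, per glycan class and in total, with
    replicate statistics across fermentation time points. Also included are a
    microplate growth-curve classifier, glycan-array replicate summarization
    with shared-motif extraction over IUPAC-condensed glycan strings, and
    seeded simulators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
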