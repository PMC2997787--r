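Package: pcrscreen
Title: Discriminating PCR Misincorporation Errors from Genuine Genetic Variation
Version: 0.1.0
Authors@R:
    person("Kerry", "Albright", email = "kalbright@example.org", role = c("aut", "cre"))
Description: Tools for estimating method-specific PCR/cloning misincorporation
    error rates from multiple alignments of clone sequences, modelling the
    expected distribution of errors per clone with a binomial probability mass
    function, testing observed deviation histograms against that model, and
    calibrating thresholds above which a clone sequence should be accepted as a
    genuine allele rather than a polymerase artefact. Includes majority-rule
    consensus building and deviation calling, transition/transversion and
    base-pair-class error spectra, UPGMA grouping of clones into putative
    alleles, windowed chimera detection, sliding-window variability profiles,
    and a branching-process PCR simulator that produces synthetic clone sets
    with full ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
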