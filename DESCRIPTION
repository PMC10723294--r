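Package: sweepconv
Title: Two-Locus Forward Simulation of Selective Sweeps Softened by
    Allelic Gene Conversion
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact two-locus diploid Wright-Fisher forward simulation of
    selective sweeps in which allelic gene conversion can copy the
    beneficial allele onto new genetic backgrounds, producing
    "pseudo-soft" sweeps that mimic soft sweeps despite a single
    mutational origin.  Ships piecewise demographic histories for human,
    Drosophila melanogaster and Arabidopsis thaliana populations
    (constant-size and multi-epoch models transcribed from the stdpopsim
    catalog), Q-rescaling of models and selection/conversion parameters,
    restart conditioning on non-loss of the beneficial allele,
    hard/pseudo-soft outcome classification in population and sample,
    scenario-grid experiment runners, and an independent individual-based
    validation oracle with diffusion-theory fixation-probability checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
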