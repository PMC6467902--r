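Package: plumrates
Title: Sex-Specific Rates and Directions of Plumage Colour Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing rates and directions of plumage colour
    evolution on phylogenies. Maps device colour measurements to avian
    cone-catch values and projects them into the tetrahedral colourspace of
    the violet-sensitive visual system; infers branch-specific rates of
    multivariate Brownian trait evolution by reversible-jump MCMC and
    summarises the posterior as mean rate phenograms with clade and branch
    shift probabilities; computes the TRES (trait rate equal splits)
    species-level rate metric; compares male and female rates with
    phylogenetic reduced major axis regression under a maximum likelihood
    estimate of Pagel's lambda; and tests for directional bias of fast
    colour divergence with a randomisation null over 20-degree segments of
    colour space. Includes a synthetic-data generator (birth-death trees,
    clade/branch rate regimes, colour datasets with known ground truth) so
    the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
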