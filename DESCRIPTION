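Package: bdtree
Title: Linear Birth-Death Processes, Tree Simulation and Likelihood-Free
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact distributions and simulators for linear birth-death
    processes in phylogenetics and population genetics. Provides the
    Yule and birth-death population-size laws, event-driven simulation
    of complete trees, pruning to reconstructed (ultrametric) trees and
    direct sampling of reconstructed trees from the conditional
    split-time order-statistic law; a marked-Poisson immigration model
    with family-size statistics including the negative-binomial
    population size and the Ewens sampling formula; Fisher's
    multiple-sampling variance for species counts in consecutive
    samples; a birth-death cell-population simulator with infinite-sites
    mutation and site-frequency-spectrum summaries; and approximate
    Bayesian computation by rejection, random-forest marginal posteriors
    and distributional-random-forest joint posteriors with permutation
    variable importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    jsonlite
Config/testthat/edition: 3
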