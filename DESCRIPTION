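Package: diauxloop
Title: Closed-Loop Refinement of Hybrid Regulatory-Metabolic Models of the
    Yeast Diauxic Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and iteratively improving hybrid models of
    the Saccharomyces cerevisiae diauxic shift. A two-slice dynamic Bayesian
    network with linear-Gaussian conditionals (the signalling layer) is coupled
    to a stoichiometric metabolic model solved by dynamic flux balance analysis,
    with metabolite-to-gene rules closing the loop. The package provides
    ensemble structure inference over Edmonds maximum spanning arborescences,
    active and discriminative experiment design driven by forward/backward
    state divergence, growth-curve phenotyping of deletant strains, greedy
    validated model revision against observed post-shift growth rates, and a
    virtual laboratory that generates ground-truth models, replicate growth
    and glucose curves, and expression time courses so that complete
    design-execute-refine cycles can be run and evaluated in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Collate: 
    'diauxloop-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'phenotype.R'
    'utils.R'
    'rules.R'
    'model-core.R'
    'dbn.R'
    'lp.R'
    'fba.R'
    'dfba.R'
    'simulate.R'
    'adarev.R'
    'virtual-lab.R'
    'elsa.R'
    'smoother.R'
    'design.R'
    'cycle.R'
    'model-io.R'
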