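Package: cpmhgf
Title: Comparing Change-Point and Hierarchical Gaussian Filter Models of
    Adaptive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-comparison toolkit for two hierarchical
    Bayesian perceptual filters used in studies of human learning in changing
    environments: the two-level Hierarchical Gaussian Filter (HGF) and a
    variational Change Point Model (CPM). Provides generators for switching
    and diffusive stimulus environments, sequential belief-update filters with
    per-trial free energy and surprise, a Gaussian response model, surprise
    minimisation for perceptual-parameter training, behavioural model
    inversion by Bayesian inference with a Laplace approximation (BI-LA) and
    by maximum likelihood with BIC, random-effects group Bayesian model
    selection, and the recovery, coverage, confusion-matrix and
    trajectory-correlation diagnostics used to compare the two inversion
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
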