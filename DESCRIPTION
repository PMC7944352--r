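Package: apml
Title: Algorithmic-Probability Machine Learning on Discrete Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machine learning with algorithmic-probability estimators on
    non-differentiable, discrete model spaces. Provides conditional Coding
    Theorem Method (CTM) tables compiled from enumerated generative systems,
    unconditional plus coarse and strong conditional Block Decomposition
    Method (BDM) approximations to conditional Kolmogorov complexity,
    algorithmic-probability centroid classifiers with greedy block training,
    complexity-ordered parameter search, algorithmic sample weighting and
    regularization, and simulators for elementary cellular automata and
    Kauffman NK Boolean gene-regulatory-network models that generate every
    experimental corpus used by the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
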