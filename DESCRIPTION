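Package: seoptim
Title: Surrogate Modeling and Multi-Objective Optimization of Somatic
    Embryogenesis Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models plant tissue-culture responses (callogenesis rate,
    embryogenesis rate and somatic embryo count) as functions of three plant
    growth regulator concentrations (2,4-D, kinetin, sodium nitroprusside)
    with epsilon-insensitive support vector regression (RBF kernel, SMO dual
    solver) and a Levenberg-Marquardt-trained multilayer perceptron; compares
    the two model families by R-squared, RMSE and MAE; ranks input importance
    by a remove-and-retrain variable sensitivity ratio; and searches the
    concentration space with an elitist NSGA-II whose Pareto front is reduced
    to a single recommendation by an ideal-point distance rule. Ships the
    published 4x4x4 factorial chrysanthemum dataset as a fixture together
    with a replicate-level reconstruction that matches the printed
    mean/standard-error summaries exactly, and a synthetic Gaussian-peak
    response-surface generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
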