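Package: avbci
Title: Bayesian Causal Inference Modelling of Audiovisual Spatial
    Localisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates, fits and compares forced-fusion and Bayesian
    causal inference observer models of audiovisual spatial localisation
    under prestimulus attention and poststimulus report cueing.  Provides
    a synthetic-data generator for factorial ventriloquist designs and
    multivoxel response patterns with known audiovisual encoding weights,
    simulation-based multinomial likelihood fitting across a 2 x 3
    factorial model space, random-effects Bayesian model selection with
    protected exceedance probabilities, behavioural and neural
    audiovisual weight indices, cross-validated support-vector-regression
    decoding, and exhaustive sign-permutation inference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
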