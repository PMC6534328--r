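Package: cosens
Title: Clusters-of-Samples Models of Ensemble Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Observer models for how people summarise a stream of
    one-dimensional samples into Mode and Mean estimates. Implements the
    Clusters-of-Samples (CoS) observer, in which samples are grouped by a
    distance-dependent Chinese Restaurant Process and only cluster centroids
    and relative weights are retained, together with a subjective-weighting
    baseline, a Dirichlet-process-mixture ideal observer, and
    moment-regression baselines. Includes a generator for the beta-mixture
    stimulus designs used in ensemble-perception experiments, per-subject
    maximum-likelihood fitting with AICc model comparison, group-level
    random-effects Bayesian model selection with protected exceedance
    probabilities, and parameter- and model-recovery pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    withr,
    lhs,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
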