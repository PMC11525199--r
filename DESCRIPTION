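Package: clonefate
Title: Clonal Dynamics and Mutant Selection in Squamous Epithelium
Version: 0.1.0
Authors@R:
    person("Clonefate", "Developers", email = "clonefate@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of clonal dynamics in stratified
    squamous epithelium. Implements the single-progenitor fate-bias model of
    clone growth (exact event-driven stochastic simulation and a truncated
    master-equation solution), two-dimensional clone-size distributions and
    their comparison (Peacock's 2D Kolmogorov-Smirnov test, residual heatmaps,
    geometric medians, aligned-rank-transform factorial ANOVA), maximum
    likelihood fitting of fate-bias parameters with profile-likelihood
    plausible intervals, and a human mutant-clone-density analysis relating
    pathogenic PIK3CA missense clone accumulation to donor age and body-mass
    class. A synthetic-data module generates lineage-tracing cohorts and donor
    mutation tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
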