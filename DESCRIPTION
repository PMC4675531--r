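Package: ictalnet
Title: Bistable Network Simulation of Seizure Onset and Virtual Resection
    on Structural Connectomes
Version: 0.9.0
Authors@R:
    person("R.", "Calder", email = "rcalder@example.org",
           role = c("aut", "cre"))
Description: Simulates noise-driven transitions into a seizure-like state on
    subject-specific structural brain networks. Subject models are built from
    streamline-count connectivity, mean fibre lengths and regional surface
    areas on an 82-region whole-brain parcellation; per-region excitability is
    derived from how far a subject's surface areas deviate from a control
    cohort. A fixed-step Euler-Maruyama solver integrates the coupled
    stochastic delay system and records node escape times. The package
    performs in-silico resections (random, clinical amygdalohippocampectomy,
    and patient-specific), reproduces the associated cohort statistics
    (Mann-Whitney U, Kruskal-Wallis with Bonferroni-corrected pairwise tests,
    paired pre/post comparisons, weighted network hub measures), and ships a
    synthetic connectome cohort generator that emulates a left temporal lobe
    epilepsy patient/control study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
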