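Package: neoqeeg
Title: Quantitative EEG Features and Outcome Regression for Neonatal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative EEG analysis for predicting later
    cognitive outcome scores from neonatal multichannel recordings.
    Implements artifact-aware preprocessing (bad-channel detection, common
    average reference, fixed-length epoching, amplitude rejection, ICA
    reconstruction), noise-assisted multivariate empirical mode
    decomposition (NA-MEMD) with Hammersley direction sampling, weighted
    phase-lag index (WPLI) connectivity with global graph metrics
    (transitivity, global efficiency, radius, diameter, characteristic
    path length), complexity features (sample, permutation and spectral
    entropy) per intrinsic mode function, Pearson correlation screening
    with t-based p-values, and leave-one-subject-out cross-validated
    bagged and boosted regression-tree ensembles.  A seeded synthetic
    cohort generator with planted oscillations, phase coupling,
    complexity gradients and artifacts makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    rpart,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
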