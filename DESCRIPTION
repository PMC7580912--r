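Package: octaquant
Title: Quantification of Retinal Perfusion from En-Face OCT Angiography
Version: 0.1.0
Authors@R:
    person("OCTA", "Maintainers", email = "octaquant@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying capillary perfusion on en-face optical
    coherence tomography angiography (OCTA) slabs of the retinal plexuses.
    Implements a vessel-length-density-based binarization threshold derived
    from the deep capillary plexus (a two-segment regression on the
    skeletonized-vessel-length versus threshold curve), comparison
    thresholders (Mean, Huang), topology-preserving skeletonization,
    parafoveal vessel density, vessel length density, adjusted flow index and
    foveal avascular zone area, a seeded synthetic angiogram and cohort
    generator with ground truth, and the cohort statistics layer (Spearman
    stage trends, age/quality-adjusted ANCOVA with Benjamini-Hochberg
    post-hoc contrasts, Cohen's d, a-priori sample size, ROC screening
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
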