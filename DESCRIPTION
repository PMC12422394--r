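Package: choroid3d
Title: Three-Dimensional Choroidal Vasculature Analysis for SS-OCT Volumes
Version: 0.1.0
Authors@R:
    person("Choroid3D", "Developers", email = "choroid3d@example.org",
           role = c("aut", "cre"))
Description: Semi-automated three-dimensional analysis of the choroidal
    vasculature in swept-source optical coherence tomography (SS-OCT)
    volumes. Delineates the choroid between the choroidal-RPE and
    choroidal-scleral junctions with a classical multistep pipeline,
    binarizes hyporeflective vessel lumens with Phansalkar local
    thresholding, builds a labelled 3D vasculature with optic-disc
    exclusion and a fovea-centered five-sector grid, and measures mean
    choroidal vessel diameter (MChVD), intervessel distance (IVD),
    choroidal thickness (CTh) and the choroidal vascularity index (CVI)
    per sector and globally. Ships a synthetic SS-OCT phantom and cohort
    generator with known ground truth, plus the cohort statistics stage:
    linear mixed models with Bonferroni-corrected contrasts, two-way
    absolute-agreement intraclass correlation, Pearson correlations and
    Fisher exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
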