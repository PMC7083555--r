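Package: normdev
Title: Voxelwise Normative Modelling of Brain Tissue Volume with Gaussian
    Process Regression
Version: 0.1.0
Authors@R:
    person("normdev", "developers", email = "normdev@example.org",
           role = c("aut", "cre"))
Description: Normative modelling of voxel-based-morphometry style tissue
    volume maps. Per-voxel Gaussian process regressions of volume on age and
    sex provide predictive means and variances in a healthy reference cohort
    (10-fold cross-validated); held-out and out-of-sample observations are
    converted to voxelwise Z deviation maps. Individual deviation maps are
    thresholded (|Z| > 2.6 or per-subject Benjamini-Hochberg FDR) into extreme
    positive/negative masks, summarised as percentage scores, and aggregated
    into group overlap maps. Group inference uses permutation tests
    (sign-flipping and label permutation) with threshold-free cluster
    enhancement and FDR correction, overdispersed-binomial Wald tests on the
    extreme-deviation scores, Bonferroni-Holm correction, and covariate
    association tests. A synthetic-cohort generator with known ground truth
    (smooth age decline, sex offset, spatially correlated noise, idiosyncratic
    focal lesions, one shared-effect region) makes the whole pipeline testable
    without clinical MRI data. Includes a minimal NIfTI-1 reader/writer and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
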