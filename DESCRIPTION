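Package: t1pve
Title: Partial-Volume Estimation for Deep Gray Matter on Quantitative T1 Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-tissue partial-volume analysis of quantitative T1
    relaxometry maps in deep gray matter nuclei (thalamus, caudate,
    putamen, pallidum). Estimates per-voxel gray-matter concentrations
    together with region-global characteristic T1 values of gray and
    white matter by an alternating estimator built on a
    uniform-concentration marginal likelihood, extracts per-region
    feature vectors from labelled volumes with lesion exclusion, and
    compares subject groups with MANOVA on the partial-volume features,
    permutation-based component tests with covariate adjustment, and a
    global signal-averaging arm. Includes a synthetic phantom and cohort
    generator so the whole pipeline can be validated without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
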