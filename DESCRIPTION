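Package: persotarget
Title: Personalized TMS Target Derivation from Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives personalized transcranial magnetic stimulation (TMS)
    targets in the dorsolateral prefrontal cortex (DLPFC) from resting-state
    fMRI, implementing two published strategies: a refined seed-based
    algorithm (weighted subgenual anterior cingulate representative signal,
    voxel ranking, centroid of the largest contiguous retained cluster) and a
    spatially constrained hierarchical clustering algorithm (Spearman-distance
    agglomeration of DLPFC subunits scored by size-weighted sgACC correlation,
    spatial concentration and extent). Includes the supporting denoising steps
    (Gaussian smoothing, nuisance and global signal regression, aCompCor,
    band-pass filtering), test-retest reliability and discriminability
    metrics over repeated runs, sign-flip permutation inference, voxel-wise
    symptom-association regression with cluster-extent thresholding, and a
    synthetic 4-D BOLD generator with planted connectivity structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
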