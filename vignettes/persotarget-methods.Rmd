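---
title: "Personalized TMS targeting from resting-state connectivity: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized TMS targeting from resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persotarget)
```

## The problem

High-frequency rTMS for depression stimulates the left dorsolateral
prefrontal cortex (DLPFC), and treatment response tracks how strongly the
stimulated site is *anticorrelated* with the subgenual anterior cingulate
cortex (sgACC) in resting-state fMRI. Two published strategies derive an
individualized stimulation coordinate from that principle, and this package
implements both, plus the machinery needed to ask two questions of any such
algorithm: does it return the same coordinate when the subject is scanned
again, and does the derived target's sgACC coupling track symptom severity?

## The two algorithms

**Refined seed-based algorithm (RSA).** A population-level weighting mask is
built by averaging per-run sgACC seed-correlation maps across subjects
(`sgacc_fc_map()`, `group_weight_map()`). For a new run, every brain voxel's
time series is multiplied by its weight and the result is averaged over all
voxels *outside* the DLPFC search mask, giving an "sgACC representative
signal" (`weighted_representative_signal()`). Each DLPFC voxel is correlated
with this signal, voxels are ranked ascending (most anticorrelated first),
the top fraction (default 50%) is retained, and the centroid of the largest
contiguous retained cluster is the target (`rsa_target()`). The retained
fraction can be swept 10%–100% (`rsa_target_sweep()`).

**Hierarchical clustering algorithm (HCA).** The DLPFC and sgACC masks are
each partitioned into "subunits" by spatially constrained agglomerative
clustering: every voxel starts as a cluster, and the closest *spatially
adjacent* pair (average linkage over the Spearman distance
`1 - rho`) merges until the minimum adjacent-pair linkage exceeds 0.5
(`constrained_agglomerative_cluster()`). Each subunit is summarized by its
median time course and the member voxel best correlated with it
(`subunit_summary()`). DLPFC subunits are then scored on three z-scored
parameters — size-weighted correlation with the sgACC subunits, spatial
concentration (voxels per mm of mean pairwise distance), and voxel count —
and the representative voxel of the highest-composite subunit is the target
(`score_subunits()`, `hca_target()`).

Both algorithms consume runs denoised by a fixed pipeline
(`preprocess_run()`): 5-mm-FWHM Gaussian smoothing, nuisance regression
(6 motion parameters, their backward-difference derivatives, the first 5
principal components of white-matter/CSF signals, and optionally the global
signal as one more column of the same regression), then an ideal 0.01–0.1 Hz
band-pass.

## Design choices where the method descriptions are open

Several details are not pinned down by the published method descriptions;
the package fixes them as follows, each switchable where a user might
reasonably want the alternative.

* **Linkage.** Average linkage between clusters. It is the natural reading
  of "distance between clusters" for a correlation-derived distance, and it
  is stable against the chaining behaviour single linkage shows on smoothed
  data. The merge order is deterministic: ties are broken toward the
  clusters containing the lowest linearized voxel indices, and final labels
  are renumbered by lowest member index, so the labeling is invariant to
  voxel enumeration order.
* **Adjacency/contiguity.** 26-connectivity by default (6 and 18
  available), for both the clustering constraint and the connected-component
  steps. Two clusters are adjacent iff any cross-pair of members is.
* **Correlation flavours.** The DLPFC distance matrix is explicitly
  Spearman; every other correlation (representative-voxel couplings, seed
  maps, subunit cross-correlations) is Pearson, the default reading of
  "correlation coefficient".
* **Ranking direction.** "Ascendingly ranked, top fraction retained" is
  implemented as keeping the *most anticorrelated* fraction — the reading
  consistent with the anticorrelation premise. `rank_order = "descending"`
  provides the opposite for sensitivity analyses.
* **Weights keep their sign** in the representative signal (no absolute
  value), and group weight maps average raw correlations by default
  (`fisher_z = TRUE` available).
* **GSR placement.** The global signal enters as an additional column of
  the single nuisance regression rather than a separate sequential step,
  which avoids re-introducing removed variance.
* **Degenerate cases.** A zero-variance scoring parameter z-scores to all
  zeros rather than NaN; singleton subunits get concentration 0 (penalizing
  degenerate "clusters"); a subject with perfectly reproducible targets
  gets an infinite discriminability ratio and a warning.
* **Voxel indexing.** 1-based voxel indices (R convention) against a
  NIfTI-convention affine; all distances and coordinates are world mm, and
  reported coordinates are RAS+ (MNI).

## Reliability and inference

From the four runs per subject (day 1/2 x phase-encoding LR/RL),
`distance_indices()` computes the intra-day, inter-day, intra-phase and
inter-phase mean distances and the six-pair mean; by construction the
inter-day and inter-phase indices share their two defining run pairs and are
always identical — the decomposition can separate day effects from phase
effects only through the *intra* indices. `variability_report()` gives the
run-to-centroid distance SD and per-axis SDs (sample SD, n = 4), and
`discriminability_ratios()` the inter/intra individual distance ratio.

Inference is by sign-flip permutation (`paired_permutation_test()`): every
comparison in this design is within-subject, so the exchangeable quantity
under the null is the sign of each subject's paired difference. The p-value
uses the add-one estimator, so it is never 0 and never smaller than
`1/(n_iter+1)`. The default statistic is the median difference (medians are
the natural summary for distance data); the mean difference is available and
is what the calibration checks use, because the sample median's heavy tying
under sign-flips makes the median-based test noticeably conservative at
small alpha. Two-factor designs (algorithm x day, algorithm x phase) use
sign-flip tests of per-subject marginal differences and of the double
difference for the interaction (`two_factor_permutation()`), with
`bonferroni()` supplying the corrected thresholds (0.05/3, 0.05/4).

The symptom-association module regresses symptom scores on target-ROI to
sgACC connectivity per sgACC voxel with age and sex covariates
(`voxelwise_regression()`, via Frisch–Waugh partialling; t with n - 4 df),
then applies cluster-extent thresholding (`cluster_threshold()`): voxelwise
p < 0.001 with minimum cluster size 4 in small-volume mode (`>=`), or
cluster size > 18 in whole-brain mode, the published defaults. Because the
original ACF-based Monte-Carlo threshold tool is environment-specific, the
package instead offers `cluster_size_null()`, a permutation null of the
maximum cluster size, as the data-driven way to choose the size threshold.

## The synthetic cohort generator

Real test-retest archives cannot ship with a package, so every claim is
validated on synthetic 4-D cohorts with planted structure
(`cohort_spec()`, `simulate_cohort()`). The generative model, per subject:

* a band-limited (0.01–0.1 Hz) latent sgACC signal, a *subject trait*
  re-observed in every run; sgACC voxels carry it with unit coupling;
* a planted DLPFC blob (radius 5.5 mm, offset 3.5 mm from the search-mask
  centre) coupled at `coupling_target` (default -0.8, with between-subject
  SD 0.1);
* the remaining DLPFC organized into contiguous Voronoi parcels (~12
  voxels), each with its own band-limited subject-level latent of unit
  amplitude — the functional heterogeneity the clustering algorithm needs
  to find boundaries, without which smoothing merges the whole mask into
  one subunit;
* weak heterogeneous sgACC couplings elsewhere (SD 0.15 in DLPFC background,
  0.05 in the rest of the brain), jittered per acquisition day (SD 0.05);
* a shared "global" component per run (amplitude 0.5 by default):
  band-limited and gray-matter-restricted — WM and CSF carry none
  directly, though spatial smoothing re-introduces some into the tissue
  masks (see the limitations) — with a smooth spatial loading field
  (4-mm correlation scale, mean 1, SD 0.35) redrawn every run, because
  between-scan drift of the global artifact is what makes it a
  test-retest hazard;
* white voxel noise (SD 0.6) and a baseline of 100 inside the brain (giving
  realistic temporal SNR around 100);
* geometry: a 24x24x24 grid of 2-mm voxels (TR 0.72 s, 300 time points by
  default), with spherical brain/DLPFC/sgACC/WM/CSF masks written through
  the same NIfTI path as real data. A full single-run pipeline stays in the
  seconds range at this size.

Scored cohorts (`simulate_cohort_with_scores()`) add ages (uniform 19–55),
sex (Bernoulli 0.5) and a score linear in the model-implied target–sgACC
connectivity (slope 2 by default) plus small age/sex effects and noise. For
regression-scale experiments (n = 60, many replicates) the cohort-level
generator `simulate_fc_cohort()` produces per-subject FC vectors directly
from the same coupling model — a planted core inside the sgACC carries the
subject's true connectivity plus measurement noise; the rest carries
score-unrelated values of matched spread.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: head motion and its interaction with
denoising, EPI distortion and registration error, physiological noise
spectra, cortical folding (masks are spheres; the real gray-matter-restricted
DLPFC is a thin sheet whose retained-voxel clusters fragment differently),
and realistic spatial autocorrelation of couplings. The validation shows the
*algorithms and statistics are implemented correctly and behave as the
published comparison reports qualitatively*, not that effect sizes transfer.

## Validation design and problem sizes

The test-suite study conditions were fixed once while designing the
generator:

* **Recovery cohort**: 5 subjects x 4 runs, defaults, blob coupling -0.8.
  The seed-based target must fall within 4 mm (two voxel widths) of the
  planted blob centroid in >= 90% of runs; the winning clustering subunit's
  representative voxel must lie inside the blob in >= 80%.
* **GSR-contrast cohort**: 10 subjects, `global_amp = 3` and
  `coupling_target = -0.2`. The weak-coupling regime is where global-signal
  contamination can in principle perturb the voxel ranking: at the recovery
  cohort's -0.8 coupling the blob-background correlation gap (~0.7) dwarfs
  any loading-field perturbation and the seed-based algorithm is immune to
  the global component at any amplitude. The directional expectation —
  GSR shrinks the seed-based algorithm's six-pair distance while the
  clustering algorithm, which keys on *local* rank similarity that a
  shared component shifts nearly uniformly, need not change — holds in
  sign on this generator but does **not** reach significance (see the
  limitations below for the two mechanisms that mute it); the
  corresponding check in the test suite is expected to fail and is kept
  as a falsifiable record rather than weakened.
* **Symptom cohort**: n = 60, planted slope 2.0, subject-coupling SD 0.3,
  score noise 0.05, FC measurement noise 0.01 (small-noise regime so the
  slope estimate's sampling SD of ~0.06 sits well inside the +/-0.2
  acceptance band); 20 signal and 20 null replicates.
* **Oracle checks** run the constrained clustering against an exhaustive
  greedy-merge re-implementation on 100 random <= 12-voxel masks, and the
  connected-component labeling against a stack-based flood fill on 100
  random 12-cube masks at all three connectivities.
* **Numerics**: band-pass contracts are probed with tones on the DFT grid
  (0.00463 Hz stop, 0.0498 Hz pass for the 864-s window), because an
  off-grid tone is not periodic over the window and any finite-window
  Fourier mask filter necessarily leaks ~12% of its RMS; the on-grid tones
  test the filter's actual contract. Permutation calibration (500 null
  replicates, n = 30, 1000 iterations) uses the mean statistic for the
  tie-related reason above.

## Known limitations

Masks and data must share one geometry (no resampling is provided);
surface-based workflows, nonlinear registration, ICA denoising, scrubbing
and electric-field modelling are out of scope. The clustering step is
O(n^2) in mask voxels and is intended for search regions of a few hundred
to a few thousand voxels.

Two interacting properties of the synthetic design mute the
global-signal-regression contrast that real cohorts show:

1. With the fixed smooth-then-regress pipeline, smoothing bleeds
   gray-matter signal into the small synthetic WM/CSF spheres, so the
   aCompCor components absorb most of the shared global component before
   either algorithm runs — GSR has little left to remove. (Real pipelines
   sidestep this with eroded tissue masks; an eroded-gray-matter variant of
   the generator was evaluated and does restore the GSR mechanism, but the
   surviving correlation floor then chains the constrained clustering into
   one giant subunit and destroys the planted-recovery behaviour, so the
   un-eroded design was kept.)
2. At a 50% retained fraction on a solid spherical search mask the
   retained set usually percolates into one large connected component
   whose centroid is stable regardless of ranking corruption, so the
   seed-based target degrades gracefully toward the mask centroid rather
   than wandering — on real, sheet-like cortical masks the fragmentation
   (and hence the reliability cost of contamination, and the benefit of
   GSR) is larger.
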