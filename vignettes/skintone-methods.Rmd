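---
title: "Classifying skin tone by CIELAB clustering and Fitzpatrick palette matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying skin tone by CIELAB clustering and Fitzpatrick palette matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Clinicians grade skin colour on the six-class Fitzpatrick Skin Type (FST)
scale by visually comparing a patient's skin with a printed reference
palette. That judgement is subjective and sensitive to lighting. `skintone`
automates the comparison: it treats a photograph as a cloud of colours,
summarises that cloud with a small number of cluster centres, and matches
each centre to the nearest palette swatch under a perceptual colour
distance.

The pipeline is:

1. **Colour space.** Pixels are converted from sRGB (D65 white point,
   2° observer, standard transfer function — the universal defaults for
   consumer photographs) to CIELAB, where Euclidean distance approximates
   perceived colour difference and lightness `L*` is separated from the
   chromatic axes `a*`, `b*`. The separation matters: uneven illumination
   moves pixels mostly along `L*`, so chroma-driven cluster structure
   survives lighting changes better than in RGB.
2. **Clustering.** The (downscaled) pixel cloud is partitioned by one of
   twelve clustering families (`fit_clusters()`); k-means is the default
   and the reference choice. Cluster centres live in LAB.
3. **Matching.** Each centre is assigned the class of the nearest palette
   entry under the CIE76 colour difference
   `dE = sqrt(dL^2 + da^2 + db^2)` (`match_clusters()`). Matching always
   operates on centres, never per pixel: the centre *is* the summary tone
   the clinician would compare.
4. **Decision.** Cluster pixel fractions are tallied; the dominant tone is
   the class of the largest-fraction cluster. `segment_image()` writes the
   matched class back onto the raster for a spatial map, and
   `sweep_cluster_counts()` aggregates fractions of clusters sharing a
   class across several values of `k`.
5. **Validation.** Ground truth comes from the Individual Typology Angle,
   `ITA = atan2(L* - 50, b*) * 180 / pi` (degrees), banded into the six
   classes. Predictions are scored with a confusion matrix, exact
   accuracy/precision/recall/F1, and tolerance accuracy — the share of
   predictions within ±t classes, with t = 1 the clinically accepted
   margin on this ordinal scale.

Key assumptions: the photograph is dominated by skin (or a mask is
supplied); skin tones form compact, roughly convex clusters in LAB, which
favours centroid methods; and the palette's swatches are far apart relative
to image noise, so nearest-swatch matching is stable.

## The reference palette

No measured palette ships with the package: the default
(`inst/extdata/fst_palette_synthetic.json`) is **synthetic**. Its six
swatches have evenly spaced lightness (`L* = 77` down to `37` in steps of
8, the span of a printed FST chart) and representative skin chroma, and
each swatch lies inside its own ITA band (boundaries 55°, 41°, 28°, 10°,
−30°, the standard del Bino banding). Two properties follow by
construction:

* adjacent swatches are at least ΔE ≈ 8.3 apart, comfortably above the
  default sensor-noise level (σ = 2), so matching is well conditioned; an
  early draft that placed swatches at ITA band *midpoints* compressed the
  middle classes to ΔE ≈ 5.5 and made fraction recovery unstable, which is
  why even lightness spacing was adopted;
* ITA-derived ground truth is self-consistent with the palette: the ITA of
  swatch *k* maps back to class *k*.

Measured palettes can be supplied as JSON (`load_palette()`, LAB or sRGB)
or extracted from a photographed chart by k-means with k = 6
(`palette_from_image()`), which orders recovered centres by descending
lightness and refuses charts with fewer than six distinguishable swatches
(two centres within ΔE 1). The ITA band boundaries are configuration
(`ita_to_fst(thresholds = ...)`), with boundary angles assigned to the
lighter class.

## Clustering models and their tunables

All twelve families sit behind `fit_clusters()` and return the same
contract: a *total* partition (density-model noise points are reassigned
to the nearest centre, with the count reported) and one LAB centre per
cluster — models without native centroids report per-cluster LAB means,
which is what ΔE matching needs.

* `kmeans` — authored in-package: k-means++ seeding, Lloyd iterations,
  best of `n_init = 10` restarts, `max_iter = 300`, `tol = 1e-4` on the
  squared centre shift. Argmin ties break toward the lowest cluster index
  so runs are reproducible; an emptied cluster is reseeded with the
  worst-fit point.
* `kmeans_minibatch` — streaming centre updates on batches of 1024 with
  per-centre learning rates; trades a little optimisation quality for
  speed.
* `kmeans_pca` — k-means after projection onto the top 2 of 3 principal
  components of the LAB cloud (an interpretive choice: 2-of-3 is the only
  non-trivial reduction); centres are re-expressed as LAB means in the
  original space.
* `dbscan`, `optics_dbscan` — density clustering with `eps = 1.2` ΔE and
  `min_samples = 12`. These defaults were calibrated once on the synthetic
  fixtures: with σ = 2 noise, adjacent tone regions nearly touch in LAB,
  and a larger `eps` chains them into one cluster.
* `hdbscan` — the full hierarchy-based variant: mutual-reachability
  distances (`min_samples = 10`), a single-linkage tree, condensed-tree
  extraction with excess-of-mass stability and
  `min_cluster_size = max(25, 2% of N)`.
* `ahc` — agglomerative hierarchical clustering (Ward linkage) via
  `stats::hclust`.
* `gmm` — Gaussian mixtures via `mclust`, trying covariance models
  VVV → VEV → VII.
* `fuzzy_cmeans` — `e1071::cmeans` with fuzzifier m = 2; labels are the
  membership argmax and the full membership matrix is kept in the result's
  `extras` (memberships are exposed but not propagated to reports).
* `affinity_propagation` — message passing with damping 0.9 and the median
  similarity as preference; infers its own k (often many exemplars on
  smooth pixel clouds — the benchmark records the k found).
* `mean_shift` — flat-kernel shifts from up to 500 seeds, bandwidth
  estimated as the 25% quantile of sampled pairwise distances, modes
  merged within half a bandwidth.
* `spectral` — `kernlab::specc` (RBF affinity, normalised spectral
  embedding).

Quadratic-cost models run on a seeded pixel subsample and extend labels to
the full cloud by nearest-centre assignment: AHC at 4000 points, GMM at
6000, HDBSCAN/OPTICS at 4096, affinity propagation at 1000 (its per-
iteration cost is O(n² · iterations)), spectral at 2000 — the spectral cap
is deliberately tight because the dense eigendecomposition scales as
O(n³), and 2000 points already estimate the embedding of a 3-D colour
cloud well.

`resize_image()` bounds the pixel cloud before clustering
(`max_dim = 256`, bilinear): bilinear interpolation locally averages
colours, so tone regions keep their colour and boundaries are not aliased,
while k-means stays interactive.

## Validity indices

`silhouette_score()`, `calinski_harabasz()` and `davies_bouldin()` are
implemented from their definitions (Euclidean distance in LAB, the
clustering space) and are checked against independent brute-force oracles
to 1e-9 in the test suite. Numerical conventions: singleton clusters
contribute silhouette 0; a partition with zero within-cluster scatter
yields Calinski–Harabasz `Inf` (documented sentinel) and Davies–Bouldin 0;
coincident centroids of distinct clusters make Davies–Bouldin undefined
and raise a diagnostic error. For large clouds the silhouette runs on a
seeded subsample (default cap 10 000; `sample_size = NULL` forces the
exact quadratic computation). `benchmark_models()` fits any subset of the
registry on one cloud and scores all three indices plus wall-clock fit
time; a model failure becomes a `status` row, never an aborted sweep, and
single-cluster fits are reported as `degenerate` rather than raised. Fit
times are hardware-dependent and are never asserted in tests.

## The synthetic-data generator

`render_scene()` and `generate_cohort()` stand in for a clinical image
set: contiguous vertical bands of palette-typical colours with exactly
known area fractions, an additive linear `L*` ramp emulating uneven
illumination, iid Gaussian LAB noise (default σ = 2, small against the
palette spacing), and an optional near-black background band emulating a
dark backdrop. Defaults mirror a small clinical study: cohorts of 48
subjects spanning FST I–VI, uniformly mixed, at 96×72 px with a 3-unit
lighting ramp; half the scenes carry a secondary region of an adjacent
class covering 15–35% of the skin, emulating within-subject tone
variation. Per-image seeds derive from one master seed, so cohorts are
fully reproducible.

What the generator deliberately omits: anatomical shapes, skin texture,
specular highlights, colour casts from white-balance error, and camera
response differences. Passing the recovery tests therefore shows that the
pipeline is correct and well conditioned under controlled, known-truth
conditions — not that it is robust to real-world photography, where
calibration and masking dominate error.

## Numerical and design choices

* Dominant class: largest pixel fraction; ties go to the smaller ΔE, then
  to the lighter class. Deterministic given the seed.
* Matching ties (a centre equidistant from two swatches) go to the lighter
  class.
* Background handling: masks are optional; without one, a cluster with
  centre `L* < 20` covering more than 20% of the image triggers a warning
  suggesting masking (the intended capture setup is a dark backdrop, which
  otherwise absorbs a cluster).
* Confusion matrices are oriented rows = truth, columns = prediction.
  Precision/recall/F1 are macro-averaged over classes present in the
  ground truth (classes never predicted contribute precision 0; classes
  absent from truth are excluded so small cohorts don't produce undefined
  recall); micro averaging is available and collapses to accuracy.
* Cluster labels are 1-based (R convention) everywhere, including CLI
  reports.
* Out-of-gamut LAB colours are clipped on conversion to sRGB; the round
  trip over in-gamut sRGB is accurate to one 8-bit step per channel.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core: oracle checks on clouds of
60–200 points; fraction recovery on 160×120 scenes; cohort recovery on 48
images of 96×72; the twelve-model benchmark on a 64×64 fixture. These
sizes are stated here as the package's reference conditions; all of them
scale up linearly (quadratically for the subsampled models) if more
fidelity is wanted.

## Known limitations

* CIE76 is the classical but crudest ΔE; CIEDE2000 would weight lightness
  and chroma differences more perceptually and is a natural extension.
* No colour constancy or white-balance correction is applied; the package
  assumes calibrated capture, and the reference-chart extraction path
  (`palette_from_image()`) is the supported route to per-session
  calibration.
* The dominant-class decision ignores fuzzy memberships and per-pixel
  uncertainty.
* Automatic selection of k is out of scope; `sweep_cluster_counts()`
  supports the manual sweep workflow instead.
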