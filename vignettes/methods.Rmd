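---
title: "Methods: segmentation-free profiling of 3D microscopy stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-free profiling of 3D microscopy stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

High-content 3D screens produce multichannel fluorescence z-stacks in which
individual cells are frequently impossible to segment: dense neuronal
cultures, organoids, and thick tissue all violate the assumptions of
nucleus-seeded segmentation. This package sidesteps segmentation entirely.
Each image is reduced to a *bag of textures*: a three-level spatial
hierarchy in which progressively larger blocks of the image are described by
the composition of learned categories one level down.

1. **Pixels.** Per-channel intensities are linearly rescaled using robust
   bounds learned from a small training set (medians across training images
   of the per-image 5% and 95% quantiles). A voxel is *background* when
   every channel falls below its channel threshold; foreground voxels are
   assigned to one of `k_p` pixel categories by nearest centroid, where the
   centroids come from k-means over multichannel intensity vectors of
   training foreground voxels (default `k_p = 15`).
2. **Supervoxels.** Non-overlapping blocks of pixels (default 10 x 10 x 3
   in x, y, z) are summarized by the normalized frequency of foreground
   pixel categories they contain; the frequency vectors are again clustered
   by k-means into `k_sv` supervoxel categories (default 20). A supervoxel
   is background when *strictly more than* half its pixels are background.
3. **Megavoxels.** Blocks of supervoxels (default 6 x 6 x 2) are summarized
   by the normalized frequency of supervoxel categories among their
   foreground members and clustered into `k_m` megavoxel categories
   (default 40). A megavoxel is foreground when *at least* half its
   supervoxels are foreground - deliberately inclusive where the supervoxel
   rule is deliberately strict, so sparse-but-real structure survives both
   levels.

The per-image feature vector is the relative frequency of foreground
megavoxel categories, plus the foreground megavoxel count kept as a
separate column. Because only foreground blocks contribute, the features
are invariant to how much empty space surrounds the biology: padding a
stack with background planes leaves the vector exactly unchanged (this is a
unit-tested identity, not an approximation).

All block partitions are anchored at the array origin and trailing partial
blocks are discarded, so features are deterministic functions of the stack
and the trained model.

## Thresholding

Foreground/background separation uses maximum correlation thresholding:
among 256 candidate thresholds evenly spaced over a plane's intensity
range, pick the one maximizing the Pearson correlation between the
binarized mask and the original intensities (ties to the smallest
candidate). Per-slice thresholds from the training set are aggregated per
channel; the median is the default working threshold, with the first and
third quartiles stored as documented alternatives for unusually dim or
bright assays (`quantile_choice`).

The implementation evaluates all 256 candidates with a single sort and
cumulative sum rather than 256 correlation calls; a brute-force oracle in
the test suite verifies the algebra.

## Clustering and the preference scan

Image profiles are clustered with affinity propagation (AP): damped
message passing (damping 0.9, up to 1000 iterations, convergence window
50) over a similarity matrix, either negative Euclidean distance (default)
or Spearman correlation. The implementation is deterministic: no random
initialization, ties broken to the lowest index, and a vanishingly small
hash-based perturbation (about 1e-9 of the similarity range, a pure
function of the cell index) to settle the oscillations that exact ties
otherwise cause.

AP's cluster count is governed by its *preference* parameter. The exact
lower bound (the largest preference at which one cluster is optimal) and
upper bound (the maximum off-diagonal similarity) are computed from the
one- versus two-exemplar constructions; 40 preference values are scanned
linearly between them, and the resulting cluster-count curve N(m) is
examined for its knee: curvature `dF(m) = N(m-1) + N(m+1) - 2 N(m)` ranks
the candidates, the top five (ties carried) are kept, and the candidate
maximizing `atan(1/|N(m)-N(m-1)|) + atan(1/|N(m+1)-N(m)|)` marks the point
just before cluster count starts growing exponentially.

Two subtleties deserve a note. First, candidates adjacent to a flat
segment (an adjacent difference of zero) are excluded from the angle
comparison: the angle formula would treat a plateau as an infinitely
sharp corner, and on the documented worked curve
`1,2,3,3,4,4,5,18,60,190` only this exclusion yields the intended answer
of 5 clusters. Second, the angle criterion favours unit steps, so a
non-monotone wobble in the curve (e.g. `...3,3,2,3...`) can outscore the
true knee; the method is a heuristic and is validated statistically (mean
adjusted Rand index across replicate synthetic datasets), not pointwise.

When no knee exists (flat curve, or all candidates flat-adjacent) the
implementation falls back, with a warning, to the median off-diagonal
similarity - the conventional single-shot AP preference. That median
preference is also the baseline the validation protocol compares against.
A caveat worth stating plainly: on the well-separated synthetic mixtures
produced by the bundled generator (means uniform on [0, 10] per dimension,
standard deviations on [0.5, 1.5], 10-30 dimensions), the median-preference
baseline itself clusters nearly perfectly, so the scan's advantage does not
materialize there; the baseline only degrades when clusters overlap
substantially. The scan's value is robustness - it needs no rule of thumb
about where the preference should sit for a given assay - rather than a
universal accuracy win over the median heuristic.

## Classification and metrics

Phenotype classification uses a 100-tree random forest whose `mtry` is
chosen from `{floor(sqrt(d))/2, floor(sqrt(d)), 2 floor(sqrt(d))}` by
internal 5-fold stratified cross-validation. Reported performance is
10-fold cross-validated Cohen's kappa, so the headline number is always
chance-corrected and never computed on training rows. Mutual information
between cluster assignments and experimental groupings is computed in nats
from the contingency table with zero cells contributing zero.

## Organoid localization

For sparse assays (a few organoids in a large field) the package locates
objects before profiling. The nuclear channel is focus-stacked: per slice,
a 3 x 3 median filter, an 11 x 11 local standard deviation, and a Sobel
gradient magnitude produce a sharpness map; per XY position the sharpest
plane (ties to the lowest z) contributes its *original* intensity to the
projection. The projection is smoothed with a disk mean filter (radius 75
at full scale), thresholded by maximum correlation, hole-filled, and split
by a distance-transform watershed; small and border-touching regions are
dropped. Per region, the histogram of best-focus planes inside the mask
selects the z-range: planes whose share exceeds the uniform-chance level
`1/n_z` are in focus, padded by two planes each side and clamped. Nine 2D
morphology features (moment-ellipse axes and eccentricity, equivalent
diameter, solidity, extent, convex area, perimeter) plus a hollowness
ratio (mean rim over mean central intensity on the middle slice, rim width
40 pixels) describe each organoid.

## Synthetic fixtures and generator realism

Everything is validated against programmatic fixtures; no binary data
ships with the package.

* **Texture stacks** place oblate blobs with per-channel intensity levels
  drawn from a class-specific mixture until a target foreground density is
  reached. Two classes with different mixture weights emulate
  treatment-induced texture shifts; the intensity histograms overlap, so
  classes are only separable through composition - exactly the regime the
  hierarchy is designed for.
* **Organoid scenes** render textured bright shells around dim interiors,
  sharp inside a per-organoid focus range and increasingly Gaussian-blurred
  and faded away from it, emulating wide-field defocus in thick samples.
* **Gaussian mixtures** draw cluster means uniformly from [0, 10] per
  dimension and isotropic standard deviations from [0.5, 1.5], matching
  the validation protocol for automated cluster-count estimation: 30
  replicate datasets per setting, dimensions 10/20/30, 3 or 5 clusters,
  30 points per cluster.

## Numerical choices and problem sizes

* Stacks are numeric 4D arrays `[y, x, z, channel]`, 1-based, read from
  one grayscale 16-bit TIFF per (channel, z) plane; integer data pass
  through exactly.
* Rescaled intensities are deliberately not clipped to [0, 1]; every
  downstream consumer tolerates values outside the unit interval.
* k-means uses 10 restarts and 300 iterations with a fixed seed; every
  stochastic step (training-image sampling, k-means, noise, embeddings)
  runs under an isolated seeded RNG that restores the caller's state.
* The AP core is O(n^2) per iteration in compiled code; a 180-point
  similarity matrix clusters in well under a second, and the full 40-point
  preference scan over 180 datasets of 90-150 points completes in a few
  minutes on one CPU. The exact t-SNE implementation is O(n^2) and meant
  for up to a few thousand profiles - image-level, not pixel-level, data.
* Feature tables, metadata, scan curves and pie-chart compositions are all
  plain TSV; models are versioned JSON. Nothing downstream ever parses an
  image.
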