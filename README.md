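# phenovoxel

Segmentation-free phenotypic profiling of multichannel 3D fluorescence
microscopy stacks.

## Why

High-content screens increasingly produce 3D data — dense neuronal
cultures, organoids, thick tissue — in which single-cell segmentation is
unreliable or impossible. Most analysis pipelines nevertheless start by
segmenting cells, and inherit every segmentation failure. `phenovoxel`
takes the opposite route: it never segments. Each image is summarized by a
three-level *bag of textures*:

1. foreground **pixels** are assigned to intensity categories learned by
   k-means over multichannel intensities (thresholds come from maximum
   correlation thresholding; rescaling bounds from robust training-set
   quantiles);
2. fixed-size blocks of pixels (**supervoxels**, default 10×10×3) are
   described by the normalized frequency of pixel categories they contain
   and clustered into supervoxel categories;
3. blocks of supervoxels (**megavoxels**, default 6×6×2) are described by
   their supervoxel-category composition, clustered once more, and the
   relative frequency of foreground megavoxel categories — plus the
   foreground megavoxel count — is the per-image profile.

Because only foreground blocks contribute, profiles are invariant to how
much empty space surrounds the biology (an exactly tested identity, not an
approximation). On top of the profiling core the package provides affinity
propagation clustering with automated preference estimation (preference
scan + knee-point detection), random-forest classification with
cross-validated Cohen's kappa, mutual information, organoid localization
in large sparse stacks (focus stacking, contour segmentation, automatic
z-range selection, 2D morphology, hollowness), PCA / Sammon / t-SNE
embeddings, and fully programmatic synthetic data generators used by the
test suite. See `vignettes/methods.Rmd` for the methods in detail.

## Worked example

Everything below is runnable as-is: the data are generated by the
package's own fixture generator (two texture classes whose per-channel
intensity *mixtures* differ while their intensity ranges overlap — so the
classes are only separable through texture composition).

```r
library(phenovoxel)

dir <- file.path(tempdir(), "demo")
specs <- list(
  texture_spec(levels = list(cbind(c(3000, 9000), c(0.8, 0.2)),
                             cbind(c(2000, 6000), c(0.3, 0.7))),
               density = 0.2, radius_range = c(4, 7), noise_sd = 40,
               label = "vehicle"),
  texture_spec(levels = list(cbind(c(3000, 9000), c(0.2, 0.8)),
                             cbind(c(2000, 6000), c(0.7, 0.3))),
               density = 0.2, radius_range = c(4, 7), noise_sd = 40,
               label = "treated"))
ds <- generate_texture_dataset(specs, n_per_class = 10, dir, seed = 1)
as.data.frame(ds)[1:3, c("image_id", "channel", "z", "class")]
#>      image_id channel z   class
#> 1 treated_001       1 1 treated
#> 2 treated_001       1 2 treated
#> 3 treated_001       1 3 treated
```

Train the category hierarchy on a sample of images and extract profiles
(the small category counts and block sizes fit the 60×60×6 demo stacks;
for real 1024×1024 acquisitions keep the defaults):

```r
cfg <- pvx_config(k_p = 4, k_sv = 5, k_m = 6, sv_size = c(5, 5, 2),
                  mv_size = c(2, 2, 1), n_train = 8)
model <- train_model(ds, cfg, seed = 1)
model
#> <pvx_model> 2 channels | k_p=4 k_sv=5 k_m=6 | SV 5x5x2 px, MV 2x2x1 sv

feats <- extract_features(ds, model)
cbind(feats[1:4, c("image_id", "class", "mv_count")],
      round(feature_matrix(feats)[1:4, ], 3))
#>      image_id   class mv_count    f1    f2    f3    f4    f5    f6
#> 1 treated_001 treated       21 0.095 0.095 0.190 0.095 0.333 0.190
#> 2 treated_002 treated       29 0.172 0.103 0.207 0.000 0.138 0.379
#> 3 treated_003 treated       22 0.364 0.182 0.045 0.000 0.227 0.182
#> 4 treated_004 treated       20 0.150 0.000 0.200 0.000 0.200 0.450
```

Cluster with the automated preference scan, classify, and embed:

```r
res <- auto_cluster(feats)
res
#> <pvx_clusters> k=4, n=20, preference=-0.5327
table(cluster = res$assignments, class = feats$class)
#>        class
#> cluster treated vehicle
#>       1      10       0
#>       2       0       2
#>       3       0       4
#>       4       0       4

mean(cross_validated_kappa(feats, feats$class, folds = 5, seed = 1))
#> [1] 0.9

emb <- project(feats, method = "pca")
group_centroids(emb, feats$class)
#>           group  n   dim1   dim2
#> treated treated 10 -0.334 -0.026
#> vehicle vehicle 10  0.334  0.026
```

No cluster mixes the two classes, 5-fold cross-validated Cohen's kappa is
0.9 on twenty images, and the class centroids sit symmetrically on the
first principal axis.

A thin command-line front end with `train` / `extract` / `cluster` /
`classify` / `organoids` / `project` / `fixtures` subcommands is installed
at `inst/cli/phenovoxel` (after installation:
`system.file("cli", "phenovoxel", package = "phenovoxel")`).

## Reproduction

The test suite (testthat, edition 3) regenerates every fixture
programmatically — the package contains no binary data:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "phenovoxel", load_package = "installed")'
```

`tests/testthat/test-acceptance.R` holds the end-to-end acceptance blocks,
including the synthetic clustering validation protocol: 30 Gaussian-mixture
datasets per setting (dimensions 10/20/30 × 3 or 5 clusters), clustered by
affinity propagation with the automated preference scan and scored by
adjusted Rand index against the generating labels. The headline numbers
can be recomputed standalone:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which reports, per setting, the mean ARI of auto-preference clustering
(the JSON records the worst setting mean; with `--seed 1` the six setting
means range from 0.757 to 0.861, all above the 0.5 success threshold) and
the median ARI when the preference is instead fixed at the median
off-diagonal similarity.

One honest caveat, documented in the vignette: on these well-separated
synthetic mixtures the median-preference baseline also clusters well
(median ARI 0.934 with `--seed 1`, not below 0.5), so the corresponding
comparison block in the
acceptance suite fails by design rather than being weakened to pass. The
automated scan's value on this data is matching the baseline without any
per-assay preference rule of thumb, not beating it.

## License

MIT (see `LICENSE`).
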