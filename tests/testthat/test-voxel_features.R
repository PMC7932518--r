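test_that("a pixel is background only when every channel is subthreshold", {
  # 2x2x1, 2 channels, thresholds (0.5, 0.5)
  stk <- array(0, c(2, 2, 1, 2))
  stk[1, 1, 1, ] <- c(0.4, 0.4)   # both below      -> background
  stk[1, 2, 1, ] <- c(0.6, 0.4)   # ch1 above       -> foreground
  stk[2, 1, 1, ] <- c(0.4, 0.6)   # ch2 above       -> foreground
  stk[2, 2, 1, ] <- c(0.5, 0.4)   # ch1 at threshold -> foreground (>=)
  centroids <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  lab <- assign_pixel_categories(stk, c(0.5, 0.5), centroids)
  expect_equal(lab[1, 1, 1], 0)
  expect_equal(lab[1, 2, 1], 1)
  expect_equal(lab[2, 1, 1], 2)
  expect_equal(lab[2, 2, 1], 1)
})

test_that("nearest-centroid ties go to the lowest label", {
  centroids <- rbind(c(0, 0), c(2, 0))   # point (1, 0) is equidistant
  lab <- phenovoxel:::nearest_centroid(rbind(c(1, 0)), centroids)
  expect_equal(lab, 1L)
})

test_that("supervoxel background rule is strict and composition normalizes", {
  # one 10x10x3 block (300 px): 151 background -> background (151/300 > 0.5)
  cs <- array(1L, c(10, 10, 3))
  cs[seq_len(151)] <- 0L
  sv <- build_supervoxels(cs, k_p = 2, sv_size = c(10, 10, 3))
  expect_true(sv$is_background[1])
  expect_equal(sv$composition[1, ], c(0, 0))

  # exactly 150 background -> foreground (not strictly more than half)
  cs[seq_len(151)] <- 1L
  cs[seq_len(150)] <- 0L
  sv <- build_supervoxels(cs, k_p = 2, sv_size = c(10, 10, 3))
  expect_false(sv$is_background[1])

  # composition: 150 of category 1, 30 of category 2, 120 background
  cs <- array(0L, c(10, 10, 3))
  cs[seq_len(150)] <- 1L
  cs[150 + seq_len(30)] <- 2L
  sv <- build_supervoxels(cs, k_p = 2, sv_size = c(10, 10, 3))
  expect_false(sv$is_background[1])
  expect_equal(sv$composition[1, ], c(150, 30) / 180)
  expect_equal(sum(sv$composition[1, ]), 1)
})

test_that("supervoxel grid downscales dimensions and drops partial blocks", {
  cs <- array(1L, c(1000, 1000, 3))
  sv <- build_supervoxels(cs, k_p = 1, sv_size = c(10, 10, 3))
  expect_equal(sv$grid, c(100, 100, 1))
  expect_equal(nrow(sv$composition), 100 * 100 * 1)

  # trailing partial blocks discarded: 25x25x7 -> 2x2x2 blocks
  cs2 <- array(1L, c(25, 25, 7))
  sv2 <- build_supervoxels(cs2, k_p = 1, sv_size = c(10, 10, 3))
  expect_equal(sv2$grid, c(2, 2, 2))

  # block ids follow array layout: mark one pixel block distinct
  cs3 <- array(1L, c(20, 10, 3))
  cs3[11:20, , ] <- 2L
  sv3 <- build_supervoxels(cs3, k_p = 2, sv_size = c(10, 10, 3))
  arr <- assign_sv_categories(sv3, diag(2))
  expect_equal(dim(arr), c(2, 1, 1))
  expect_equal(arr[1, 1, 1], 1L)
  expect_equal(arr[2, 1, 1], 2L)
})

test_that("megavoxel foreground rule is inclusive at the boundary", {
  # 6x6x2 block of supervoxels (72): exactly 36 foreground -> foreground
  sv_arr <- array(0L, c(6, 6, 2))
  sv_arr[seq_len(36)] <- 1L
  mv <- build_megavoxels(sv_arr, k_sv = 2, mv_size = c(6, 6, 2))
  expect_true(mv$is_foreground[1])
  expect_equal(mv$composition[1, ], c(1, 0))

  # 35 foreground -> background
  sv_arr[seq_len(36)] <- 0L
  sv_arr[seq_len(35)] <- 1L
  mv <- build_megavoxels(sv_arr, k_sv = 2, mv_size = c(6, 6, 2))
  expect_false(mv$is_foreground[1])

  # composition ignores background members: 27 cat1, 9 cat2, 36 bg
  sv_arr <- array(0L, c(6, 6, 2))
  sv_arr[seq_len(27)] <- 1L
  sv_arr[27 + seq_len(9)] <- 2L
  mv <- build_megavoxels(sv_arr, k_sv = 2, mv_size = c(6, 6, 2))
  expect_true(mv$is_foreground[1])
  expect_equal(mv$composition[1, ], c(0.75, 0.25))
})

test_that("image features normalize to 1 and count foreground megavoxels", {
  f <- compute_image_features(c(1L, 1L, 2L, 3L), k_m = 4)
  expect_equal(f$f, c(0.5, 0.25, 0.25, 0))
  expect_equal(f$mv_count, 4L)
  expect_warning(f0 <- compute_image_features(integer(0), k_m = 4),
                 "foreground")
  expect_true(all(is.nan(f0$f)))
  expect_equal(f0$mv_count, 0L)
})

test_that("seeded k-means recovers well-separated blobs", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(100, 0), 50, 2),
               matrix(rnorm(100, 10), 50, 2),
               matrix(rnorm(100, 20), 50, 2))
  truth <- rep(1:3, each = 50)
  km <- phenovoxel:::km_seeded(pts, 3, seed = 2)
  expect_equal(adjusted_rand_index(km$cluster, truth), 1)
  km2 <- phenovoxel:::km_seeded(pts, 3, seed = 2)
  expect_identical(km$centers, km2$centers)
  expect_error(phenovoxel:::km_seeded(pts[c(1, 1, 1), ], 3), "distinct")
})

test_that("training and extraction are deterministic and discriminative", {
  fx <- get_small_model()
  feats <- extract_features(fx$dataset, fx$model)
  fm <- feature_matrix(feats)
  expect_true(all(abs(rowSums(fm) - 1) < 1e-9))
  expect_true(all(feats$mv_count > 0))

  # determinism of extraction
  feats2 <- extract_features(fx$dataset, fx$model)
  expect_identical(feature_matrix(feats2), fm)

  # determinism of training given the seed
  m2 <- train_model(fx$dataset, fx$model$config, seed = 5)
  expect_identical(m2$pixel_centroids, fx$model$pixel_centroids)
  expect_identical(m2$mv_centroids, fx$model$mv_centroids)

  # the two texture classes are separated in feature space: mean
  # between-class distance exceeds mean within-class distance
  cls <- feats$class
  d <- as.matrix(dist(fm))
  same <- outer(cls, cls, "==") & upper.tri(d)
  diff <- outer(cls, cls, "!=") & upper.tri(d)
  expect_gt(mean(d[diff]), mean(d[same]))
})

test_that("features are invariant to trailing background padding", {
  fx <- get_small_model()
  id <- dataset_images(fx$dataset)[1]
  stk <- read_stack(fx$dataset, id)
  base <- phenovoxel:::stack_features(stk, fx$model)

  # pad +15 zero-intensity rows (three full supervoxel rows in y):
  # rescaled zeros sit far below both thresholds, so every added block is
  # background and must not perturb the features
  dm <- dim(stk)
  padded <- array(0, c(dm[1] + 15L, dm[2], dm[3], dm[4]))
  padded[seq_len(dm[1]), , , ] <- stk
  pad <- phenovoxel:::stack_features(padded, fx$model)
  expect_equal(pad$f, base$f, tolerance = 1e-12)
  expect_equal(pad$mv_count, base$mv_count)
})
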