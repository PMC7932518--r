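test_that("focus stacking recovers the sharp plane per region", {
  # three z-planes, each sharp (noisy texture) only in its own row band
  set.seed(41)
  stk <- array(100, c(60, 60, 3))
  bands <- list(1:20, 21:40, 41:60)
  for (z in 1:3)
    stk[bands[[z]], , z] <- 100 + matrix(runif(20 * 60, 0, 2000), 20, 60)
  fs <- focus_stack(stk)
  # evaluate away from band borders (filters smear ~half a window)
  interior <- list(1:12, 29:32, 49:60)
  for (z in 1:3) {
    hit <- mean(fs$best_plane_map[interior[[z]], ] == z)
    expect_gte(hit, 0.95)
  }
  # projected intensities are the original values at the chosen planes
  pick <- cbind(as.vector(row(fs$best_plane_map)),
                as.vector(col(fs$best_plane_map)),
                as.vector(fs$best_plane_map))
  expect_equal(as.vector(fs$best_focus_image), stk[pick])

  # constant stack: ties everywhere resolve to the lowest plane
  cst <- array(5, c(20, 20, 4))
  expect_true(all(focus_stack(cst)$best_plane_map == 1L))

  # single-plane stack is the identity, with a warning
  expect_warning(one <- focus_stack(array(1:100, c(10, 10, 1))), "single")
  expect_equal(one$best_focus_image, matrix(1:100, 10, 10))
})

test_that("segmentation finds bright regions and splits touching ones", {
  set.seed(17)
  img <- matrix(100 + runif(150 * 150, 0, 30), 150, 150)
  yy <- row(img); xx <- col(img)
  d1 <- sqrt((yy - 40)^2 + (xx - 45)^2)
  d2 <- sqrt((yy - 105)^2 + (xx - 100)^2)
  img[d1 <= 16] <- img[d1 <= 16] + 3000
  img[d2 <= 16] <- img[d2 <= 16] + 3000
  seg <- segment_organoids(img, disk_radius = 6, min_area = 300, ws_ext = 12)
  expect_equal(nrow(seg$regions), 2)
  expect_true(all(seg$regions$area > 300))
  # each planted center lies inside a segmented region and its bbox
  cent <- rbind(c(40, 45), c(105, 100))
  for (i in 1:2) {
    lb <- seg$labels[cent[i, 1], cent[i, 2]]
    expect_gt(lb, 0)
    reg <- seg$regions[seg$regions$label == lb, ]
    expect_true(reg$y0 <= cent[i, 1] && reg$y1 >= cent[i, 1] &&
                reg$x0 <= cent[i, 2] && reg$x1 >= cent[i, 2])
  }
  # labels are contiguous 1..R
  expect_setequal(setdiff(unique(as.vector(seg$labels)), 0), 1:2)

  # touching disks are separated by the watershed
  img2 <- matrix(100 + runif(150 * 150, 0, 30), 150, 150)
  d3 <- sqrt((row(img2) - 75)^2 + (col(img2) - 55)^2)
  d4 <- sqrt((row(img2) - 75)^2 + (col(img2) - 95)^2)
  img2[d3 <= 22 | d4 <= 22] <- img2[d3 <= 22 | d4 <= 22] + 3000
  seg2 <- segment_organoids(img2, disk_radius = 6, min_area = 300,
                            ws_ext = 12)
  expect_equal(nrow(seg2$regions), 2)

  # border-touching and tiny regions are dropped
  img3 <- matrix(100 + runif(100 * 100, 0, 30), 100, 100)
  d5 <- sqrt((row(img3) - 5)^2 + (col(img3) - 50)^2)   # clipped at border
  img3[d5 <= 20] <- img3[d5 <= 20] + 3000
  seg3 <- segment_organoids(img3, disk_radius = 4, min_area = 300,
                            ws_ext = 10)
  expect_equal(nrow(seg3$regions), 0)
  expect_error(segment_organoids(matrix(1, 50, 50)), "constant")
})

test_that("z-plane selection follows the focus histogram rule", {
  # n_z = 10: planes 4 (60%) and 6 (30%) exceed the 1/10 chance level
  bpm <- matrix(c(rep(4L, 60), rep(6L, 30), rep(1L, 10)), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  zr <- select_z_planes(bpm, mask, n_z = 10)
  expect_equal(zr$focus_histogram[c(1, 4, 6)], c(0.1, 0.6, 0.3))
  expect_equal(sum(zr$focus_histogram), 1)
  expect_equal(c(zr$z_lo, zr$z_hi), c(2, 8))   # [4,6] padded by 2

  # single dominant plane 7 -> [5, 9]
  bpm2 <- matrix(c(rep(7L, 95), rep(2L, 5)), 10, 10)
  zr2 <- select_z_planes(bpm2, mask, n_z = 10)
  expect_equal(c(zr2$z_lo, zr2$z_hi), c(5, 9))

  # clamped at the stack boundary
  bpm3 <- matrix(1L, 10, 10)
  zr3 <- select_z_planes(bpm3, mask, n_z = 10)
  expect_equal(c(zr3$z_lo, zr3$z_hi), c(1, 3))

  # exactly uniform histogram: no plane beats chance, fall back to argmax
  bpm4 <- matrix(rep(1:10, 10), 10, 10)
  zr4 <- select_z_planes(bpm4, mask, n_z = 10)
  expect_equal(c(zr4$z_lo, zr4$z_hi), c(1, 3))

  expect_error(select_z_planes(bpm, mask & FALSE, 10), "empty")
})

test_that("cropping honours the bounding box and clamps to the stack", {
  stk <- array(seq_len(20 * 20 * 6 * 2), c(20, 20, 6, 2))
  reg <- list(y0 = 3, y1 = 8, x0 = 5, x1 = 14, z_lo = 2, z_hi = 5)
  cr <- crop_organoid(stk, reg)
  expect_equal(dim(cr), c(6, 10, 4, 2))
  expect_equal(cr[1, 1, 1, 1], stk[3, 5, 2, 1])
  expect_equal(cr[6, 10, 4, 2], stk[8, 14, 5, 2])
  # out-of-range requests are clamped
  reg2 <- list(y0 = -5, y1 = 100, x0 = 1, x1 = 20, z_lo = 5, z_hi = 99)
  expect_equal(dim(crop_organoid(stk, reg2)), c(20, 20, 2, 2))
  # 3D input stays 3D
  expect_equal(dim(crop_organoid(stk[, , , 1], reg)), c(6, 10, 4))
})

test_that("morphology features match analytic shapes", {
  # filled disk, radius 20
  m <- matrix(0, 61, 61)
  d <- sqrt((row(m) - 31)^2 + (col(m) - 31)^2)
  m[d <= 20] <- 1
  f <- morphology_2d(m)
  expect_equal(f[["area"]], sum(m))
  expect_equal(f[["area"]] / (pi * 20^2), 1, tolerance = 0.03)
  expect_equal(f[["major_axis"]], 40, tolerance = 0.05 * 40)
  expect_equal(f[["major_axis"]], f[["minor_axis"]], tolerance = 0.02 * 40)
  expect_lt(f[["eccentricity"]], 0.25)
  expect_equal(f[["equivalent_diameter"]], 40, tolerance = 0.03 * 40)
  expect_gt(f[["solidity"]], 0.97)
  expect_equal(f[["extent"]], pi / 4, tolerance = 0.05)

  # axis-aligned 10 x 30 rectangle: uniform-distribution moments
  r <- matrix(0, 40, 50)
  r[11:20, 11:40] <- 1
  fr <- morphology_2d(r)
  expect_equal(fr[["area"]], 300)
  expect_equal(fr[["extent"]], 1)
  expect_equal(fr[["solidity"]], 1)
  expect_equal(fr[["major_axis"]], 4 * sqrt(30^2 / 12), tolerance = 1e-9)
  expect_equal(fr[["minor_axis"]], 4 * sqrt(10^2 / 12), tolerance = 1e-9)
  expect_equal(fr[["eccentricity"]], sqrt(1 - 10^2 / 30^2), tolerance = 1e-9)
  expect_equal(fr[["perimeter"]], 2 * 30 + 2 * 10 - 4)

  # plus shape is not convex: solidity drops below 1
  p <- matrix(0, 31, 31)
  p[14:18, 6:26] <- 1
  p[6:26, 14:18] <- 1
  fp <- morphology_2d(p)
  expect_lt(fp[["solidity"]], 0.9)
  expect_gt(fp[["convex_area"]], fp[["area"]])
  expect_error(morphology_2d(matrix(0, 5, 5)), "empty")
})

test_that("hollowness is elevated for shells and ~1 for solid objects", {
  m <- matrix(0, 81, 81)
  d <- sqrt((row(m) - 41)^2 + (col(m) - 41)^2)
  m[d <= 30] <- 1
  shell_img <- matrix(10, 81, 81)
  shell_img[m > 0 & d >= 20] <- 200    # bright rim, dim lumen
  expect_gt(hollowness(m, shell_img, ring_width = 10), 3)

  solid_img <- matrix(150, 81, 81)
  expect_equal(hollowness(m, solid_img, ring_width = 10), 1)

  # erosion that removes everything yields NA with a warning
  expect_warning(h <- hollowness(m, shell_img, ring_width = 40), "empty")
  expect_true(is.na(h))
})

test_that("end-to-end localization recovers planted organoids", {
  spec <- organoid_scene_spec(
    centers = rbind(c(110, 110), c(280, 290)),
    radii = c(55, 65), focus_lo = c(3, 9), focus_hi = c(5, 11),
    size = c(400L, 400L), n_z = 15L)
  scene <- generate_organoid_scene(spec, seed = 2)
  stk <- array(scene$stack, c(dim(scene$stack), 1))
  found <- locate_organoids(stk, disk_radius = 20, min_area = 2000,
                            ws_ext = 40)
  expect_equal(length(found), 2)
  # match found regions to planted organoids by center containment
  for (i in 1:2) {
    ctr <- spec$centers[i, ]
    j <- which(vapply(found, function(o)
      o$y0 <= ctr[1] && o$y1 >= ctr[1] && o$x0 <= ctr[2] && o$x1 >= ctr[2],
      TRUE))
    expect_length(j, 1)
    o <- found[[j]]
    # selected z-range overlaps the planted focus range
    expect_lte(o$z_lo, spec$focus_hi[i])
    expect_gte(o$z_hi, spec$focus_lo[i])
    # disk-mean smoothing (radius 20) can dilate the planted disk by up to
    # the kernel radius but never beyond, and should not shrink it much
    ratio <- o$morphology[["area"]] / (pi * spec$radii[i]^2)
    expect_gt(ratio, 0.8)
    expect_lt(ratio, (1 + 20 / spec$radii[i])^2)
    # the rendered shells are hollow
    expect_gt(o$hollowness, 1.2)
  }
})
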