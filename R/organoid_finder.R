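#' Focus stacking (extended depth of field)
#'
#' Per z-slice: 3x3 median filter, 11x11 local standard deviation, then the
#' Sobel gradient magnitude of the local-deviation image. Per XY pixel the
#' best-focus plane is the z with the maximum gradient magnitude (ties to
#' the lowest z); the projected image takes the original, pre-filter
#' intensity at that plane.
#'
#' @param stack Numeric 3D array `[y, x, z]` (nuclear channel).
#' @param median_size Median-filter kernel edge (odd, default 3).
#' @param sd_window Local standard-deviation window edge (odd, default 11).
#' @return List: `best_focus_image` (2D) and `best_plane_map` (2D integer,
#'   values in `1..n_z`).
#' @export
focus_stack <- function(stack, median_size = 3L, sd_window = 11L) {
  dm <- dim(stack)
  n_z <- dm[3]
  if (n_z < 2L) {
    warnf("single-plane stack: focus stacking is the identity")
    return(list(best_focus_image = stack[, , 1],
                best_plane_map = matrix(1L, dm[1], dm[2])))
  }
  best_g <- matrix(-Inf, dm[1], dm[2])
  best_z <- matrix(1L, dm[1], dm[2])
  for (zi in seq_len(n_z)) {
    g <- slice_focus_measure(stack[, , zi], median_size, sd_window)
    better <- g > best_g          # strict: ties keep the lowest z
    best_g[better] <- g[better]
    best_z[better] <- zi
  }
  proj <- matrix(stack[cbind(as.vector(row(best_z)), as.vector(col(best_z)),
                             as.vector(best_z))], dm[1], dm[2])
  list(best_focus_image = proj, best_plane_map = best_z)
}

slice_focus_measure <- function(plane, median_size, sd_window) {
  rng <- range(plane)
  norm <- if (rng[2] > rng[1]) (plane - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(plane), ncol(plane))
  med <- EBImage::medianFilter(norm, (median_size - 1L) %/% 2L)
  med <- med * (rng[2] - rng[1]) + rng[1]
  box <- matrix(1 / sd_window^2, sd_window, sd_window)
  m1 <- EBImage::filter2(med, box, boundary = "replicate")
  m2 <- EBImage::filter2(med^2, box, boundary = "replicate")
  sdl <- sqrt(pmax(m2 - m1^2, 0))
  sobel_gradient(sdl)
}

sobel_gradient <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gy <- EBImage::filter2(img, kx, boundary = "replicate")
  gx <- EBImage::filter2(img, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Segment organoid contours in a focus-stacked image
#'
#' Disk-mean smoothing (radius 75 by default), maximum correlation
#' thresholding, hole filling, then a watershed split of touching regions
#' seeded from the distance transform. Regions touching the image border or
#' smaller than `min_area` pixels are dropped; labels are relabeled
#' contiguously `1..R`.
#'
#' @param best_focus_image Numeric 2D matrix (non-constant).
#' @param disk_radius Smoothing disk radius in pixels.
#' @param min_area Minimum region area in pixels.
#' @param drop_border Drop regions touching the image border.
#' @param ws_ext Watershed neighborhood radius used when searching for seed
#'   maxima (about half the minimum seed separation).
#' @param ws_tolerance Watershed merge tolerance on the distance transform.
#' @return List: `labels` (integer matrix, 0 = background) and `regions`
#'   data frame (`label`, inclusive 1-based `y0, y1, x0, x1`, `area`).
#'   Empty result (zero rows) when no foreground survives.
#' @export
segment_organoids <- function(best_focus_image, disk_radius = 75L,
                              min_area = 500L, drop_border = TRUE,
                              ws_ext = 25L, ws_tolerance = 1) {
  img <- best_focus_image
  if (max(img) <= min(img)) stopf("constant image: nothing to segment")
  side <- 2L * disk_radius + 1L
  disk <- EBImage::makeBrush(side, shape = "disc")
  disk <- disk / sum(disk)
  smooth <- EBImage::filter2(img, disk, boundary = "replicate")
  thr <- mct_threshold(smooth)
  mask <- smooth >= thr
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                regions = data.frame(label = integer(), y0 = integer(),
                                     y1 = integer(), x0 = integer(),
                                     x1 = integer(), area = integer()))
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask * 1)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = ws_tolerance,
                                                  ext = ws_ext))
  keep <- integer(0)
  for (lb in seq_len(max(labels))) {
    idx <- which(labels == lb, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    if (drop_border &&
        (min(idx[, 1]) == 1L || min(idx[, 2]) == 1L ||
         max(idx[, 1]) == nrow(img) || max(idx[, 2]) == ncol(img))) next
    keep <- c(keep, lb)
  }
  if (length(keep) == 0L) return(empty)
  out <- matrix(0L, nrow(img), ncol(img))
  regions <- NULL
  for (i in seq_along(keep)) {
    idx <- which(labels == keep[i], arr.ind = TRUE)
    out[idx] <- i
    regions <- rbind(regions, data.frame(
      label = i, y0 = min(idx[, 1]), y1 = max(idx[, 1]),
      x0 = min(idx[, 2]), x1 = max(idx[, 2]), area = nrow(idx)))
  }
  list(labels = out, regions = regions)
}

#' Select the z-range of an organoid from its best-focus planes
#'
#' The normalized histogram of best-focus plane indices inside the organoid
#' mask measures each plane's contribution; with `n_z` planes, any plane
#' whose fraction exceeds `1/n_z` (the random chance of being in focus) is
#' "in focus". The selected range spans the in-focus planes, padded by `pad`
#' planes on each side and clamped to `[1, n_z]`.
#'
#' @param best_plane_map Integer 2D map from [focus_stack()].
#' @param mask Logical/0-1 2D mask of the organoid (nonempty).
#' @param n_z Number of z planes.
#' @param pad Padding planes per side (default 2).
#' @return List: `z_lo`, `z_hi`, `focus_histogram` (length `n_z`, sums
#'   to 1).
#' @export
select_z_planes <- function(best_plane_map, mask, n_z, pad = 2L) {
  sel <- best_plane_map[mask > 0]
  if (length(sel) == 0L) stopf("empty organoid mask")
  h <- tabulate(sel, nbins = n_z) / length(sel)
  infocus <- which(h > 1 / n_z)
  if (length(infocus) == 0L) infocus <- which.max(h)
  list(z_lo = max(1L, min(infocus) - pad),
       z_hi = min(n_z, max(infocus) + pad),
       focus_histogram = h)
}

#' Crop an organoid's 3D bounding box from a multichannel stack
#'
#' All channels are cropped identically using the XY bounding box and the
#' selected z-range (clamped to the stack).
#'
#' @param stack Numeric 4D `[y, x, z, channel]` (or 3D) array.
#' @param region List with `y0, y1, x0, x1` (inclusive, 1-based) and
#'   `z_lo, z_hi`.
#' @return Cropped stack of shape
#'   `(y1-y0+1, x1-x0+1, z_hi-z_lo+1, n_channels)`.
#' @export
crop_organoid <- function(stack, region) {
  d3 <- length(dim(stack)) == 3L
  if (d3) dim(stack) <- c(dim(stack), 1L)
  dm <- dim(stack)
  ys <- max(1L, region$y0):min(dm[1], region$y1)
  xs <- max(1L, region$x0):min(dm[2], region$x1)
  zs <- max(1L, region$z_lo):min(dm[3], region$z_hi)
  out <- stack[ys, xs, zs, , drop = FALSE]
  if (d3) dim(out) <- dim(out)[1:3]
  out
}

#' 2D morphological features of a mask
#'
#' Nine features: area, major/minor axis length and eccentricity of the
#' ellipse with the same normalized second central moments, equivalent
#' diameter, solidity (area / convex area), extent (area / bounding-box
#' area), convex area, and perimeter (count of mask pixels on the region
#' border).
#'
#' @param mask Logical/0-1 2D matrix (nonempty).
#' @return Named numeric vector.
#' @export
morphology_2d <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("empty mask")
  area <- nrow(idx)
  yc <- idx[, 1] - mean(idx[, 1])
  xc <- idx[, 2] - mean(idx[, 2])
  # normalized second central moments (+1/12 for the unit-pixel extent)
  myy <- mean(yc^2) + 1 / 12
  mxx <- mean(xc^2) + 1 / 12
  mxy <- mean(xc * yc)
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- sqrt(1 - l2 / l1)
  eqd <- sqrt(4 * area / pi)
  bbox_area <- (max(idx[, 1]) - min(idx[, 1]) + 1) *
    (max(idx[, 2]) - min(idx[, 2]) + 1)
  conv <- convex_area(idx)
  per <- perimeter_pixels(mask)
  c(area = area, major_axis = major, minor_axis = minor, eccentricity = ecc,
    equivalent_diameter = eqd, solidity = area / conv,
    extent = area / bbox_area, convex_area = conv, perimeter = per)
}

# pixels whose centers lie in the convex hull of the mask pixel centers
convex_area <- function(idx) {
  if (nrow(idx) < 3L) return(nrow(idx))
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[h, 2]; hy <- idx[h, 1]
  if (length(h) < 3L) return(nrow(idx))
  ys <- min(idx[, 1]):max(idx[, 1])
  xs <- min(idx[, 2]):max(idx[, 2])
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(gx))
  nh <- length(h)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
    inside <- inside & cross <= 1e-9
  }
  sum(inside)
}

perimeter_pixels <- function(mask) {
  m <- (mask > 0) * 1L
  pad <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  nb <- pad[1:nrow(m), 2:(ncol(m) + 1)] + pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] +
    pad[2:(nrow(m) + 1), 1:ncol(m)] + pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  sum(core == 1L & nb < 4L)
}

#' Hollowness of an organoid
#'
#' The mask is split into an outer ring (`ring_width` pixels wide, by
#' erosion) and a central region; the value is the mean ring intensity
#' divided by the mean central intensity on the middle z-slice. Elevated for
#' hollow acini (bright rim, dim lumen). If the central region is empty the
#' result is `NA` with a warning.
#'
#' @param mask Logical/0-1 2D matrix.
#' @param mid_slice_intensity Numeric 2D matrix of mid-slice intensities.
#' @param ring_width Ring width in pixels (default 40).
#' @return Scalar ratio (or `NA`).
#' @export
hollowness <- function(mask, mid_slice_intensity, ring_width = 40L) {
  m <- (mask > 0) * 1
  central <- EBImage::erode(m, EBImage::makeBrush(2L * ring_width + 1L,
                                                  shape = "disc"))
  if (sum(central) == 0) {
    warnf("central region empty after erosion: hollowness undefined")
    return(NA_real_)
  }
  ring <- m > 0 & !(central > 0)
  mean(mid_slice_intensity[ring]) / mean(mid_slice_intensity[central > 0])
}

#' Locate organoids in a multichannel stack
#'
#' End-to-end convenience: focus-stack the nuclear channel, segment organoid
#' contours, and per region select the z-range and compute 2D morphology and
#' hollowness. Optionally drops regions whose mean nuclear intensity falls
#' below `min_mean_intensity`.
#'
#' @param stack Numeric 4D `[y, x, z, channel]` array.
#' @param nuclear_channel Channel index used for localization.
#' @param pad z-padding per side.
#' @param min_mean_intensity Optional mean-intensity floor (default `NULL`,
#'   off).
#' @param ... Passed to [segment_organoids()].
#' @return List of `pvx_organoid` regions: `label`, bbox (`y0,y1,x0,x1`),
#'   `z_lo`, `z_hi`, `mask`, `focus_histogram`, `morphology`, `hollowness`.
#' @export
locate_organoids <- function(stack, nuclear_channel = 1L, pad = 2L,
                             min_mean_intensity = NULL, ...) {
  nuc <- stack[, , , nuclear_channel]
  fs <- focus_stack(nuc)
  seg <- segment_organoids(fs$best_focus_image, ...)
  n_z <- dim(nuc)[3]
  out <- list()
  for (i in seq_len(nrow(seg$regions))) {
    reg <- seg$regions[i, ]
    mask <- seg$labels == reg$label
    if (!is.null(min_mean_intensity) &&
        mean(fs$best_focus_image[mask]) < min_mean_intensity) next
    zr <- select_z_planes(fs$best_plane_map, mask, n_z, pad = pad)
    mid <- nuc[, , (zr$z_lo + zr$z_hi) %/% 2L]
    sub_mask <- mask[reg$y0:reg$y1, reg$x0:reg$x1, drop = FALSE]
    region <- list(label = reg$label, y0 = reg$y0, y1 = reg$y1,
                   x0 = reg$x0, x1 = reg$x1,
                   z_lo = zr$z_lo, z_hi = zr$z_hi, mask = sub_mask,
                   focus_histogram = zr$focus_histogram,
                   morphology = morphology_2d(sub_mask),
                   hollowness = suppressWarnings(
                     hollowness(mask, mid)))
    class(region) <- "pvx_organoid"
    out[[length(out) + 1L]] <- region
  }
  out
}
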