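#' Texture-class specification for synthetic stacks
#'
#' Describes one phenotype class: per channel a mixture of blob intensity
#' levels with weights, a target foreground density, a blob radius range, a
#' noise level and a class label. Stands in for a treatment-induced
#' phenotype when testing the feature hierarchy.
#'
#' @param levels List (one entry per channel) of two-column matrices /
#'   data frames `(level, weight)`; weights must sum to 1.
#' @param density Target foreground voxel fraction in `(0, 0.6]`.
#' @param radius_range Blob radius range in pixels (positive).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param bg_level Background intensity level.
#' @param label Class label string.
#' @return A `pvx_texture_spec` list.
#' @export
texture_spec <- function(levels, density = 0.15, radius_range = c(4, 8),
                         noise_sd = 0, bg_level = 50, label = "class") {
  levels <- lapply(levels, function(l) {
    l <- as.matrix(as.data.frame(l))
    if (ncol(l) != 2L) stopf("each channel needs (level, weight) columns")
    if (abs(sum(l[, 2]) - 1) > 1e-9) stopf("mixture weights must sum to 1")
    l
  })
  if (any(radius_range <= 0)) stopf("radii must be positive")
  if (density <= 0 || density > 0.6)
    stopf("infeasible density %.3g (must be in (0, 0.6])", density)
  structure(list(levels = levels, density = density,
                 radius_range = radius_range, noise_sd = noise_sd,
                 bg_level = bg_level, label = label),
            class = "pvx_texture_spec")
}

#' Generate a textured multichannel 3D stack
#'
#' Bright spherical blobs on a dark background. Each blob draws, per
#' channel, one intensity level from the class's mixture; blobs are placed
#' at random until the target foreground density is reached. Deterministic
#' per seed; the ground-truth foreground mask is returned alongside.
#'
#' @param spec A [texture_spec()].
#' @param shape Stack shape `(y, x, z)`.
#' @param seed RNG seed.
#' @return List: `stack` (4D `[y, x, z, channel]`), `mask` (logical 3D
#'   foreground), `label`.
#' @export
generate_texture_stack <- function(spec, shape = c(60L, 60L, 6L), seed = 0L) {
  n_ch <- length(spec$levels)
  dm <- as.integer(shape)
  with_seed(seed, {
    stack <- array(spec$bg_level, c(dm, n_ch))
    mask <- array(FALSE, dm)
    target <- spec$density * prod(dm)
    tries <- 0L
    while (sum(mask) < target && tries < 10000L) {
      tries <- tries + 1L
      r <- runif(1, spec$radius_range[1], spec$radius_range[2])
      cy <- runif(1, 1, dm[1]); cx <- runif(1, 1, dm[2])
      cz <- runif(1, 1, dm[3])
      ys <- max(1, floor(cy - r)):min(dm[1], ceiling(cy + r))
      xs <- max(1, floor(cx - r)):min(dm[2], ceiling(cx + r))
      zs <- max(1, floor(cz - r / 2)):min(dm[3], ceiling(cz + r / 2))
      lv <- vapply(spec$levels, function(l)
        l[sample.int(nrow(l), 1L, prob = l[, 2]), 1], numeric(1))
      for (zi in zs) {
        dz2 <- ((zi - cz) * 2)^2      # z compressed: blobs are oblate
        d2 <- outer((ys - cy)^2, (xs - cx)^2, "+") + dz2
        hit <- d2 <= r^2
        if (!any(hit)) next
        sub <- cbind(ys[row(hit)[hit]], xs[col(hit)[hit]], zi)
        mask[cbind(sub[, 1], sub[, 2], sub[, 3])] <- TRUE
        for (ci in seq_len(n_ch))
          stack[cbind(sub[, 1], sub[, 2], sub[, 3], ci)] <- lv[ci]
      }
    }
    if (sum(mask) < target * 0.5)
      stopf("could not reach the requested foreground density")
    if (spec$noise_sd > 0)
      stack <- stack + array(rnorm(length(stack), 0, spec$noise_sd),
                             dim(stack))
    list(stack = stack, mask = mask, label = spec$label)
  })
}

#' Generate a dataset of texture stacks on disk
#'
#' Renders `n_per_class` stacks per class spec, writes one TIFF per
#' (channel, z) plus a metadata table with a `class` column, and returns the
#' loaded `pvx_dataset`. Image ids are `<label>_<i>`.
#'
#' @param specs List of [texture_spec()] objects.
#' @param n_per_class Stacks per class.
#' @param dir Output directory.
#' @param shape Stack shape `(y, x, z)`.
#' @param seed Base RNG seed (stack `i` of class `j` uses
#'   `seed + 1000 j + i`).
#' @return A `pvx_dataset` with metadata column `class`.
#' @export
generate_texture_dataset <- function(specs, n_per_class, dir,
                                     shape = c(60L, 60L, 6L), seed = 0L) {
  rows <- NULL
  for (j in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      g <- generate_texture_stack(specs[[j]], shape,
                                  seed = seed + 1000L * j + i)
      id <- sprintf("%s_%03d", specs[[j]]$label, i)
      r <- write_stack_planes(g$stack, dir, id)
      r$class <- specs[[j]]$label
      rows <- rbind(rows, r)
    }
  }
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(rows, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_dataset(meta_path, base_dir = "")
}

#' Organoid scene specification
#'
#' @param centers `n x 2` matrix of (y, x) organoid centers.
#' @param radii Radius per organoid (pixels).
#' @param shell_frac Shell thickness as a fraction of the radius.
#' @param focus_lo,focus_hi In-focus z-range per organoid (within
#'   `1..n_z`).
#' @param size XY scene size `(y, x)`.
#' @param n_z Number of z planes.
#' @param bg_level Background intensity.
#' @param intensity Shell peak intensity.
#' @return A `pvx_organoid_spec` list.
#' @export
organoid_scene_spec <- function(centers, radii, shell_frac = 0.35,
                                focus_lo, focus_hi, size = c(400L, 400L),
                                n_z = 15L, bg_level = 100, intensity = 4000) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(length(radii) == n, length(focus_lo) == n, length(focus_hi) == n)
  if (any(focus_lo < 1L | focus_hi > n_z | focus_lo > focus_hi))
    stopf("focus ranges must lie within [1, n_z]")
  if (any(centers[, 1] - radii < 1 | centers[, 1] + radii > size[1] |
          centers[, 2] - radii < 1 | centers[, 2] + radii > size[2]))
    stopf("organoids must lie within the scene bounds")
  if (n > 1L) {
    dd <- as.matrix(dist(centers))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (dd[i, j] < radii[i] + radii[j])
        stopf("organoids %d and %d overlap beyond tolerance", i, j)
  }
  structure(list(centers = centers, radii = radii, shell_frac = shell_frac,
                 focus_lo = as.integer(focus_lo),
                 focus_hi = as.integer(focus_hi),
                 size = as.integer(size), n_z = as.integer(n_z),
                 bg_level = bg_level, intensity = intensity),
            class = "pvx_organoid_spec")
}

#' Generate a synthetic organoid scene
#'
#' Each organoid is rendered as a textured bright shell (annulus) around a
#' dimmer interior. Within its in-focus z-range the texture is sharp; on
#' other planes it is Gaussian-blurred with a width proportional to the
#' z-distance from the focus range. Ground truth (label map, per-organoid
#' masks and focus ranges) is emitted alongside.
#'
#' @param spec An [organoid_scene_spec()].
#' @param seed RNG seed.
#' @return List: `stack` (3D `[y, x, z]` nuclear channel), `truth` with
#'   `labels` (2D), `masks`, `focus_lo`, `focus_hi`, `centers`, `radii`.
#' @export
generate_organoid_scene <- function(spec, seed = 0L) {
  dm <- c(spec$size, spec$n_z)
  n <- nrow(spec$centers)
  with_seed(seed, {
    stack <- array(spec$bg_level, dm)
    stack <- stack + array(abs(rnorm(prod(dm), 0, spec$bg_level * 0.1)), dm)
    labels <- matrix(0L, dm[1], dm[2])
    masks <- vector("list", n)
    yy <- matrix(seq_len(dm[1]), dm[1], dm[2])
    xx <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
    for (i in seq_len(n)) {
      r <- spec$radii[i]
      d <- sqrt((yy - spec$centers[i, 1])^2 + (xx - spec$centers[i, 2])^2)
      disk <- d <= r
      shell <- disk & d >= r * (1 - spec$shell_frac)
      masks[[i]] <- disk
      labels[disk] <- i
      # speckled texture so focus measures have local contrast
      tex <- matrix(0, dm[1], dm[2])
      tex[shell] <- spec$intensity * (0.5 + runif(sum(shell)))
      tex[disk & !shell] <- spec$intensity * 0.12 *
        (0.5 + runif(sum(disk & !shell)))
      for (zi in seq_len(spec$n_z)) {
        dz <- max(0, spec$focus_lo[i] - zi, zi - spec$focus_hi[i])
        pl <- if (dz == 0) tex
              else as.matrix(EBImage::gblur(tex, sigma = 1.5 * dz + 0.5))
        fade <- 1 / (1 + 0.4 * dz)
        stack[, , zi] <- stack[, , zi] + pl * fade
      }
    }
    list(stack = stack,
         truth = list(labels = labels, masks = masks,
                      focus_lo = spec$focus_lo, focus_hi = spec$focus_hi,
                      centers = spec$centers, radii = spec$radii))
  })
}

#' Generate an isotropic Gaussian mixture dataset
#'
#' Cluster means are drawn uniformly on `[0, 10]` per dimension and cluster
#' standard deviations uniformly on `[0.5, 1.5]`; points are isotropic
#' Gaussian draws. Used to validate automated cluster-number estimation.
#'
#' @param dims Dimensionality (>= 1).
#' @param k Number of clusters (>= 2).
#' @param n_per_cluster Points per cluster (default 30).
#' @param seed RNG seed.
#' @param mean_range,sd_range Uniform ranges for cluster means and sds.
#' @return List: `points` (`n x dims`), `labels`, `means`, `sds`.
#' @export
generate_gaussian_mixture <- function(dims, k, n_per_cluster = 30L,
                                      seed = 0L, mean_range = c(0, 10),
                                      sd_range = c(0.5, 1.5)) {
  if (dims < 1L) stopf("dims must be >= 1")
  if (k < 2L) stopf("k must be >= 2")
  with_seed(seed, {
    means <- matrix(runif(k * dims, mean_range[1], mean_range[2]), k, dims)
    sds <- runif(k, sd_range[1], sd_range[2])
    pts <- do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(n_per_cluster * dims, 0, sds[i]), n_per_cluster, dims) +
        matrix(means[i, ], n_per_cluster, dims, byrow = TRUE)))
    list(points = pts, labels = rep(seq_len(k), each = n_per_cluster),
         means = means, sds = sds)
  })
}
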