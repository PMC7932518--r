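#' Training-set intensity scaling parameters
#'
#' For every training image and channel the 5% and 95% intensity quantiles are
#' computed over all voxels of that image; the per-channel scaling bounds
#' `chmin`/`chmax` are the medians of those per-image quantiles across the
#' training images. Scaling can be computed per group (e.g. per plate) by
#' naming a metadata column, which yields one `(chmin, chmax)` pair per
#' (channel, group); images are then rescaled with their own group's
#' parameters so between-image intensity differences within a group are
#' preserved.
#'
#' @param training A `pvx_dataset` of training images.
#' @param group_by Optional metadata column name defining scaling groups.
#' @param probs Lower/upper quantiles (default `c(0.05, 0.95)`).
#' @return A `pvx_scaling` object: per group, `chmin` and `chmax` numeric
#'   vectors indexed by channel, plus a `degenerate` flag per channel where
#'   `chmin == chmax`.
#' @export
compute_scaling_params <- function(training, group_by = NULL,
                                   probs = c(0.05, 0.95)) {
  ids <- dataset_images(training)
  if (length(ids) == 0L) stopf("empty training set")
  meta <- image_metadata(training)
  if (!is.null(group_by)) {
    if (!group_by %in% names(meta))
      stopf("scaling group column '%s' not in metadata", group_by)
    grp <- setNames(meta[[group_by]], meta$image_id)
  } else {
    grp <- setNames(rep("all", length(ids)), ids)
  }
  channels <- sort(unique(training$channel))
  groups <- list()
  for (g in unique(grp)) {
    gids <- names(grp)[grp == g]
    qlo <- matrix(NA_real_, length(gids), length(channels))
    qhi <- qlo
    for (i in seq_along(gids)) {
      stk <- read_stack(training, gids[i])
      for (ci in seq_along(channels)) {
        q <- quantile(stk[, , , ci], probs, names = FALSE, type = 7)
        qlo[i, ci] <- q[1]
        qhi[i, ci] <- q[2]
      }
    }
    chmin <- apply(qlo, 2, median)
    chmax <- apply(qhi, 2, median)
    deg <- chmax <= chmin
    if (any(deg))
      warnf("degenerate channel(s) %s in scaling group '%s' (chmin == chmax)",
            paste(channels[deg], collapse = ","), g)
    groups[[as.character(g)]] <- list(chmin = chmin, chmax = chmax,
                                      degenerate = deg)
  }
  structure(list(group_by = group_by, groups = groups, channels = channels),
            class = "pvx_scaling")
}

scaling_for_image <- function(scaling, dataset, image_id) {
  if (is.null(scaling$group_by)) return(scaling$groups[[1]])
  meta <- image_metadata(dataset)
  g <- as.character(meta[[scaling$group_by]][meta$image_id == image_id][1])
  sg <- scaling$groups[[g]]
  if (is.null(sg)) stopf("no scaling parameters for group '%s'", g)
  sg
}

#' Rescale a stack's intensities
#'
#' Per channel, `(I - chmin) / (chmax - chmin)` — a linear, order-preserving
#' map. Values are deliberately not clipped to `[0, 1]`; downstream
#' thresholding tolerates values outside the unit interval.
#'
#' @param stack Numeric 4D array `[y, x, z, channel]`.
#' @param params A `pvx_scaling` object or a single group's
#'   `list(chmin, chmax)`.
#' @param group Group name when `params` is a grouped `pvx_scaling` (ignored
#'   otherwise).
#' @return Rescaled stack, same shape.
#' @export
rescale_intensities <- function(stack, params, group = NULL) {
  if (inherits(params, "pvx_scaling")) {
    params <- if (is.null(params$group_by)) params$groups[[1]]
              else params$groups[[as.character(group)]]
    if (is.null(params)) stopf("unknown scaling group")
  }
  n_ch <- dim(stack)[4]
  if (length(params$chmin) < n_ch)
    stopf("scaling parameters cover %d channel(s), stack has %d",
          length(params$chmin), n_ch)
  for (ci in seq_len(n_ch)) {
    span <- params$chmax[ci] - params$chmin[ci]
    if (span <= 0)
      stopf("degenerate channel %d: chmax == chmin, cannot rescale", ci)
    stack[, , , ci] <- (stack[, , , ci] - params$chmin[ci]) / span
  }
  stack
}

#' Maximum correlation threshold of a 2D plane
#'
#' Scans a grid of candidate thresholds (evenly spaced between the plane's
#' minimum and maximum) and returns the candidate maximizing the Pearson
#' correlation between the binarized plane (`intensity >= T`) and the original
#' intensities. Ties are broken to the smallest threshold. Candidates whose
#' mask is constant (all foreground / all background) carry no correlation and
#' are skipped.
#'
#' @param plane Numeric 2D matrix (or vector) with at least two distinct
#'   values.
#' @param n_candidates Number of grid levels (default 256).
#' @return The selected threshold (scalar).
#' @export
mct_threshold <- function(plane, n_candidates = 256L) {
  v <- as.numeric(plane)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stopf("constant plane: no valid threshold")
  cand <- seq(lo, hi, length.out = n_candidates)
  n <- length(v)
  asc <- sort(v)
  cs <- cumsum(asc)
  tot <- cs[n]
  mu <- tot / n
  sdv <- sqrt(sum((v - mu)^2) / n)
  n_less <- findInterval(cand, asc, left.open = TRUE)  # count of v < T
  n1 <- n - n_less
  s1 <- tot - ifelse(n_less > 0, cs[pmax(n_less, 1L)], 0)
  p1 <- n1 / n
  r <- (s1 / n - mu * p1) / (sdv * sqrt(p1 * (1 - p1)))
  r[p1 <= 0 | p1 >= 1] <- -Inf
  cand[which.max(r)]
}

#' Aggregate per-slice thresholds over a training set
#'
#' [mct_threshold()] is run on every z-slice of every (rescaled) training
#' image, per channel. The stored distribution's median is the default
#' threshold; `quantile_choice` picks another quantile within the
#' interquartile range (0.25 = Q1, 0.75 = Q3).
#'
#' @param training A `pvx_dataset`.
#' @param scaling A `pvx_scaling` from [compute_scaling_params()].
#' @param quantile_choice Fraction in `[0.25, 0.75]` (default 0.5, the
#'   median).
#' @return A `pvx_thresholds` object: per channel the active threshold `t`
#'   and the training-distribution quartiles `q1`, `median`, `q3`.
#' @export
aggregate_thresholds <- function(training, scaling, quantile_choice = 0.5) {
  if (quantile_choice < 0.25 || quantile_choice > 0.75)
    stopf("quantile_choice must lie in [0.25, 0.75]")
  channels <- sort(unique(training$channel))
  vals <- vector("list", length(channels))
  for (id in dataset_images(training)) {
    stk <- read_stack(training, id)
    meta <- image_metadata(training)
    g <- if (is.null(scaling$group_by)) NULL
         else meta[[scaling$group_by]][meta$image_id == id][1]
    stk <- rescale_intensities(stk, scaling, group = g)
    for (ci in seq_along(channels)) {
      for (zi in seq_len(dim(stk)[3])) {
        pl <- stk[, , zi, ci]
        if (max(pl) > min(pl))
          vals[[ci]] <- c(vals[[ci]], mct_threshold(pl))
      }
    }
  }
  if (all(lengths(vals) == 0L))
    stopf("all training slices are constant: no thresholds")
  t_active <- q1 <- med <- q3 <- numeric(length(channels))
  for (ci in seq_along(channels)) {
    x <- vals[[ci]]
    if (length(x) == 0L) stopf("channel %d: all slices constant", channels[ci])
    qq <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    q1[ci] <- qq[1]; med[ci] <- qq[2]; q3[ci] <- qq[3]
    t_active[ci] <- quantile(x, quantile_choice, names = FALSE, type = 7)
  }
  structure(list(t = t_active, q1 = q1, median = med, q3 = q3,
                 quantile_choice = quantile_choice, channels = channels),
            class = "pvx_thresholds")
}

#' Additive Gaussian noise (robustness evaluation)
#'
#' Adds i.i.d. zero-mean Gaussian noise to every voxel of every channel.
#' Evaluation-only: never part of the default feature-extraction path.
#'
#' @param stack Numeric array.
#' @param sigma Noise standard deviation (intensity units, `>= 0`).
#' @param seed RNG seed (reproducible; caller's RNG state is untouched).
#' @return Noisy stack, same shape.
#' @export
add_gaussian_noise <- function(stack, sigma, seed = 0L) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(stack)
  noise <- with_seed(seed, rnorm(length(stack), 0, sigma))
  stack + array(noise, dim(stack))
}

gauss_kernel_1d <- function(len, sigma) {
  r <- (len - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Truncated 3D Gaussian blur (robustness evaluation)
#'
#' Separable Gaussian smoothing with a truncated kernel, default
#' 21 x 21 x 5 voxels (y, x, z). Borders are handled by replication so mean
#' intensity is conserved away from the edges.
#'
#' @param stack 3D `[y, x, z]` or 4D `[y, x, z, channel]` numeric array.
#' @param sigma Gaussian standard deviation (> 0), shared by all axes.
#' @param kernel_shape Integer `(ky, kx, kz)` kernel extent; must fit within
#'   the stack.
#' @return Blurred stack, same shape.
#' @export
gaussian_blur_3d <- function(stack, sigma, kernel_shape = c(21L, 21L, 5L)) {
  if (sigma <= 0) stopf("sigma must be > 0")
  d3 <- length(dim(stack)) == 3L
  if (d3) dim(stack) <- c(dim(stack), 1L)
  dm <- dim(stack)
  if (any(kernel_shape > dm[1:3]))
    stopf("kernel %s does not fit in stack %s",
          paste(kernel_shape, collapse = "x"), paste(dm[1:3], collapse = "x"))
  ky <- gauss_kernel_1d(kernel_shape[1], sigma)
  kx <- gauss_kernel_1d(kernel_shape[2], sigma)
  kz <- gauss_kernel_1d(kernel_shape[3], sigma)
  k2 <- outer(ky, kx)
  out <- stack
  for (ci in seq_len(dm[4])) {
    for (zi in seq_len(dm[3]))
      out[, , zi, ci] <- EBImage::filter2(stack[, , zi, ci], k2,
                                          boundary = "replicate")
    out[, , , ci] <- conv_z(out[, , , ci, drop = FALSE][, , , 1], kz)
  }
  if (d3) dim(out) <- dm[1:3]
  out
}

# replicate-padded 1D convolution along the z axis of a [y, x, z] array
conv_z <- function(arr, k) {
  r <- (length(k) - 1L) / 2L
  nz <- dim(arr)[3]
  idx <- pmin(pmax(seq(1L - r, nz + r), 1L), nz)
  padded <- arr[, , idx, drop = FALSE]
  out <- array(0, dim(arr))
  for (j in seq_along(k))
    out <- out + k[j] * padded[, , j:(j + nz - 1L), drop = FALSE]
  out
}
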