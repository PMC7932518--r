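#' Default pipeline configuration
#'
#' Category counts and window sizes for the pixel / supervoxel / megavoxel
#' hierarchy. Defaults: 15 pixel categories, 20 supervoxel categories, 40
#' megavoxel categories; supervoxels of 10 x 10 x 3 pixels (x, y, z) and
#' megavoxels of 6 x 6 x 2 supervoxels; a supervoxel is background when more
#' than 50% of its pixels are background, a megavoxel is foreground when at
#' least 50% of its supervoxels are foreground.
#'
#' @param k_p Number of pixel categories.
#' @param k_sv Number of supervoxel categories.
#' @param k_m Number of megavoxel categories (the feature dimensionality).
#' @param sv_size Supervoxel size `(x, y, z)` in pixels.
#' @param mv_size Megavoxel size `(x, y, z)` in supervoxels.
#' @param bg_fraction Background-pixel fraction above which (strictly) a
#'   supervoxel is background.
#' @param fg_fraction Foreground-supervoxel fraction at or above which
#'   (inclusive) a megavoxel is foreground.
#' @param threshold_quantile Quantile of the training threshold distribution
#'   used as the active threshold (0.5 = median).
#' @param scaling_group Optional metadata column for per-group scaling.
#' @param n_train Number of training images sampled by default.
#' @param pixel_cap Optional cap on foreground pixels sampled per training
#'   image for pixel-category k-means (`Inf` = use all).
#' @return A list of configuration values.
#' @export
pvx_config <- function(k_p = 15L, k_sv = 20L, k_m = 40L,
                       sv_size = c(10L, 10L, 3L), mv_size = c(6L, 6L, 2L),
                       bg_fraction = 0.5, fg_fraction = 0.5,
                       threshold_quantile = 0.5, scaling_group = NULL,
                       n_train = 10L, pixel_cap = Inf) {
  stopifnot(k_p >= 2L, k_sv >= 2L, k_m >= 2L,
            all(sv_size >= 1L), all(mv_size >= 1L))
  list(k_p = as.integer(k_p), k_sv = as.integer(k_sv), k_m = as.integer(k_m),
       sv_size = as.numeric(sv_size), mv_size = as.numeric(mv_size),
       bg_fraction = bg_fraction, fg_fraction = fg_fraction,
       threshold_quantile = threshold_quantile, scaling_group = scaling_group,
       n_train = as.integer(n_train), pixel_cap = pixel_cap)
}

#' Select training images
#'
#' A reproducible uniform sample without replacement (default 10 images), or
#' the user's list verbatim.
#'
#' @param dataset A `pvx_dataset`.
#' @param n Number of images to sample.
#' @param seed RNG seed.
#' @param user_list Optional explicit image-id vector, returned unchanged
#'   (after membership validation).
#' @return Character vector of image ids.
#' @export
select_training_images <- function(dataset, n = 10L, seed = 0L,
                                   user_list = NULL) {
  ids <- dataset_images(dataset)
  if (!is.null(user_list)) {
    missing <- setdiff(user_list, ids)
    if (length(missing))
      stopf("unknown training image id(s): %s", paste(missing, collapse = ","))
    return(user_list)
  }
  if (n > length(ids))
    stopf("requested %d training images but dataset has %d", n, length(ids))
  with_seed(seed, sample(ids, n))
}

# seeded k-means with restarts; best inertia wins
km_seeded <- function(x, k, seed) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k)
    stopf("k-means: only %d distinct point(s) for k = %d", nrow(unique(x)), k)
  with_seed(seed, suppressWarnings(
    kmeans(x, centers = k, iter.max = 300L, nstart = 10L)))
}

# nearest centroid by Euclidean distance, ties -> lowest label
nearest_centroid <- function(x, centroids) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(centroids))
    stopf("dimension mismatch: points have %d column(s), centroids %d",
          ncol(x), ncol(centroids))
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Assign pixel categories
#'
#' A voxel is background (label 0) iff every channel at that location is
#' strictly below its threshold; otherwise it is assigned to the nearest
#' pixel-category centroid by Euclidean distance over the multichannel
#' intensity vector (ties to the lowest label).
#'
#' @param stack Rescaled 4D array `[y, x, z, channel]`.
#' @param thresholds A `pvx_thresholds` object (or numeric vector of
#'   per-channel thresholds on the rescaled scale).
#' @param centroids `k_p x n_channels` centroid matrix.
#' @return Integer 3D array `[y, x, z]` of labels `0..k_p`.
#' @export
assign_pixel_categories <- function(stack, thresholds, centroids) {
  t_ch <- if (inherits(thresholds, "pvx_thresholds")) thresholds$t
          else as.numeric(thresholds)
  n_ch <- dim(stack)[4]
  if (length(t_ch) < n_ch || ncol(centroids) != n_ch)
    stopf("channel count mismatch (stack %d, thresholds %d, centroids %d)",
          n_ch, length(t_ch), ncol(centroids))
  nvox <- prod(dim(stack)[1:3])
  flat <- matrix(stack, nvox, n_ch)
  fg <- rowSums(sweep(flat, 2, t_ch[seq_len(n_ch)], ">=")) > 0
  lab <- integer(nvox)
  if (any(fg))
    lab[fg] <- nearest_centroid(flat[fg, , drop = FALSE], centroids)
  array(lab, dim(stack)[1:3])
}

#' Learn pixel-category centroids
#'
#' k-means on the foreground multichannel pixels pooled from the training
#' stacks; background pixels are excluded.
#'
#' @param stacks List of rescaled 4D arrays.
#' @param thresholds Per-channel thresholds (see
#'   [assign_pixel_categories()]).
#' @param k_p Number of pixel categories (default 15).
#' @param seed RNG seed.
#' @param pixel_cap Optional per-stack cap on sampled foreground pixels.
#' @return `k_p x n_channels` centroid matrix.
#' @export
learn_pixel_categories <- function(stacks, thresholds, k_p = 15L, seed = 0L,
                                   pixel_cap = Inf) {
  t_ch <- if (inherits(thresholds, "pvx_thresholds")) thresholds$t
          else as.numeric(thresholds)
  pool <- list()
  for (si in seq_along(stacks)) {
    stk <- stacks[[si]]
    n_ch <- dim(stk)[4]
    flat <- matrix(stk, prod(dim(stk)[1:3]), n_ch)
    fg <- rowSums(sweep(flat, 2, t_ch[seq_len(n_ch)], ">=")) > 0
    px <- flat[fg, , drop = FALSE]
    if (is.finite(pixel_cap) && nrow(px) > pixel_cap) {
      keep <- with_seed(seed + si, sample(nrow(px), pixel_cap))
      px <- px[keep, , drop = FALSE]
    }
    pool[[si]] <- px
  }
  pool <- do.call(rbind, pool)
  if (nrow(pool) < k_p)
    stopf("only %d foreground pixel(s) for k_p = %d", nrow(pool), k_p)
  km_seeded(pool, k_p, seed)$centers
}

# tabulate (block, value) counts; values in 0..k -> matrix [n_blocks, k+1]
block_counts <- function(arr, bs, k) {
  dm <- dim(arr)
  nb <- dm %/% bs
  if (any(nb == 0L)) stopf("block size %s exceeds array %s",
                           paste(bs, collapse = "x"),
                           paste(dm, collapse = "x"))
  keep_y <- seq_len(nb[1] * bs[1]); keep_x <- seq_len(nb[2] * bs[2])
  keep_z <- seq_len(nb[3] * bs[3])
  arr <- arr[keep_y, keep_x, keep_z, drop = FALSE]
  by <- (seq_len(nb[1] * bs[1]) - 1L) %/% bs[1]
  bx <- (seq_len(nb[2] * bs[2]) - 1L) %/% bs[2]
  bz <- (seq_len(nb[3] * bs[3]) - 1L) %/% bs[3]
  bid <- 1L + outer(outer(by, nb[1] * bx, "+"), nb[1] * nb[2] * bz, "+")
  nbt <- prod(nb)
  counts <- matrix(tabulate(bid + nbt * as.integer(arr), nbins = nbt * (k + 1L)),
                   nrow = nbt)
  list(counts = counts, nb = nb)
}

#' Build supervoxels from a pixel-category stack
#'
#' The stack is partitioned into non-overlapping `sv_size` blocks anchored at
#' the origin (trailing partial blocks are discarded). A block is background
#' iff its fraction of background pixels (label 0) strictly exceeds
#' `bg_fraction`; foreground blocks are summarized by the normalized frequency
#' of foreground pixel categories (each composition row sums to 1).
#'
#' @param category_stack Integer 3D array of labels `0..k_p`.
#' @param k_p Number of pixel categories.
#' @param sv_size Supervoxel size `(x, y, z)` in pixels.
#' @param bg_fraction Background threshold (strict).
#' @return List: `composition` (`n_blocks x k_p` matrix, background rows 0),
#'   `is_background` logical, `grid` = supervoxel-array dimensions
#'   `(y, x, z)`.
#' @export
build_supervoxels <- function(category_stack, k_p,
                              sv_size = c(10L, 10L, 3L), bg_fraction = 0.5) {
  bs <- as.integer(sv_size[c(2, 1, 3)])  # (x, y, z) -> (y, x, z)
  bc <- block_counts(category_stack, bs, k_p)
  vol <- prod(bs)
  is_bg <- bc$counts[, 1] / vol > bg_fraction
  comp <- bc$counts[, -1, drop = FALSE]
  fg_tot <- rowSums(comp)
  comp <- comp / ifelse(fg_tot > 0, fg_tot, 1)
  comp[is_bg, ] <- 0
  list(composition = comp, is_background = is_bg, grid = bc$nb)
}

#' Learn / assign supervoxel categories
#'
#' `learn_sv_categories` runs k-means on the foreground supervoxel
#' composition vectors. `assign_sv_categories` produces the downscaled
#' supervoxel-category array (dimensions divided by the supervoxel size):
#' background supervoxels keep label 0, foreground ones get the nearest
#' centroid (ties to the lowest label).
#'
#' @param supervoxels Output of [build_supervoxels()].
#' @param k_sv Number of supervoxel categories.
#' @param seed RNG seed.
#' @return `learn_sv_categories`: `k_sv x k_p` centroid matrix (rows sum
#'   to 1). `assign_sv_categories`: integer 3D array `[y, x, z]` of labels
#'   `0..k_sv`.
#' @export
learn_sv_categories <- function(supervoxels, k_sv = 20L, seed = 0L) {
  fg <- supervoxels$composition[!supervoxels$is_background, , drop = FALSE]
  if (nrow(fg) < k_sv)
    stopf("only %d foreground supervoxel(s) for k_sv = %d", nrow(fg), k_sv)
  km_seeded(fg, k_sv, seed)$centers
}

#' @rdname learn_sv_categories
#' @param centroids Centroid matrix from `learn_sv_categories`.
#' @export
assign_sv_categories <- function(supervoxels, centroids) {
  lab <- integer(nrow(supervoxels$composition))
  fg <- !supervoxels$is_background
  if (any(fg))
    lab[fg] <- nearest_centroid(supervoxels$composition[fg, , drop = FALSE],
                                centroids)
  array(lab, supervoxels$grid)
}

#' Build megavoxels from a supervoxel-category array
#'
#' Non-overlapping `mv_size` blocks of the supervoxel array. A block is
#' foreground iff its fraction of foreground supervoxels is at least
#' `fg_fraction` (inclusive); foreground blocks are summarized by the
#' normalized frequency of supervoxel categories among their foreground
#' supervoxels.
#'
#' @param sv_array Integer 3D array of supervoxel labels `0..k_sv`.
#' @param k_sv Number of supervoxel categories.
#' @param mv_size Megavoxel size `(x, y, z)` in supervoxels.
#' @param fg_fraction Foreground threshold (inclusive).
#' @return List: `composition` (`n_blocks x k_sv`), `is_foreground` logical,
#'   `grid` megavoxel-array dimensions.
#' @export
build_megavoxels <- function(sv_array, k_sv, mv_size = c(6L, 6L, 2L),
                             fg_fraction = 0.5) {
  bs <- as.integer(mv_size[c(2, 1, 3)])
  bc <- block_counts(sv_array, bs, k_sv)
  vol <- prod(bs)
  fg_frac <- 1 - bc$counts[, 1] / vol
  is_fg <- fg_frac >= fg_fraction
  comp <- bc$counts[, -1, drop = FALSE]
  tot <- rowSums(comp)
  comp <- comp / ifelse(tot > 0, tot, 1)
  comp[!is_fg, ] <- 0
  list(composition = comp, is_foreground = is_fg, grid = bc$nb)
}

#' Learn megavoxel categories and compute image features
#'
#' `learn_mv_categories` clusters foreground megavoxel compositions with
#' k-means. `assign_mv_categories` labels foreground megavoxels by nearest
#' centroid. `compute_image_features` turns megavoxel labels into the
#' per-image feature vector: the relative frequency of foreground megavoxel
#' categories (background megavoxels are ignored, so blank image regions do
#' not affect the features) plus the foreground-megavoxel count.
#'
#' @param megavoxels Output of [build_megavoxels()].
#' @param k_m Number of megavoxel categories.
#' @param seed RNG seed.
#' @return `learn_mv_categories`: `k_m x k_sv` centroid matrix.
#'   `assign_mv_categories`: integer vector of labels for foreground
#'   megavoxels. `compute_image_features`: list `f` (length `k_m`, sums to 1;
#'   all-NaN when the image has no foreground megavoxels, with a warning) and
#'   `mv_count`.
#' @export
learn_mv_categories <- function(megavoxels, k_m = 40L, seed = 0L) {
  fg <- megavoxels$composition[megavoxels$is_foreground, , drop = FALSE]
  if (nrow(fg) < k_m)
    stopf("only %d foreground megavoxel(s) for k_m = %d", nrow(fg), k_m)
  km_seeded(fg, k_m, seed)$centers
}

#' @rdname learn_mv_categories
#' @param centroids Centroid matrix from `learn_mv_categories`.
#' @export
assign_mv_categories <- function(megavoxels, centroids) {
  fg <- megavoxels$composition[megavoxels$is_foreground, , drop = FALSE]
  if (nrow(fg) == 0L) return(integer(0))
  nearest_centroid(fg, centroids)
}

#' @rdname learn_mv_categories
#' @param mv_labels Integer labels from `assign_mv_categories`.
#' @export
compute_image_features <- function(mv_labels, k_m) {
  n <- length(mv_labels)
  if (n == 0L) {
    warnf("image has no foreground megavoxels; feature vector undefined")
    return(list(f = rep(NaN, k_m), mv_count = 0L))
  }
  counts <- tabulate(mv_labels, nbins = k_m)
  list(f = counts / n, mv_count = n)
}

#' Train a profiling model
#'
#' Chains all learning steps on a (sampled or user-given) training set:
#' intensity scaling parameters, per-channel thresholds, pixel-category
#' k-means on foreground pixels, supervoxel-category k-means on foreground
#' supervoxel compositions, and megavoxel-category k-means. The returned
#' model is self-contained; [extract_features()] applies it deterministically
#' to any dataset.
#'
#' @param dataset A `pvx_dataset`.
#' @param config A [pvx_config()] list.
#' @param seed RNG seed (controls training-image sampling and every k-means).
#' @param training_ids Optional explicit training image ids.
#' @return A `pvx_model`.
#' @export
train_model <- function(dataset, config = pvx_config(), seed = 0L,
                        training_ids = NULL) {
  ids <- select_training_images(dataset,
                                n = min(config$n_train,
                                        length(dataset_images(dataset))),
                                seed = seed, user_list = training_ids)
  training <- dataset[dataset$image_id %in% ids, , drop = FALSE]
  attr(training, "meta_cols") <- attr(dataset, "meta_cols")
  class(training) <- class(dataset)

  scaling <- compute_scaling_params(training, group_by = config$scaling_group)
  thresholds <- aggregate_thresholds(training, scaling,
                                     quantile_choice = config$threshold_quantile)

  meta <- image_metadata(training)
  stacks <- lapply(ids, function(id) {
    g <- if (is.null(config$scaling_group)) NULL
         else meta[[config$scaling_group]][meta$image_id == id][1]
    rescale_intensities(read_stack(training, id), scaling, group = g)
  })

  px_centroids <- learn_pixel_categories(stacks, thresholds, k_p = config$k_p,
                                         seed = seed,
                                         pixel_cap = config$pixel_cap)

  sv_pool <- list(); sv_objs <- list()
  for (i in seq_along(stacks)) {
    cat_stack <- assign_pixel_categories(stacks[[i]], thresholds, px_centroids)
    sv <- build_supervoxels(cat_stack, config$k_p, config$sv_size,
                            config$bg_fraction)
    sv_objs[[i]] <- sv
    sv_pool[[i]] <- sv$composition[!sv$is_background, , drop = FALSE]
  }
  sv_centroids <- learn_sv_categories(
    list(composition = do.call(rbind, sv_pool),
         is_background = rep(FALSE, sum(vapply(sv_pool, nrow, 1L)))),
    k_sv = config$k_sv, seed = seed)

  mv_pool <- list()
  for (i in seq_along(stacks)) {
    sv_arr <- assign_sv_categories(sv_objs[[i]], sv_centroids)
    mv <- build_megavoxels(sv_arr, config$k_sv, config$mv_size,
                           config$fg_fraction)
    mv_pool[[i]] <- mv$composition[mv$is_foreground, , drop = FALSE]
  }
  mv_centroids <- learn_mv_categories(
    list(composition = do.call(rbind, mv_pool),
         is_foreground = rep(TRUE, sum(vapply(mv_pool, nrow, 1L)))),
    k_m = config$k_m, seed = seed)

  structure(list(
    scaling = scaling, thresholds = thresholds,
    pixel_centroids = px_centroids,
    sv_size = config$sv_size, bg_fraction = config$bg_fraction,
    sv_centroids = sv_centroids,
    mv_size = config$mv_size, fg_fraction = config$fg_fraction,
    mv_centroids = mv_centroids,
    config = config,
    training = list(image_ids = ids, seed = seed)),
    class = "pvx_model")
}

#' @export
print.pvx_model <- function(x, ...) {
  cat(sprintf(
    "<pvx_model> %d channels | k_p=%d k_sv=%d k_m=%d | SV %s px, MV %s sv\n",
    ncol(x$pixel_centroids), nrow(x$pixel_centroids), nrow(x$sv_centroids),
    nrow(x$mv_centroids), paste(x$sv_size, collapse = "x"),
    paste(x$mv_size, collapse = "x")))
  invisible(x)
}

# apply a trained model to one in-memory (raw-intensity) stack
stack_features <- function(stack, model, group = NULL) {
  stk <- rescale_intensities(stack, model$scaling, group = group)
  cat_stack <- assign_pixel_categories(stk, model$thresholds,
                                       model$pixel_centroids)
  sv <- build_supervoxels(cat_stack, nrow(model$pixel_centroids),
                          model$sv_size, model$bg_fraction)
  sv_arr <- assign_sv_categories(sv, model$sv_centroids)
  mv <- build_megavoxels(sv_arr, nrow(model$sv_centroids), model$mv_size,
                         model$fg_fraction)
  labels <- assign_mv_categories(mv, model$mv_centroids)
  compute_image_features(labels, nrow(model$mv_centroids))
}

#' Extract image features with a trained model
#'
#' Applies the full pixel-to-megavoxel hierarchy to every image of a dataset.
#' Deterministic given a model. Images with no foreground megavoxels yield an
#' all-NaN feature row and a warning.
#'
#' @param dataset A `pvx_dataset`.
#' @param model A `pvx_model` from [train_model()].
#' @param image_ids Optional subset of images to extract.
#' @return A `pvx_features` data frame: `image_id`, metadata columns,
#'   `mv_count`, feature columns `f1..fk_m` (each row sums to 1 when
#'   `mv_count > 0`).
#' @export
extract_features <- function(dataset, model, image_ids = NULL) {
  ids <- image_ids %||% dataset_images(dataset)
  meta <- image_metadata(dataset)
  k_m <- nrow(model$mv_centroids)
  fmat <- matrix(NA_real_, length(ids), k_m,
                 dimnames = list(NULL, paste0("f", seq_len(k_m))))
  mv_count <- integer(length(ids))
  for (i in seq_along(ids)) {
    g <- if (is.null(model$scaling$group_by)) NULL
         else meta[[model$scaling$group_by]][meta$image_id == ids[i]][1]
    res <- stack_features(read_stack(dataset, ids[i]), model, group = g)
    fmat[i, ] <- res$f
    mv_count[i] <- res$mv_count
  }
  out <- cbind(
    data.frame(image_id = ids, stringsAsFactors = FALSE),
    meta[match(ids, meta$image_id), setdiff(names(meta), "image_id"),
         drop = FALSE],
    data.frame(mv_count = mv_count),
    as.data.frame(fmat))
  rownames(out) <- NULL
  structure(out, feature_cols = paste0("f", seq_len(k_m)),
            class = c("pvx_features", "data.frame"))
}
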