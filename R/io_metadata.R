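#' Image-stack datasets
#'
#' A `pvx_dataset` indexes a multichannel 3D image collection stored as one 2D
#' grayscale TIFF per (channel, z-plane). It is a data frame with the canonical
#' columns `image_id`, `channel`, `z`, `path` plus any number of metadata
#' columns (plate, well, treatment, ...) carried through to feature tables.
#'
#' Invariants enforced at construction: every `(image_id, channel, z)` triple
#' is unique; per `(image_id, channel)` the z values form a contiguous
#' `1..n_z` range; all channels of one image share `n_z`. All planes of one
#' image must share identical height/width; this is verified when planes are
#' actually read (see [read_stack()]), or eagerly with `validate = "full"`.
#'
#' @param metadata Path to a delimited text file (TSV/CSV, sniffed from the
#'   extension) or a data frame.
#' @param roles Named list mapping the canonical roles to column names in
#'   `metadata`: `path`, `channel`, `z`, `id`. Any remaining columns are
#'   treated as per-image metadata.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved. Defaults to the metadata file's directory.
#' @param validate `"files"` (default) checks file existence and index
#'   invariants; `"full"` additionally reads every plane and checks shape
#'   consistency; `"none"` checks index invariants only.
#' @return A `pvx_dataset` data frame.
#' @export
load_dataset <- function(metadata,
                         roles = list(path = "path", channel = "channel",
                                      z = "z", id = "image_id"),
                         base_dir = NULL,
                         validate = c("files", "full", "none")) {
  validate <- match.arg(validate)
  if (is.character(metadata)) {
    if (!file.exists(metadata))
      stopf("metadata table not found: %s", metadata)
    sep <- if (grepl("\\.csv$", metadata, ignore.case = TRUE)) "," else "\t"
    tab <- read.delim(metadata, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (is.null(base_dir)) base_dir <- dirname(metadata)
  } else {
    tab <- as.data.frame(metadata, stringsAsFactors = FALSE)
  }
  roles <- utils::modifyList(
    list(path = "path", channel = "channel", z = "z", id = "image_id"), roles)
  for (r in c("path", "channel", "z", "id"))
    if (!roles[[r]] %in% names(tab))
      stopf("metadata table lacks a '%s' column ('%s')", r, roles[[r]])

  ds <- data.frame(
    image_id = as.character(tab[[roles$id]]),
    channel  = as.integer(tab[[roles$channel]]),
    z        = as.integer(tab[[roles$z]]),
    path     = as.character(tab[[roles$path]]),
    stringsAsFactors = FALSE)
  meta_cols <- setdiff(names(tab),
                       unlist(roles[c("path", "channel", "z", "id")]))
  for (mc in meta_cols) ds[[mc]] <- as.character(tab[[mc]])

  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", ds$path)
    ds$path[rel] <- file.path(base_dir, ds$path[rel])
  }
  validate_dataset(ds, files = validate != "none")

  ds <- ds[order(ds$image_id, ds$channel, ds$z), , drop = FALSE]
  rownames(ds) <- NULL
  structure(ds, meta_cols = meta_cols, class = c("pvx_dataset", "data.frame"))
}

validate_dataset <- function(ds, files = TRUE) {
  key <- paste(ds$image_id, ds$channel, ds$z, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (image_id, channel, z) entries in metadata")
  if (any(ds$channel < 1L) || any(ds$z < 1L))
    stopf("channel and z indices must be 1-based positive integers")
  for (id in unique(ds$image_id)) {
    sub <- ds[ds$image_id == id, ]
    nz <- tapply(sub$z, sub$channel, function(zz) {
      if (!setequal(zz, seq_len(max(zz))))
        stopf("image '%s': z planes are not a contiguous 1..n_z range (%s)",
              id, paste(sort(zz), collapse = ","))
      max(zz)
    })
    if (length(unique(nz)) != 1L)
      stopf("image '%s': channels disagree on the number of z planes", id)
  }
  if (files) {
    missing <- !file.exists(ds$path)
    if (any(missing))
      stopf("missing image file(s): %s",
            paste(head(ds$path[missing], 3), collapse = ", "))
  }
  invisible(ds)
}

#' @export
print.pvx_dataset <- function(x, ...) {
  cat(sprintf("<pvx_dataset> %d images, %d channels, %d planes\n",
              length(unique(x$image_id)), length(unique(x$channel)), nrow(x)))
  invisible(x)
}

#' List image ids of a dataset
#' @param dataset A `pvx_dataset`.
#' @return Character vector of unique image ids.
#' @export
dataset_images <- function(dataset) unique(dataset$image_id)

#' Per-image metadata
#'
#' One row per image id with the metadata columns (first occurrence wins when
#' a column varies across planes of one image).
#' @inheritParams dataset_images
#' @return A data frame with `image_id` plus metadata columns.
#' @export
image_metadata <- function(dataset) {
  meta_cols <- attr(dataset, "meta_cols") %||% character()
  first <- !duplicated(dataset$image_id)
  out <- dataset[first, c("image_id", meta_cols), drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Read one image stack
#'
#' Assembles the 2D TIFF planes of one image into a numeric 4D array
#' `[y, x, z, channel]`. 8/12/16-bit integer TIFFs are promoted to double
#' with no intensity rescaling.
#'
#' @inheritParams dataset_images
#' @param image_id Image id to read.
#' @return Numeric 4D array `[y, x, z, channel]`.
#' @export
read_stack <- function(dataset, image_id) {
  sub <- dataset[dataset$image_id == image_id, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("unknown image id '%s'", image_id)
  channels <- sort(unique(sub$channel))
  n_z <- max(sub$z)
  arr <- NULL
  for (ci in seq_along(channels)) {
    for (zi in seq_len(n_z)) {
      row <- sub[sub$channel == channels[ci] & sub$z == zi, ]
      plane <- read_plane(row$path)
      if (is.null(arr)) {
        arr <- array(NA_real_, c(nrow(plane), ncol(plane), n_z,
                                 length(channels)))
      } else if (!all(dim(plane) == dim(arr)[1:2])) {
        stopf("image '%s': plane %s has shape %dx%d, expected %dx%d",
              image_id, row$path, nrow(plane), ncol(plane),
              dim(arr)[1], dim(arr)[2])
      }
      arr[, , zi, ci] <- plane
    }
  }
  arr
}

read_plane <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # collapse unexpected RGB
  storage.mode(img) <- "double"
  img
}

#' Write an image stack as per-plane TIFF files
#'
#' Inverse of [read_stack()]: one 16-bit grayscale TIFF per (channel, z).
#' Intensities are clamped to `[0, 65535]` and rounded.
#'
#' @param stack Numeric 4D array `[y, x, z, channel]` (a 3D array is treated
#'   as single-channel).
#' @param dir Output directory (created if needed).
#' @param image_id Id used in file names.
#' @return Data frame of `(image_id, channel, z, path)` rows for the planes
#'   written, suitable for a metadata table.
#' @export
write_stack_planes <- function(stack, dir, image_id) {
  if (length(dim(stack)) == 3L) dim(stack) <- c(dim(stack), 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- NULL
  for (ci in seq_len(dim(stack)[4])) {
    for (zi in seq_len(dim(stack)[3])) {
      fn <- file.path(dir, sprintf("%s_ch%d_z%02d.tif", image_id, ci, zi))
      plane <- pmin(pmax(stack[, , zi, ci], 0), 65535)
      tiff::writeTIFF(round(plane) / 65535, fn, bits.per.sample = 16L)
      rows <- rbind(rows, data.frame(image_id = image_id, channel = ci,
                                     z = zi, path = fn,
                                     stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Save a dataset index to delimited text
#'
#' Canonical column names are written so the table reloads with default roles.
#' @inheritParams dataset_images
#' @param path Output TSV path.
#' @export
save_dataset <- function(dataset, path) {
  write.table(as.data.frame(dataset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Split a stack into a grid of equally sized sub-stacks
#'
#' The XY plane is divided into `grid[1] x grid[2]` tiles; z planes and
#' channels are untouched. When a dimension is not divisible by the grid the
#' trailing remainder pixels are discarded so all tiles are equally sized.
#' Tiles are returned row-major (top-left first).
#'
#' @param stack Numeric 3D `[y, x, z]` or 4D `[y, x, z, channel]` array.
#' @param grid Integer `(rows, cols)`.
#' @return List of sub-stacks, each with attribute `offset` = (y, x) of its
#'   top-left pixel in the input (1-based).
#' @export
tile_image <- function(stack, grid) {
  d3 <- length(dim(stack)) == 3L
  if (d3) dim(stack) <- c(dim(stack), 1L)
  dm <- dim(stack)
  grid <- as.integer(grid)
  if (any(grid < 1L)) stopf("grid must be positive")
  if (grid[1] > dm[1] || grid[2] > dm[2])
    stopf("grid (%d, %d) larger than image (%d, %d)",
          grid[1], grid[2], dm[1], dm[2])
  th <- dm[1] %/% grid[1]
  tw <- dm[2] %/% grid[2]
  tiles <- vector("list", grid[1] * grid[2])
  k <- 0L
  for (r in seq_len(grid[1])) {
    for (cc in seq_len(grid[2])) {
      k <- k + 1L
      ys <- (r - 1L) * th + seq_len(th)
      xs <- (cc - 1L) * tw + seq_len(tw)
      tl <- stack[ys, xs, , , drop = FALSE]
      if (d3) dim(tl) <- dim(tl)[1:3]
      attr(tl, "offset") <- c(y = ys[1], x = xs[1])
      tiles[[k]] <- tl
    }
  }
  tiles
}

#' Write / read a feature table
#'
#' Feature tables are TSV with a header: `image_id`, metadata columns,
#' `mv_count`, then the feature columns `f1..fk`.
#'
#' @param features A `pvx_features` data frame from [extract_features()].
#' @param path TSV path.
#' @return `read_feature_table` returns a `pvx_features` data frame.
#' @export
write_feature_table <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fc <- grep("^f[0-9]+$", names(tab), value = TRUE)
  structure(tab, feature_cols = fc,
            class = c("pvx_features", "data.frame"))
}

#' Extract the feature matrix from a feature table
#'
#' Drops metadata columns and returns the numeric matrix of megavoxel-category
#' frequencies (rows = images). Rows with undefined features (images with no
#' foreground megavoxels) can be removed.
#'
#' @param features `pvx_features` data frame.
#' @param drop_nan Drop all-NaN rows (default TRUE, with a message giving the
#'   count).
#' @return Numeric matrix with rownames = image ids.
#' @export
feature_matrix <- function(features, drop_nan = TRUE) {
  fc <- attr(features, "feature_cols") %||%
    grep("^f[0-9]+$", names(features), value = TRUE)
  m <- as.matrix(features[, fc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$image_id
  if (drop_nan) {
    bad <- !stats::complete.cases(m)
    if (any(bad)) {
      message(sprintf("dropping %d image(s) with undefined features",
                      sum(bad)))
      m <- m[!bad, , drop = FALSE]
    }
  }
  m
}

# ---- model persistence -------------------------------------------------

#' Save / load a trained profiling model
#'
#' Models are serialized as versioned JSON holding every learned parameter:
#' per-channel scaling (per scaling group), per-channel thresholds with their
#' training-distribution quartiles, pixel/supervoxel/megavoxel centroids,
#' window sizes, category counts, configuration, and the training manifest
#' (image ids and seed).
#'
#' @param model A `pvx_model` from [train_model()].
#' @param path JSON file path.
#' @return `load_model` returns the `pvx_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "phenovoxel-model",
    format_version = 1L,
    scaling = list(group_by = model$scaling$group_by,
                   groups = lapply(model$scaling$groups, function(g)
                     list(chmin = g$chmin, chmax = g$chmax))),
    thresholds = unclass(model$thresholds),
    pixel_centroids = model$pixel_centroids,
    sv = list(size = model$sv_size, bg_fraction = model$bg_fraction,
              centroids = model$sv_centroids),
    mv = list(size = model$mv_size, fg_fraction = model$fg_fraction,
              centroids = model$mv_centroids),
    config = model$config,
    training = model$training)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (!identical(p$format, "phenovoxel-model"))
    stopf("%s is not a phenovoxel model file", path)
  thr <- p$thresholds
  class(thr) <- "pvx_thresholds"
  model <- list(
    scaling = structure(list(group_by = p$scaling$group_by,
                             groups = lapply(p$scaling$groups, function(g)
                               list(chmin = as.numeric(g$chmin),
                                    chmax = as.numeric(g$chmax)))),
                        class = "pvx_scaling"),
    thresholds = thr,
    pixel_centroids = as.matrix(p$pixel_centroids),
    sv_size = as.numeric(p$sv$size),
    bg_fraction = p$sv$bg_fraction,
    sv_centroids = as.matrix(p$sv$centroids),
    mv_size = as.numeric(p$mv$size),
    fg_fraction = p$mv$fg_fraction,
    mv_centroids = as.matrix(p$mv$centroids),
    config = p$config,
    training = p$training)
  class(model) <- "pvx_model"
  model
}
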