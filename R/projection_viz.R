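#' Low-dimensional embedding of the feature space
#'
#' Three methods: `pca` (top-d eigenvectors of the centered covariance,
#' deterministic up to sign — signs are fixed so the largest-magnitude
#' loading of each component is positive), `sammon` (iterative stress
#' minimization from a PCA initialization), and `tsne` (exact
#' t-distributed stochastic neighbor embedding, seeded, PCA-initialized).
#'
#' @param features Numeric matrix or `pvx_features` data frame (no NaN
#'   rows).
#' @param method `"pca"`, `"sammon"` or `"tsne"`.
#' @param d Target dimensionality (2 or 3).
#' @param seed RNG seed (t-SNE only).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   when `n` is small).
#' @param n_iter Iterations for sammon/t-SNE.
#' @return A `pvx_embedding`: `coordinates` (`n x d`), `method`, `params`.
#' @export
project <- function(features, method = c("pca", "sammon", "tsne"), d = 2L,
                    seed = 0L, perplexity = 30, n_iter = 500L) {
  method <- match.arg(method)
  x <- if (inherits(features, "pvx_features")) feature_matrix(features)
       else as.matrix(features)
  if (nrow(x) <= d) stopf("need more than d = %d points", d)
  if (any(!stats::complete.cases(x))) stopf("NaN rows in features")
  pca_init <- function(k) {
    p <- prcomp(x, center = TRUE, rank. = k)
    co <- p$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      ld <- p$rotation[, j]
      if (ld[which.max(abs(ld))] < 0) co[, j] <- -co[, j]
    }
    co
  }
  coords <- switch(method,
    pca = pca_init(d),
    sammon = {
      dm <- dist(x)
      if (any(dm < 1e-12))
        stopf("sammon mapping requires distinct points (duplicate rows)")
      init <- pca_init(d)
      MASS::sammon(dm, y = init, k = d, niter = n_iter, trace = FALSE)$points
    },
    tsne = tsne_exact(x, d = d, perplexity = perplexity, seed = seed,
                      n_iter = n_iter))
  dimnames(coords) <- list(rownames(x), paste0("dim", seq_len(d)))
  structure(list(coordinates = coords, method = method,
                 params = list(d = d, seed = seed, perplexity = perplexity,
                               n_iter = n_iter)),
            class = "pvx_embedding")
}

#' @export
print.pvx_embedding <- function(x, ...) {
  cat(sprintf("<pvx_embedding> %s, %d points in %d dimensions\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

# Exact (dense) t-SNE: symmetric affinities with per-point perplexity
# calibration by bisection on the Gaussian bandwidth, Student-t similarities
# in the embedding, gradient descent with momentum, gains and early
# exaggeration. O(n^2) memory/time - meant for n up to a few thousand.
tsne_exact <- function(x, d = 2L, perplexity = 30, seed = 0L,
                       n_iter = 500L) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps

  p0 <- prcomp(x, center = TRUE, rank. = d)
  y <- p0$x[, seq_len(d), drop = FALSE] * 1e-4
  y <- y + with_seed(seed, matrix(rnorm(n * d, sd = 1e-6), n, d))
  inc <- matrix(0, n, d)
  gains <- matrix(1, n, d)
  momentum <- 0.5; eta <- 100
  exag <- 4
  Pe <- P * exag
  for (it in seq_len(n_iter)) {
    if (it == 101L) Pe <- P
    if (it == 251L) momentum <- 0.8
    yd2 <- as.matrix(dist(y))^2
    num <- 1 / (1 + yd2); diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' Per-group centroids
#'
#' Arithmetic mean of the coordinates (or features) within each group; empty
#' groups are skipped with a warning.
#'
#' @param x A `pvx_embedding`, numeric matrix, or `pvx_features`.
#' @param groups Grouping vector aligned with the rows.
#' @return Data frame: `group`, `n`, one column per dimension.
#' @export
group_centroids <- function(x, groups) {
  m <- if (inherits(x, "pvx_embedding")) x$coordinates
       else if (inherits(x, "pvx_features")) feature_matrix(x)
       else as.matrix(x)
  if (length(groups) != nrow(m)) stopf("grouping does not cover all rows")
  declared <- if (is.factor(groups)) levels(groups)
              else unique(as.character(groups))
  empty <- setdiff(declared, unique(as.character(groups)))
  if (length(empty)) warnf("skipping empty group(s): %s",
                           paste(empty, collapse = ", "))
  groups <- factor(as.character(groups))
  means <- rowsum(m, groups) / as.vector(table(groups)[levels(droplevels(groups))])
  out <- data.frame(group = rownames(means),
                    n = as.integer(table(groups)[rownames(means)]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(means, row.names = NULL))
}

#' Cluster pie-chart plot
#'
#' Draws the embedding with one pie chart per cluster at the cluster's
#' centroid: wedge fractions are the group proportions within the cluster
#' and the pie radius grows monotonically with cluster size. A
#' machine-readable sidecar TSV (`<path>.tsv`) with the centroid
#' coordinates, radii and wedge fractions is always written so downstream
#' code never parses the image.
#'
#' @param embedding A `pvx_embedding` (2D) or `n x 2` coordinate matrix.
#' @param assignments Cluster ids aligned with the rows.
#' @param groups Metadata grouping aligned with the rows.
#' @param path Output figure path (`.pdf` or `.png`).
#' @return Invisibly, the sidecar data frame.
#' @export
cluster_pie_plot <- function(embedding, assignments, groups, path) {
  co <- if (inherits(embedding, "pvx_embedding")) embedding$coordinates
        else as.matrix(embedding)
  if (nrow(co) != length(assignments) || nrow(co) != length(groups))
    stopf("assignments/groups must align with embedding rows")
  cl <- sort(unique(assignments))
  glev <- sort(unique(as.character(groups)))
  sizes <- vapply(cl, function(k) sum(assignments == k), 1L)
  span <- max(apply(co, 2, function(v) diff(range(v))))
  rmax <- 0.08 * span
  radii <- rmax * sqrt(sizes / max(sizes))

  side <- NULL
  for (i in seq_along(cl)) {
    sel <- assignments == cl[i]
    cx <- mean(co[sel, 1]); cy <- mean(co[sel, 2])
    frac <- table(factor(as.character(groups)[sel], levels = glev)) / sum(sel)
    side <- rbind(side, data.frame(cluster = cl[i], size = sizes[i],
                                   cx = cx, cy = cy, radius = radii[i],
                                   group = glev, fraction = as.numeric(frac)))
  }
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = 800, height = 800)
  } else {
    grDevices::pdf(path, width = 7, height = 7)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- grDevices::hcl.colors(max(3L, length(glev)), "Dark 3")[seq_along(glev)]
  plot(co[, 1], co[, 2], pch = 16, cex = 0.4, col = "grey70",
       xlab = "dim1", ylab = "dim2", asp = 1,
       main = "clusters with group composition")
  for (i in seq_along(cl)) {
    sub <- side[side$cluster == cl[i], ]
    draw_pie(sub$cx[1], sub$cy[1], sub$radius[1], sub$fraction, cols)
  }
  graphics::legend("topright", legend = glev, fill = cols, cex = 0.8,
                   bty = "n")
  invisible(side)
}

draw_pie <- function(cx, cy, r, fractions, cols) {
  start <- 0
  for (i in seq_along(fractions)) {
    if (fractions[i] <= 0) next
    th <- seq(2 * pi * start, 2 * pi * (start + fractions[i]),
              length.out = max(8, ceiling(180 * fractions[i])))
    graphics::polygon(c(cx, cx + r * cos(th)), c(cy, cy + r * sin(th)),
                      col = cols[i], border = "white")
    start <- start + fractions[i]
  }
}
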