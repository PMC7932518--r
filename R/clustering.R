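#' Similarity matrix for affinity propagation
#'
#' Either the negative Euclidean distance between feature rows or the
#' Spearman rank correlation between them. The diagonal is left `NA`; the
#' clustering routines inject the preference there.
#'
#' @param features Numeric matrix (rows = points) or a `pvx_features` data
#'   frame.
#' @param metric `"euclidean"` (negative Euclidean distance) or
#'   `"spearman"`.
#' @return Symmetric `n x n` similarity matrix with `NA` diagonal.
#' @export
similarity_matrix <- function(features, metric = c("euclidean", "spearman")) {
  metric <- match.arg(metric)
  x <- if (inherits(features, "pvx_features")) feature_matrix(features)
       else as.matrix(features)
  if (nrow(x) < 3L) stopf("need at least 3 points")
  bad <- !stats::complete.cases(x)
  if (any(bad))
    stopf("NaN/NA feature row(s): %s",
          paste(head(rownames(x)[bad] %||% which(bad), 5), collapse = ", "))
  s <- switch(metric,
              euclidean = -as.matrix(dist(x)),
              spearman = cor(t(x), method = "spearman"))
  diag(s) <- NA_real_
  attr(s, "metric") <- metric
  s
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing with damping.
#' Deterministic given its inputs: no random initialization, argmax ties
#' broken to the lowest index. Non-convergence within `max_iter` is flagged
#' on the result, not raised.
#'
#' @param similarity Symmetric similarity matrix (diagonal ignored).
#' @param preference Scalar preference (diagonal value); larger values yield
#'   more clusters.
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Iteration cap.
#' @param convergence_iter Iterations of unchanged exemplar decisions
#'   required for convergence.
#' @return A `pvx_clusters` object: `assignments` (cluster id per point),
#'   `exemplars` (point indices; exemplars are assigned to themselves), `k`,
#'   `preference`, `converged`.
#' @export
affinity_propagation <- function(similarity, preference, damping = 0.9,
                                 max_iter = 1000L, convergence_iter = 50L) {
  s <- as.matrix(similarity)
  diag(s) <- 0
  if (any(!is.finite(s))) stopf("similarities must be finite")
  res <- ap_cluster_cpp(s, preference, damping, as.integer(max_iter),
                        as.integer(convergence_iter))
  structure(list(assignments = res$assignments, exemplars = res$exemplars,
                 k = res$k, preference = preference,
                 converged = res$converged, iterations = res$iterations,
                 metric = attr(similarity, "metric") %||% "unknown"),
            class = "pvx_clusters")
}

#' @export
print.pvx_clusters <- function(x, ...) {
  cat(sprintf("<pvx_clusters> k=%d, n=%d, preference=%.4g%s\n", x$k,
              length(x$assignments), x$preference,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Preference bounds for the scan
#'
#' `p_min` is the largest preference for which a single cluster is optimal
#' (exact one- vs two-exemplar construction from the similarity matrix);
#' `p_max` is the maximum off-diagonal similarity, at which nearly every
#' point becomes its own exemplar.
#'
#' @param similarity Symmetric similarity matrix.
#' @return `list(p_min, p_max)` with `p_min < p_max`.
#' @export
preference_bounds <- function(similarity) {
  s <- as.matrix(similarity)
  diag(s) <- 0
  n <- nrow(s)
  if (n < 3L) stopf("need at least 3 points")
  off <- s[row(s) != col(s)]
  if (max(off) - min(off) < .Machine$double.eps * 100)
    stopf("degenerate similarities: all points equally similar")
  b <- pref_bounds_cpp(s)
  if (!(b$pmin < b$pmax)) stopf("degenerate preference range")
  list(p_min = b$pmin, p_max = b$pmax)
}

#' Knee point of a cluster-count curve
#'
#' Given the number of clusters `N(m)` observed at each of an ascending
#' series of preference values, locates the point just before the cluster
#' count starts to grow exponentially. The curvature `dF(m) = N(m-1) +
#' N(m+1) - 2 N(m)` is computed for interior points; the `n_keep` largest
#' positions are retained (ties within the cut all carried); for each the
#' angle `atan(1 / |N(m) - N(m-1)|) + atan(1 / |N(m+1) - N(m)|)` is
#' evaluated, skipping candidates that sit on a flat segment (an adjacent
#' difference of zero is not a knee); the maximum-angle point marks the
#' inflexion and its `N` is the chosen cluster count.
#'
#' @param n_clusters Integer vector `N(m)` ordered by ascending preference
#'   (at least 5 points).
#' @param n_keep Number of top-curvature candidates retained (default 5).
#' @return The chosen cluster count.
#' @export
knee_point <- function(n_clusters, n_keep = 5L) {
  N <- as.numeric(n_clusters)
  M <- length(N)
  if (M < 5L) stopf("need at least 5 scan points")
  m <- 2:(M - 1)
  dF <- N[m - 1] + N[m + 1] - 2 * N[m]
  if (all(dF == 0)) stopf("no knee detected: flat cluster-count curve")
  cut <- sort(dF, decreasing = TRUE)[min(n_keep, length(dF))]
  cand <- m[dF >= cut]
  dl <- abs(N[cand] - N[cand - 1])
  dr <- abs(N[cand + 1] - N[cand])
  ok <- dl > 0 & dr > 0
  if (!any(ok)) stopf("no knee detected: candidates lie on flat segments")
  cand <- cand[ok]
  angle <- atan(1 / dl[ok]) + atan(1 / dr[ok])
  m_star <- cand[which.max(angle)]
  structure(N[m_star], index = m_star)
}

#' Automated clustering with preference estimation
#'
#' In auto mode, affinity propagation is run over `n_scan_points` preference
#' values linearly spaced between the bounds of [preference_bounds()]; the
#' knee of the resulting cluster-count curve selects the preference, and AP
#' is re-run there. If no knee is detected, AP at the median off-diagonal
#' similarity is used with a warning. When `user_k` is given, the preference
#' is binary-searched (at most 50 probes) until AP yields exactly `user_k`
#' clusters, else the nearest achieved count.
#'
#' @param features Feature matrix or `pvx_features` data frame (no NaN
#'   rows).
#' @param metric Similarity metric, see [similarity_matrix()].
#' @param n_scan_points Number of preference values scanned (default 40).
#' @param user_k Optional fixed cluster count.
#' @param damping,max_iter,convergence_iter Passed to
#'   [affinity_propagation()].
#' @return A `pvx_clusters` object with an additional `scan` component
#'   (`data.frame(preference, n_clusters)`) in auto mode.
#' @export
auto_cluster <- function(features, metric = c("euclidean", "spearman"),
                         n_scan_points = 40L, user_k = NULL, damping = 0.9,
                         max_iter = 1000L, convergence_iter = 50L) {
  s <- similarity_matrix(features, metric = match.arg(metric))
  b <- preference_bounds(s)
  run <- function(p) affinity_propagation(s, p, damping, max_iter,
                                          convergence_iter)
  if (!is.null(user_k)) {
    lo <- b$p_min; hi <- b$p_max
    best <- NULL
    for (probe in seq_len(50L)) {
      mid <- (lo + hi) / 2
      res <- run(mid)
      if (is.null(best) || abs(res$k - user_k) < abs(best$k - user_k))
        best <- res
      if (res$k == user_k) break
      if (res$k < user_k) lo <- mid else hi <- mid
    }
    return(best)
  }
  prefs <- seq(b$p_min, b$p_max, length.out = n_scan_points)
  scans <- lapply(prefs, run)
  N <- vapply(scans, `[[`, 1L, "k")
  scan_df <- data.frame(preference = prefs, n_clusters = N)
  k_star <- tryCatch(knee_point(N), error = function(e) NULL)
  if (is.null(k_star)) {
    warnf("no knee detected; falling back to the median-similarity preference")
    off <- s[row(s) != col(s)]
    res <- run(median(off))
  } else {
    res <- run(prefs[attr(k_star, "index")])
  }
  res$scan <- scan_df
  res
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement under the permutation model: 1 for
#' identical partitions (up to relabeling), about 0 for independent random
#' partitions.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors differ in length (%d vs %d)",
          length(labels_a), length(labels_b))
  mclust::adjustedRandIndex(labels_a, labels_b)
}
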