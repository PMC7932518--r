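#' Train a random-forest phenotype classifier
#'
#' A 100-tree forest; the per-node candidate-variable count (`mtry`) is
#' selected from `{floor(sqrt(d))/2, floor(sqrt(d)), 2 floor(sqrt(d))}` by
#' 5-fold stratified cross-validation on the training rows (ties to the
#' smallest `mtry`).
#'
#' @param features Numeric matrix or `pvx_features` data frame.
#' @param labels Class labels (at least 2 classes, at least 5 rows each).
#' @param seed RNG seed.
#' @param n_trees Number of trees (default 100).
#' @param inner_folds Folds for the internal `mtry` selection.
#' @return A `pvx_classifier`: the forest, selected `mtry`, class levels and
#'   training manifest.
#' @export
train_classifier <- function(features, labels, seed = 0L, n_trees = 100L,
                             inner_folds = 5L) {
  x <- if (inherits(features, "pvx_features")) feature_matrix(features)
       else as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  if (min(table(y)) < 5L) stopf("need at least 5 rows per class")
  if (nrow(x) != length(y)) stopf("features/labels length mismatch")
  d <- ncol(x)
  base <- max(1L, floor(sqrt(d)))
  grid <- sort(unique(pmin(d, pmax(1L, c(base %/% 2L, base, 2L * base)))))

  folds <- stratified_folds(y, inner_folds, seed)
  acc <- vapply(grid, function(mtry) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      fit <- with_seed(seed + 1000L * mtry + f,
                       randomForest::randomForest(x[tr, , drop = FALSE],
                                                  y[tr], ntree = n_trees,
                                                  mtry = mtry))
      correct <- correct +
        sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  mtry <- grid[which.max(acc)]
  forest <- with_seed(seed,
                      randomForest::randomForest(x, y, ntree = n_trees,
                                                 mtry = mtry))
  structure(list(forest = forest, mtry = mtry, levels = levels(y),
                 n_trees = n_trees, seed = seed, n_train = nrow(x)),
            class = "pvx_classifier")
}

# per-class cyclic fold assignment after a seeded shuffle
stratified_folds <- function(y, folds, seed) {
  f <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  f
}

#' Predict classes with a trained classifier
#'
#' @param model A `pvx_classifier`.
#' @param features Feature matrix or `pvx_features` data frame with the
#'   training dimensionality.
#' @return Character vector of predicted labels.
#' @export
classify <- function(model, features) {
  x <- if (inherits(features, "pvx_features")) feature_matrix(features)
       else as.matrix(features)
  if (ncol(x) != length(model$forest$importance[, 1]))
    stopf("feature dimensionality %d does not match the model (%d)",
          ncol(x), length(model$forest$importance[, 1]))
  as.character(predict(model$forest, x))
}

#' Per-group class fractions
#'
#' For each group (e.g. drug x concentration) the fraction of rows assigned
#' to each class; fractions sum to 1 within every group.
#'
#' @param predictions Predicted class labels.
#' @param groups Grouping vector aligned with `predictions`.
#' @return Data frame: `group`, `n`, one fraction column per class.
#' @export
class_fractions <- function(predictions, groups) {
  if (length(predictions) != length(groups))
    stopf("predictions/groups length mismatch")
  tab <- table(group = groups, class = predictions)
  frac <- prop.table(tab, margin = 1)
  out <- data.frame(group = rownames(tab), n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (cl in colnames(frac)) out[[cl]] <- as.numeric(frac[, cl])
  rownames(out) <- NULL
  out
}

#' Cross-validated Cohen's kappa
#'
#' Stratified k-fold cross-validation: per fold a classifier is trained on
#' the remaining rows and Cohen's kappa is computed on the held-out
#' predictions.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (default 10).
#' @return Numeric vector of per-fold kappa values.
#' @export
cross_validated_kappa <- function(features, labels, folds = 10L, seed = 0L) {
  x <- if (inherits(features, "pvx_features")) feature_matrix(features)
       else as.matrix(features)
  y <- factor(labels)
  if (min(table(y)) < folds)
    stopf("smallest class (%d rows) cannot populate %d folds",
          min(table(y)), folds)
  fold_id <- stratified_folds(y, folds, seed)
  vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- train_classifier(x[tr, , drop = FALSE], y[tr], seed = seed + f)
    cohens_kappa(as.character(y[!tr]),
                 classify(fit, x[!tr, , drop = FALSE]))
  }, numeric(1))
}

#' Cohen's kappa
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the marginal
#' products; 1 on identical labelings, 0 at chance level. When both
#' labelings are the same single class (`p_e = 1`) the value is defined as 0
#' with a warning.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Scalar kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stopf("label vectors differ in length")
  lev <- union(unique(as.character(truth)), unique(as.character(predicted)))
  t_f <- factor(as.character(truth), levels = lev)
  p_f <- factor(as.character(predicted), levels = lev)
  tab <- table(t_f, p_f)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warnf("degenerate single-class labelings: kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Mutual information of a contingency table
#'
#' `MI = sum_ij p(i,j) log(p(i,j) / (p(i) p(j)))` with the joint from the
#' normalized counts and marginals by row/column sums; zero-count cells
#' contribute 0. Natural logarithm by default.
#'
#' @param table Nonnegative count matrix (groups x clusters).
#' @param base Logarithm base (default `exp(1)`, nats).
#' @return Scalar MI (nonnegative).
#' @export
mutual_information <- function(table, base = exp(1)) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stopf("negative counts")
  tot <- sum(tab)
  if (tot <= 0) stopf("empty contingency table")
  p <- tab / tot
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log(p / outer(pr, pc))
  sum(terms[p > 0]) / log(base)
}
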