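# stratified index sample: fraction `frac` of each class
.stratified_indices <- function(labels, frac) {
  idx <- integer(0)
  for (lv in levels(labels)) {
    members <- which(labels == lv)
    if (length(members) < 2L) {
      abort(paste0("class '", lv, "' has fewer than 2 members"),
            class = "eap_stratification_error")
    }
    n_take <- max(1L, round(frac * length(members)))
    n_take <- min(n_take, length(members) - 1L)
    idx <- c(idx, sample(members, n_take))
  }
  sort(idx)
}

#' Random-forest classification with grid search
#'
#' Stratified 20% holdout; grid search over tree depth and ensemble size on
#' the remaining 80% selected by out-of-bag score; k-fold cross-validated
#' accuracy of the selected parameters; final model refitted on the
#' training split and scored on the holdout, with Gini (impurity)
#' importances normalized to sum 1.
#'
#' @param features N x K numeric matrix (or data frame).
#' @param labels Class label per row (>= 2 classes, each >= 2 members).
#' @param grid List with `max_depth` (0 = unlimited) and `num_trees`
#'   vectors.
#' @param holdout Holdout fraction (default 0.2).
#' @param cv_folds Cross-validation folds (default 5).
#' @param max_features Optional `mtry` (features per split); e.g. 4 for the
#'   baseline-feature comparison.
#' @param seed Integer seed (splits and forests).
#' @return A `classifier_report`: list with `holdout_accuracy`, `oob_score`,
#'   `cv_accuracy`, `per_class_accuracy`, `confusion` (rows = truth),
#'   `gini_importances`, `best_params`.
#' @export
rf_classify <- function(features, labels,
                        grid = list(max_depth = c(4, 8, 16, 0),
                                    num_trees = c(100, 300, 500)),
                        holdout = 0.2, cv_folds = 5L, max_features = NULL,
                        seed = 0L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("need at least two classes",
                                  class = "eap_usage_error")
  if (length(grid$max_depth) == 0 || length(grid$num_trees) == 0) {
    abort("empty hyperparameter grid", class = "eap_usage_error")
  }
  df <- as.data.frame(features)
  names(df) <- make.names(names(df), unique = TRUE)
  feat_names <- names(df)
  df$.y <- labels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  test_idx <- .stratified_indices(labels, holdout)
  train <- df[-test_idx, , drop = FALSE]
  test <- df[test_idx, , drop = FALSE]

  mtry <- if (is.null(max_features)) NULL else
    min(as.integer(max_features), length(feat_names))
  combos <- expand.grid(max_depth = grid$max_depth,
                        num_trees = grid$num_trees,
                        KEEP.OUT.ATTRS = FALSE)
  oob <- vapply(seq_len(nrow(combos)), function(i) {
    fit <- ranger::ranger(dependent.variable.name = ".y", data = train,
                          num.trees = combos$num_trees[i],
                          max.depth = combos$max_depth[i], mtry = mtry,
                          seed = as.integer(seed) + i)
    1 - fit$prediction.error
  }, numeric(1))
  best <- combos[which.max(oob), ]

  # k-fold CV accuracy of the selected parameters on the training split
  folds <- sample(rep_len(seq_len(cv_folds), nrow(train)))
  cv_acc <- vapply(seq_len(cv_folds), function(k) {
    tr <- train[folds != k, , drop = FALSE]
    va <- train[folds == k, , drop = FALSE]
    if (nlevels(droplevels(tr$.y)) < 2L) return(NA_real_)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = tr,
                          num.trees = best$num_trees,
                          max.depth = best$max_depth, mtry = mtry,
                          seed = as.integer(seed) + 100L + k)
    mean(predict(fit, va)$predictions == va$.y)
  }, numeric(1))

  final <- ranger::ranger(dependent.variable.name = ".y", data = train,
                          num.trees = best$num_trees,
                          max.depth = best$max_depth, mtry = mtry,
                          importance = "impurity",
                          seed = as.integer(seed) + 999L)
  pred <- predict(final, test)$predictions
  acc <- mean(pred == test$.y)
  confusion <- table(truth = test$.y, predicted = pred)
  per_class <- vapply(levels(labels), function(lv) {
    m <- test$.y == lv
    if (!any(m)) NA_real_ else mean(pred[m] == lv)
  }, numeric(1))
  gini <- final$variable.importance
  if (sum(gini) > 0) gini <- gini / sum(gini)

  structure(list(
    holdout_accuracy = acc, oob_score = max(oob),
    cv_accuracy = mean(cv_acc, na.rm = TRUE),
    per_class_accuracy = per_class, confusion = confusion,
    gini_importances = gini,
    best_params = list(max_depth = best$max_depth,
                       num_trees = best$num_trees, mtry = mtry)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> holdout accuracy:",
      sprintf("%.1f%%", 100 * x$holdout_accuracy),
      " oob:", sprintf("%.1f%%", 100 * x$oob_score), "\n")
  cat("  best params: depth =", x$best_params$max_depth,
      "(0 = unlimited), trees =", x$best_params$num_trees, "\n")
  invisible(x)
}

#' Unsupervised excitatory/inhibitory clustering benchmark
#'
#' Clusters the unit source prevalences into two groups with k-means,
#' agglomerative clustering (Ward and average linkage, Euclidean) and a
#' Gaussian mixture model, and scores each method as the best fraction of
#' units matching the true binary labels over the two label permutations.
#'
#' @param prevalences N x R numeric matrix.
#' @param true_labels Binary class label per row (exactly two classes).
#' @param k Number of clusters; only 2 is supported in this benchmark.
#' @param seed Integer seed.
#' @return Tibble: `method`, `accuracy` (fraction in `[0, 1]`).
#' @export
clustering_benchmark <- function(prevalences, true_labels, k = 2L,
                                 seed = 0L) {
  if (k != 2L) abort("this benchmark is defined for k = 2",
                     class = "eap_usage_error")
  truth <- factor(true_labels)
  if (nlevels(truth) != 2L) abort("true_labels must have exactly 2 classes",
                                  class = "eap_usage_error")
  P <- as.matrix(prevalences)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  perm_accuracy <- function(cl) {
    cl <- as.integer(factor(cl))
    t1 <- mean((cl == 1L) == (truth == levels(truth)[1]))
    max(t1, 1 - t1)
  }
  d <- dist(P)
  assignments <- list(
    kmeans = kmeans(P, centers = 2L, nstart = 10L)$cluster,
    ward = cutree(hclust(d, method = "ward.D2"), k = 2L),
    average = cutree(hclust(d, method = "average"), k = 2L),
    gmm = {
      mclustBIC <- mclust::mclustBIC   # Mclust resolves this by name
      fit <- mclust::Mclust(P, G = 2L, verbose = FALSE)
      fit$classification
    })
  tibble(method = names(assignments),
         accuracy = vapply(assignments, perm_accuracy, numeric(1)))
}
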