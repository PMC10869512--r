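#' Bootstrapped family centroids in source-prevalence space
#'
#' Per bootstrap draw: 80% of the units are resampled with replacement and
#' each family's mean prevalence vector is computed; the final centroid is
#' the coordinate-wise median across draws (draws missing a family are
#' skipped for that family).
#'
#' @param prevalences N x R prevalence matrix.
#' @param family_labels Family per row.
#' @param n_boot Bootstrap draws (default 1000).
#' @param frac Fraction of units resampled per draw (default 0.8).
#' @param seed Integer seed.
#' @return Families x R numeric matrix (row names = families).
#' @export
bootstrap_centroids <- function(prevalences, family_labels, n_boot = 1000L,
                                frac = 0.8, seed = 0L) {
  fams <- sort(unique(as.character(family_labels)))
  N <- nrow(prevalences)
  R <- ncol(prevalences)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  acc <- array(NA_real_, dim = c(n_boot, length(fams), R))
  labs <- as.character(family_labels)
  n_take <- max(1L, round(frac * N))
  for (b in seq_len(n_boot)) {
    idx <- sample(N, n_take, replace = TRUE)
    lb <- labs[idx]
    for (fi in seq_along(fams)) {
      m <- lb == fams[fi]
      if (any(m)) acc[b, fi, ] <- colMeans(prevalences[idx[m], , drop = FALSE])
    }
  }
  centroids <- matrix(NA_real_, length(fams), R,
                      dimnames = list(fams, colnames(prevalences)))
  for (fi in seq_along(fams)) {
    for (r in seq_len(R)) {
      centroids[fi, r] <- median(acc[, fi, r], na.rm = TRUE)
    }
  }
  centroids
}

#' Build the morpho-electrophysiological (ME) hierarchy
#'
#' Pairwise Euclidean distances between family centroids are normalized by
#' their maximum, agglomerated with average linkage, and the dendrogram is
#' cut at `threshold` (on the normalized distance) to yield the ME classes.
#'
#' @param centroids Families x R matrix from [bootstrap_centroids()].
#' @param threshold Cut height in `(0, 1]` on the normalized distance.
#' @return An `me_hierarchy`: list with `centroids`, `distance_matrix`
#'   (normalized, symmetric, zero diagonal, max 1), `linkage` (hclust),
#'   `threshold`, `me_assignment` (named integer vector family -> class),
#'   `n_me_classes`.
#' @export
build_hierarchy <- function(centroids, threshold = 0.45) {
  if (nrow(centroids) < 2L) abort("need at least two families",
                                  class = "eap_usage_error")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]", class = "eap_config_error")
  }
  D <- as.matrix(dist(centroids))
  mx <- max(D)
  Dn <- if (mx > 0) D / mx else D
  hc <- hclust(as.dist(Dn), method = "average")
  classes <- cutree(hc, h = threshold)
  stopifnot(isTRUE(all.equal(Dn, t(Dn))), all(diag(Dn) == 0),
            mx == 0 || abs(max(Dn) - 1) < 1e-12)
  structure(list(
    centroids = centroids, distance_matrix = Dn, linkage = hc,
    threshold = threshold, me_assignment = classes,
    n_me_classes = length(unique(classes))), class = "me_hierarchy")
}

#' @export
print.me_hierarchy <- function(x, ...) {
  cat("<me_hierarchy>", nrow(x$centroids), "families ->", x$n_me_classes,
      "ME classes at threshold", x$threshold, "\n")
  invisible(x)
}

#' Choose the cut threshold giving a target number of ME classes
#'
#' Scans normalized-distance thresholds and returns the largest one that
#' yields the requested class count (the class count is monotonically
#' non-increasing in the threshold), or `NA` when no threshold does.
#'
#' @param centroids Families x R centroid matrix.
#' @param n_classes Target ME class count (the full-scale analysis uses 6).
#' @return Scalar threshold or `NA`.
#' @export
threshold_for_classes <- function(centroids, n_classes) {
  D <- as.matrix(dist(centroids))
  mx <- max(D)
  if (mx == 0) return(NA_real_)
  hc <- hclust(as.dist(D / mx), method = "average")
  heights <- sort(unique(c(hc$height, 1)))
  for (h in rev(heights)) {
    k <- length(unique(cutree(hc, h = h - 1e-9)))
    if (k == n_classes) return(h - 1e-9)
  }
  NA_real_
}

#' Leave-one-out exclusion analysis over ME classes
#'
#' For each ME class: its units are dropped, the wavelet features and the
#' non-negative CP decomposition are recomputed at the original rank, and
#' the refitted model is compared to the original by the two shared modes
#' (spatial, temporal) of [decomposition_similarity()]; an ME-type random
#' forest is retrained on the remaining units and its out-of-bag accuracy
#' change is reported. Exclusions leaving fewer than two families are
#' skipped.
#'
#' @param X 31 x 128 x N data tensor.
#' @param meta Unit metadata aligned to the third axis (`family` column).
#' @param model The original fitted `demix_model`.
#' @param hierarchy An `me_hierarchy` over the same families.
#' @param n_restarts Restarts per refit (default 2).
#' @param seed Integer seed.
#' @param tol,max_iter Passed to [ncp_bcd()].
#' @return List: `results` (tibble: me_class, similarity, accuracy,
#'   accuracy_delta, n_units), `spatial_sources` (list of refitted spatial
#'   factors for overlay), `baseline_accuracy`.
#' @export
exclusion_analysis <- function(X, meta, model, hierarchy, n_restarts = 2L,
                               seed = 0L, tol = 1e-6, max_iter = 200L) {
  me_of_family <- hierarchy$me_assignment
  me_labels <- me_of_family[as.character(meta$family)]
  baseline_acc <- .rf_oob_accuracy(model$prevalence, factor(me_labels),
                                   seed = seed)
  rows <- list()
  overlays <- list()
  for (cls in sort(unique(me_labels))) {
    keep <- which(me_labels != cls)
    if (length(unique(meta$family[keep])) < 2L) {
      inform(paste0("excluding ME class ", cls,
                    " leaves < 2 families; skipped"))
      next
    }
    Fsub <- build_feature_tensor(X[, , keep, drop = FALSE])
    refit <- ncp_restarts(Fsub, model$R, n_restarts = n_restarts,
                          base_seed = seed + 10L * cls, tol = tol,
                          max_iter = max_iter)$best
    sim <- decomposition_similarity(model, refit,
                                    modes = c("spatial", "temporal"))
    acc <- .rf_oob_accuracy(refit$prevalence,
                            factor(me_labels[keep]), seed = seed)
    rows[[length(rows) + 1L]] <- tibble(
      me_class = cls, similarity = as.numeric(sim), accuracy = acc,
      accuracy_delta = acc - baseline_acc, n_units = length(keep))
    overlays[[as.character(cls)]] <- refit$spatial
  }
  list(results = dplyr::bind_rows(rows), spatial_sources = overlays,
       baseline_accuracy = baseline_acc)
}
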