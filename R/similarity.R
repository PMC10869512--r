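# Hungarian algorithm (shortest augmenting paths), minimizes total cost of a
# square assignment. Returns for each row the assigned column.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  VIRT <- n + 1L                       # virtual column index
  u <- numeric(n)                      # row potentials
  v <- numeric(VIRT)                   # column potentials (incl. virtual)
  p <- integer(VIRT)                   # p[j]: row matched to column j (0 = none)
  way <- integer(VIRT)
  for (i in seq_len(n)) {
    p[VIRT] <- i
    j0 <- VIRT
    minv <- rep(Inf, VIRT)
    used <- rep(FALSE, VIRT)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(VIRT)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VIRT) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}

# cosine-normalize the columns of a matrix (zero columns stay zero)
.colcos <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

#' Similarity between two CP decompositions
#'
#' Matches the components of `b` one-to-one to those of `a` so that the
#' summed per-pair agreement is maximal (Hungarian assignment); per-pair
#' agreement is the product over the compared modes of the cosine
#' similarity of the matched factor columns; the score is the mean matched
#' agreement. Invariant to component permutation and to positive rescaling
#' within a component.
#'
#' @param a,b `demix_model` objects of equal rank.
#' @param modes Factor modes entering the agreement product (default all
#'   three; the exclusion analysis uses `c("spatial", "temporal")` since
#'   its unit axes differ).
#' @return Scalar score in `[0, 1]`; attribute `"matching"` gives the
#'   column of `b` matched to each column of `a`.
#' @export
decomposition_similarity <- function(a, b,
                                     modes = c("spatial", "temporal",
                                               "prevalence")) {
  if (!identical(a$R, b$R)) abort("rank mismatch between decompositions",
                                  class = "eap_usage_error")
  M <- matrix(1, a$R, a$R)
  for (mode in modes) {
    M <- M * (crossprod(.colcos(a[[mode]]), .colcos(b[[mode]])))
  }
  M <- pmin(pmax(M, -1), 1)
  assign <- hungarian_assignment(max(M) - M)
  score <- mean(M[cbind(seq_len(a$R), assign)])
  structure(score, matching = assign)
}

#' Restart-similarity rank selection
#'
#' For each candidate rank R, fits `n_restarts` independently seeded
#' decompositions, takes the lowest-error fit as reference and computes the
#' mean similarity of the remaining fits against it. Ranks with mean
#' similarity above `sim_threshold` form the candidate set; candidates are
#' scored by a random-forest classifier (out-of-bag accuracy) predicting
#' the family labels from the unit prevalences, and the selected rank is
#' the largest candidate whose accuracy is maximal (accuracy ties break
#' toward the larger rank). If no rank clears the similarity threshold the
#' most similar rank is returned with a flag.
#'
#' @param F_tensor Non-negative feature tensor.
#' @param labels Family label per unit (third-axis row), for the accuracy
#'   scoring.
#' @param R_range Candidate ranks (default 1:19).
#' @param n_restarts Restarts per rank (>= 2; default 4).
#' @param sim_threshold Mean-similarity acceptance threshold (default 0.99).
#' @param base_seed Seed; restart i at any rank uses `base_seed + i - 1`.
#' @param tol,max_iter Passed to [ncp_bcd()].
#' @return List: `R_star`, `diagnostics` (tibble: R, mean_similarity,
#'   best_error, accuracy, candidate), `flagged` (`TRUE` when no rank met
#'   the similarity threshold), `fits` (best fit per rank).
#' @export
select_rank <- function(F_tensor, labels, R_range = 1:19, n_restarts = 4L,
                        sim_threshold = 0.99, base_seed = 0L, tol = 1e-6,
                        max_iter = 500L) {
  if (n_restarts < 2L) abort("similarity needs at least 2 restarts",
                             class = "eap_usage_error")
  rows <- list()
  best_fits <- list()
  for (R in R_range) {
    res <- ncp_restarts(F_tensor, R, n_restarts = n_restarts,
                        base_seed = base_seed, tol = tol,
                        max_iter = max_iter)
    errs <- vapply(res$fits, function(m) m$reconstruction_error, numeric(1))
    ref <- res$best
    sims <- vapply(res$fits[-which.min(errs)], function(m) {
      as.numeric(decomposition_similarity(ref, m))
    }, numeric(1))
    best_fits[[as.character(R)]] <- ref
    rows[[length(rows) + 1L]] <- tibble(
      R = R, mean_similarity = mean(sims),
      best_error = ref$reconstruction_error)
  }
  diag <- dplyr::bind_rows(rows)
  diag$candidate <- diag$mean_similarity > sim_threshold
  diag$accuracy <- NA_real_
  labels <- factor(labels)
  for (k in which(diag$candidate)) {
    prev <- best_fits[[as.character(diag$R[k])]]$prevalence
    diag$accuracy[k] <- .rf_oob_accuracy(prev, labels,
                                         seed = base_seed + 1000L)
  }
  flagged <- !any(diag$candidate)
  if (flagged) {
    R_star <- diag$R[which.max(diag$mean_similarity)]
    warn("no rank met the similarity threshold; returning the most similar")
  } else {
    cand <- diag[diag$candidate, ]
    best_acc <- max(cand$accuracy)
    R_star <- max(cand$R[cand$accuracy >= best_acc - 1e-12])
  }
  list(R_star = as.integer(R_star), diagnostics = diag, flagged = flagged,
       fits = best_fits)
}

# quick OOB accuracy of a default random forest on a feature matrix
.rf_oob_accuracy <- function(features, labels, seed = 0L, num_trees = 300L) {
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(labels)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, seed = as.integer(seed))
  1 - fit$prediction.error
}

#' Order the components of a demix model by classification importance
#'
#' Fits a random forest on the unit prevalences against the family labels,
#' extracts Gini (impurity) importances of the R prevalence features, and
#' permutes the columns of all three factor matrices into
#' decreasing-importance order.
#'
#' @param model A fitted `demix_model`.
#' @param labels Family label per prevalence row; needs >= 2 classes.
#' @param seed Random-forest seed.
#' @param num_trees Forest size.
#' @return List: `model` (column-permuted copy), `importance` (vector in
#'   the new order), `order` (permutation applied).
#' @export
order_sources <- function(model, labels, seed = 0L, num_trees = 500L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("need at least two classes to order sources",
                                  class = "eap_usage_error")
  df <- as.data.frame(model$prevalence)
  names(df) <- paste0("src", seq_len(ncol(df)))
  df$.y <- labels
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, importance = "impurity",
                        seed = as.integer(seed))
  imp <- fit$variable.importance
  ord <- order(imp, decreasing = TRUE)
  out <- model
  out$spatial <- model$spatial[, ord, drop = FALSE]
  out$temporal <- model$temporal[, ord, drop = FALSE]
  out$prevalence <- model$prevalence[, ord, drop = FALSE]
  out$component_scales <- model$component_scales[ord]
  list(model = out, importance = imp[ord], order = ord)
}
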