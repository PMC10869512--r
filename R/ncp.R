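# column-wise Khatri-Rao product: (rows(A)*rows(B)) x R, B's index fastest
khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# one HALS pass over the columns of factor U for unfolding M = F_(mode),
# with MKR = M %*% khatri_rao(...), G = gram product of the other two factors
.hals_update <- function(U, MKR, G) {
  R <- ncol(U)
  for (r in seq_len(R)) {
    g <- G[r, r]
    if (g < .Machine$double.eps) next
    u <- U[, r] + (MKR[, r] - U %*% G[, r]) / g
    U[, r] <- pmax(u, 0)
  }
  U
}

#' Non-negative CP decomposition by block coordinate descent
#'
#' Fits the rank-R non-negative canonical polyadic model
#' `F[s, w, n] ~ sum_r spatial[s, r] * temporal[w, r] * prevalence[n, r]`
#' by alternating non-negative block updates (HALS within each mode),
#' minimizing the Frobenius reconstruction error. The relative error is
#' tracked every iteration and verified to be non-increasing; iteration
#' stops when its change drops below `tol` or at `max_iter`. Spatial and
#' temporal columns are normalized to unit Euclidean norm with the scale
#' pushed into the prevalences.
#'
#' @param F_tensor Non-negative S x W x N array (see
#'   [build_feature_tensor()]).
#' @param R Number of components (rank), >= 1.
#' @param tol Stop when the relative-error change per iteration falls below
#'   this (default 1e-6).
#' @param max_iter Maximum BCD iterations (default 500).
#' @param seed Integer seed for the random non-negative initialization.
#' @return A `demix_model`: list with `R`, `spatial` (S x R), `temporal`
#'   (W x R), `prevalence` (N x R), `component_scales`,
#'   `reconstruction_error` (relative Frobenius), `error_history`,
#'   `converged`, `iterations`, `seed`.
#' @export
ncp_bcd <- function(F_tensor, R, tol = 1e-6, max_iter = 500L, seed = 0L) {
  d <- dim(F_tensor)
  if (length(d) != 3L) abort("F must be a 3-way array",
                             class = "eap_input_error")
  if (any(!is.finite(F_tensor)) || any(F_tensor < 0)) {
    abort("F must be finite and non-negative", class = "eap_input_error")
  }
  if (R < 1L) abort("rank must be >= 1", class = "eap_usage_error")
  S <- d[1]; W <- d[2]; N <- d[3]
  normF2 <- sum(F_tensor^2)
  if (normF2 == 0) {
    return(structure(list(
      R = as.integer(R), spatial = matrix(0, S, R),
      temporal = matrix(0, W, R), prevalence = matrix(0, N, R),
      component_scales = numeric(R), reconstruction_error = 0,
      error_history = 0, converged = TRUE, iterations = 0L,
      seed = as.integer(seed)), class = "demix_model"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  A <- matrix(runif(S * R), S, R)
  B <- matrix(runif(W * R), W, R)
  C <- matrix(runif(N * R), N, R)
  # scale the random init to the tensor norm
  est2 <- sum((crossprod(A) * crossprod(B)) * crossprod(C))
  sc <- (normF2 / est2)^(1 / 6)
  A <- A * sc; B <- B * sc; C <- C * sc

  F1 <- matrix(F_tensor, S, W * N)                     # cols: (w, n), w fastest
  F2 <- matrix(aperm(F_tensor, c(2, 1, 3)), W, S * N)  # cols: (s, n), s fastest
  F3 <- matrix(aperm(F_tensor, c(3, 1, 2)), N, S * W)  # cols: (s, w), s fastest

  err_hist <- numeric(0)
  prev_err <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- .hals_update(A, F1 %*% khatri_rao(C, B), crossprod(B) * crossprod(C))
    B <- .hals_update(B, F2 %*% khatri_rao(C, A), crossprod(A) * crossprod(C))
    M3 <- F3 %*% khatri_rao(B, A)
    G3 <- crossprod(A) * crossprod(B)
    C <- .hals_update(C, M3, G3)
    err2 <- normF2 - 2 * sum(C * M3) + sum((G3) * crossprod(C))
    # monotonicity of the squared objective, with roundoff slack (the
    # subtraction cancels catastrophically once the fit is near-exact)
    if (!is.null(attr(err_hist, "prev2")) &&
        err2 > attr(err_hist, "prev2") + 1e-9 * normF2) {
      abort("BCD objective increased", class = "eap_internal_error")
    }
    attr(err_hist, "prev2") <- err2
    err <- sqrt(max(err2, 0) / normF2)
    prev2 <- attr(err_hist, "prev2")
    err_hist <- c(err_hist, err)
    attr(err_hist, "prev2") <- prev2
    if (is.finite(prev_err) && abs(prev_err - err) < tol) {
      converged <- TRUE
      break
    }
    prev_err <- err
  }
  stopifnot(all(A >= 0), all(B >= 0), all(C >= 0))

  # normalization convention: unit-norm spatial/temporal, scale in prevalence
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  for (r in seq_len(R)) {
    if (na[r] > 0) A[, r] <- A[, r] / na[r]
    if (nb[r] > 0) B[, r] <- B[, r] / nb[r]
    C[, r] <- C[, r] * na[r] * nb[r]
  }
  attr(err_hist, "prev2") <- NULL
  structure(list(
    R = as.integer(R), spatial = A, temporal = B, prevalence = C,
    component_scales = sqrt(colSums(C^2)),
    reconstruction_error = err_hist[length(err_hist)],
    error_history = err_hist, converged = converged, iterations = it,
    seed = as.integer(seed)), class = "demix_model")
}

#' @export
print.demix_model <- function(x, ...) {
  cat("<demix_model> R =", x$R,
      " rel. error =", signif(x$reconstruction_error, 4),
      " iterations =", x$iterations,
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Fit several restarts and keep the best
#'
#' Runs [ncp_bcd()] with seeds `base_seed + 0:(n_restarts-1)` and returns
#' the fit with the lowest reconstruction error plus all fits.
#'
#' @inheritParams ncp_bcd
#' @param n_restarts Number of independently seeded fits.
#' @param base_seed First seed; restart i uses `base_seed + i - 1`.
#' @return List: `best` (a `demix_model`), `fits` (list of all fits).
#' @export
ncp_restarts <- function(F_tensor, R, n_restarts = 4L, base_seed = 0L,
                         tol = 1e-6, max_iter = 500L) {
  fits <- lapply(seq_len(n_restarts) - 1L, function(i) {
    ncp_bcd(F_tensor, R, tol = tol, max_iter = max_iter,
            seed = base_seed + i)
  })
  errs <- vapply(fits, function(m) m$reconstruction_error, numeric(1))
  list(best = fits[[which.min(errs)]], fits = fits)
}
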