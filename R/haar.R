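#' Orthonormal Haar multiresolution transform
#'
#' Full-depth orthonormal Haar analysis of a power-of-two length series.
#' For length 128 this yields 7 detail levels plus one approximation
#' coefficient, concatenated coarse-to-fine:
#' `[approx, d7 (1), d6 (2), d5 (4), d4 (8), d3 (16), d2 (32), d1 (64)]`.
#' The transform is orthonormal, so Parseval holds exactly.
#'
#' @param x Numeric series, length a power of two.
#' @return Numeric coefficient vector of the same length, with attribute
#'   `"level_boundaries"` (tibble: level, start, end).
#' @export
haar_transform <- function(x) {
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    abort("series length must be a power of two", class = "eap_shape_error")
  }
  n_levels <- as.integer(log2(n))
  a <- x
  details <- vector("list", n_levels)
  for (lev in seq_len(n_levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[lev]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  coeffs <- c(a, unlist(rev(details)))
  sizes <- c(1L, 2L^(0:(n_levels - 1L)))
  labels <- c("approx", paste0("d", n_levels:1))
  ends <- cumsum(sizes)
  attr(coeffs, "level_boundaries") <-
    tibble(level = labels, start = ends - sizes + 1L, end = ends)
  coeffs
}

#' Inverse orthonormal Haar transform
#'
#' Exact inverse of [haar_transform()] (for coefficients that did not go
#' through the absolute value).
#'
#' @param coeffs Coefficient vector in the package's coarse-to-fine order.
#' @return Reconstructed series.
#' @export
haar_inverse <- function(coeffs) {
  n <- length(coeffs)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    abort("coefficient length must be a power of two",
          class = "eap_shape_error")
  }
  n_levels <- as.integer(log2(n))
  a <- coeffs[1]
  pos <- 2L
  for (lev in n_levels:1) {
    d <- coeffs[pos:(pos + length(a) - 1L)]
    pos <- pos + length(a)
    out <- numeric(2L * length(a))
    out[seq(1, length(out), 2)] <- (a + d) / sqrt(2)
    out[seq(2, length(out), 2)] <- (a - d) / sqrt(2)
    a <- out
  }
  a
}

# cached orthonormal Haar analysis matrix (coeffs = H %*% x)
haar_matrix <- function(n = 128L) {
  key <- paste0("H", n)
  if (!is.null(.eap_cache[[key]])) return(.eap_cache[[key]])
  H <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    as.numeric(haar_transform(e))
  }, numeric(n))
  .eap_cache[[key]] <- H
  H
}

#' Haar multiresolution magnitude features of one waveform
#'
#' Absolute values of the full-depth orthonormal Haar coefficients. The
#' absolute value makes the representation invariant to waveform inversion
#' (sign flip), so EAPs generated by opposite poles of a current dipole map
#' to the same features.
#'
#' @param waveform 128-sample series (any power-of-two length accepted).
#' @return Non-negative coefficient vector with `"level_boundaries"`.
#' @export
haar_features <- function(waveform) {
  coeffs <- haar_transform(waveform)
  out <- abs(coeffs)
  attr(out, "level_boundaries") <- attr(coeffs, "level_boundaries")
  out
}

#' Assemble the feature tensor F from the data tensor X
#'
#' Applies [haar_features()] to every channel of every unit:
#' `F[s, , n] = |Haar(X[s, , n])|`, giving a non-negative S x W x N tensor
#' with W = T.
#'
#' @param X 31 x 128 x N data tensor (from [balance_dataset()], or any
#'   S x T x N array with T a power of two).
#' @return S x W x N array with attribute `"level_boundaries"`.
#' @export
build_feature_tensor <- function(X) {
  d <- dim(X)
  H <- haar_matrix(d[2])
  # coefficients for all channels/units in one multiply per unit
  Fv <- array(0, dim = d)
  for (n in seq_len(d[3])) {
    Fv[, , n] <- abs(t(H %*% t(X[, , n])))
  }
  attr(Fv, "level_boundaries") <-
    attr(haar_transform(numeric(d[2])), "level_boundaries")
  Fv
}

#' Normalize each unit's waveform matrix by its maximum amplitude
#'
#' Divides every unit's S x T waveform matrix by the unit's maximum
#' peak-to-trough amplitude across channels, so source loadings describe
#' the relative composition of each unit's EAP rather than its absolute
#' magnitude. Without this, every loading simply decays with recording
#' distance; with it, the relative contribution of dendritic (and noise)
#' sources grows with distance while the perisomatic contribution shrinks.
#'
#' @param X S x T x N data tensor.
#' @return Tensor of the same shape; all-zero units are left untouched.
#' @export
normalize_units <- function(X) {
  for (n in seq_len(dim(X)[3])) {
    a <- max(amplitude_profile(X[, , n]))
    if (a > 0) X[, , n] <- X[, , n] / a
  }
  X
}

#' Reconstruct the temporal dynamics of a multiresolution source
#'
#' Treats a non-negative multiresolution temporal source `w` as a Haar
#' coefficient vector and applies the inverse transform; the output is read
#' as the magnitude of the source's contribution over time.
#'
#' @param w_r Non-negative W-vector (a `temporal` column of a demix model).
#' @param rectify If `TRUE`, return absolute values (display convention).
#' @return 128-sample trace.
#' @export
reconstruct_temporal_source <- function(w_r, rectify = FALSE) {
  if (any(w_r < 0)) abort("temporal source must be non-negative",
                          class = "eap_shape_error")
  out <- haar_inverse(as.numeric(w_r))
  if (rectify) abs(out) else out
}
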