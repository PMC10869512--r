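#' Quasi-static line-source kernel for one segment
#'
#' Returns the extracellular potential per unit current (uV/nA) generated at
#' `point` by a uniform line source along the segment in an infinite
#' homogeneous, isotropic volume conductor of conductivity `sigma`.
#' Dendritic/axonal segments use the line-source approximation (LSA); the
#' soma is treated as a point source at its center. The perpendicular
#' (respectively radial) distance is clamped at 1 um to avoid the
#' singularity on the source axis.
#'
#' @param seg One-row segment tibble (as in `morphology$segments`).
#' @param point Numeric xyz triple, um.
#' @param sigma Extracellular conductivity, S/m (default 0.3).
#' @return Scalar kernel in uV per nA.
#' @export
line_source_potential <- function(seg, point, sigma = 0.3) {
  if (sigma <= 0) abort("sigma must be > 0", class = "eap_config_error")
  a <- c(seg$px, seg$py, seg$pz)
  b <- c(seg$dx, seg$dy, seg$dz)
  if (identical(seg$domain, "soma")) {
    mid <- (a + b) / 2
    r <- max(sqrt(sum((point - mid)^2)), 1)
    return(1e3 / (4 * pi * sigma * r))
  }
  u <- b - a
  L <- sqrt(sum(u^2))
  if (L < 1e-9) {
    r <- max(sqrt(sum((point - a)^2)), 1)
    return(1e3 / (4 * pi * sigma * r))
  }
  u <- u / L
  w <- point - a
  s0 <- sum(w * u)                       # longitudinal coordinate of the point
  rho2 <- max(sum(w^2) - s0^2, 0)
  rho <- max(sqrt(rho2), 1)              # clamped perpendicular distance
  val <- asinh((L - s0) / rho) - asinh(-s0 / rho)
  1e3 / (4 * pi * sigma * L) * val
}

# kernel matrix: points (rows) x segments (cols), uV/nA
forward_kernel <- function(morph, points, sigma = 0.3) {
  if (sigma <= 0) abort("sigma must be > 0", class = "eap_config_error")
  segs <- morph$segments
  K <- matrix(0, nrow(points), nrow(segs))
  for (j in seq_len(nrow(segs))) {
    seg <- segs[j, ]
    for (i in seq_len(nrow(points))) {
      K[i, j] <- line_source_potential(seg, as.numeric(points[i, ]), sigma)
    }
  }
  K
}

#' Extracellular potentials from current templates
#'
#' Superposes the line-source contributions of all segments:
#' `V_e(point, t) = sum_seg kernel(seg, point) * I_seg(t)`. Linear in the
#' currents by construction.
#'
#' @param morph A `morphology`.
#' @param templates Matching `current_templates`.
#' @param points Numeric matrix (n x 3) of evaluation points, um.
#' @param sigma Extracellular conductivity, S/m.
#' @return Matrix (points x time), uV.
#' @export
simulate_extracellular <- function(morph, templates, points, sigma = 0.3) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points))) abort("non-finite evaluation point",
                                     class = "eap_config_error")
  if (!identical(as.integer(morph$segments$id),
                 as.integer(templates$segment_ids))) {
    abort("segment ids of morphology and templates do not match",
          class = "eap_integrity_error")
  }
  K <- forward_kernel(morph, points, sigma)
  K %*% templates$currents
}
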