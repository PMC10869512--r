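#' Default detectability-scan grid
#'
#' Ten uniformly random angles in the XZ plane, 21 radial distances from 10
#' to 110 um in 5 um increments, and five Y offsets (20, 10, 0, -10, -20
#' um): 1,050 evaluation locations in total.
#'
#' @param n_angles Number of random angles.
#' @param radii Radial distances, um.
#' @param y_offsets Y offsets of the radial grids, um.
#' @param threshold Detectability amplitude threshold, uV.
#' @return Named list of grid parameters.
#' @export
default_grid_spec <- function(n_angles = 10L,
                              radii = seq(10, 110, by = 5),
                              y_offsets = c(20, 10, 0, -10, -20),
                              threshold = 20) {
  list(n_angles = as.integer(n_angles), radii = radii,
       y_offsets = y_offsets, threshold = threshold)
}

#' Detectability scan of a model
#'
#' Evaluates the extracellular action potential at every grid location,
#' records the peak-to-trough amplitude (max - min of the waveform) and
#' derives the detectability limit: the mean over (angle, Y-offset) rays of
#' the largest radius whose amplitude still reaches the threshold (rays with
#' no qualifying radius are excluded from the mean). Additionally fits
#' `A(r) = A0 * exp(-r / lambda)` to the per-radius mean amplitudes and
#' flags the model undetectable when the extrapolated amplitude at 1 um
#' falls below the threshold.
#'
#' @param morph A `morphology`.
#' @param templates Matching `current_templates`.
#' @param grid_spec See [default_grid_spec()].
#' @param sigma Extracellular conductivity, S/m.
#' @param seed Integer seed for the random angles.
#' @return List: `amplitudes` (tibble angle/y_offset/r/amplitude), `limit`
#'   (um, `NA` when undetectable), `undetectable` (flag), `fit`
#'   (`A0`, `lambda`, `amp_at_1um`).
#' @export
detectability_scan <- function(morph, templates,
                               grid_spec = default_grid_spec(),
                               sigma = 0.3, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  angles <- runif(grid_spec$n_angles, 0, 2 * pi)

  grid <- expand.grid(angle = angles, y_offset = grid_spec$y_offsets,
                      r = grid_spec$radii, KEEP.OUT.ATTRS = FALSE)
  pts <- cbind(grid$r * cos(grid$angle), grid$y_offset,
               grid$r * sin(grid$angle))
  V <- simulate_extracellular(morph, templates, pts, sigma)
  amp <- apply(V, 1, function(x) max(x) - min(x))
  amps <- tibble(angle = grid$angle, y_offset = grid$y_offset,
                 r = grid$r, amplitude = amp)
  thr <- grid_spec$threshold

  limit_summary <- amps |>
    dplyr::group_by(.data$angle, .data$y_offset) |>
    dplyr::summarise(
      max_ok = if (any(.data$amplitude >= thr))
        max(.data$r[.data$amplitude >= thr]) else NA_real_,
      .groups = "drop")
  ok <- limit_summary$max_ok[!is.na(limit_summary$max_ok)]
  limit <- if (length(ok) > 0) mean(ok) else NA_real_

  mean_amp <- amps |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  fit <- list(A0 = NA_real_, lambda = NA_real_, amp_at_1um = NA_real_)
  pos <- mean_amp$amplitude > 0
  if (sum(pos) >= 2) {
    co <- coef(lm(log(amplitude) ~ r, data = mean_amp[pos, ]))
    fit$A0 <- exp(co[[1]])
    fit$lambda <- -1 / co[[2]]
    fit$amp_at_1um <- exp(co[[1]] + co[[2]] * 1)
  }
  undetectable <- is.na(limit) ||
    (is.finite(fit$amp_at_1um) && fit$amp_at_1um < thr)

  list(amplitudes = amps, limit = limit, undetectable = undetectable,
       fit = fit)
}

#' Sample probe placements within the detectability limit
#'
#' Draws `n_locations` placements of a 64-channel linear probe (10 um
#' pitch): radial distance uniform on (10, limit) in the XZ plane, angle
#' uniform on (0, 2 pi), and a uniform +/- 5 um Y jitter of the probe
#' center, which is otherwise aligned to the soma depth.
#'
#' @param morph A `morphology` (carried into the placement metadata).
#' @param limit Detectability limit, um; must exceed 10.
#' @param n_locations Number of placements (default 100).
#' @param seed Integer seed.
#' @return Tibble with one row per placement: `angle`, `r`, `jitter`, and a
#'   list-column `channel_xyz` of 64 x 3 matrices (rows ordered by
#'   ascending Y).
#' @export
sample_probes <- function(morph, limit, n_locations = 100L, seed = 0L) {
  if (!is.finite(limit) || limit <= 10) {
    warn(sprintf("detectability limit %.1f um <= 10 um: model '%s' skipped",
                 limit, morph$family))
    return(tibble(angle = numeric(), r = numeric(), jitter = numeric(),
                  channel_xyz = list()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- as.integer(n_locations)
  r <- runif(n, 10, limit)
  angle <- runif(n, 0, 2 * pi)
  jitter <- runif(n, -5, 5)
  ch_rel <- (seq_len(64) - 32.5) * 10     # 10 um pitch, centered
  channel_xyz <- lapply(seq_len(n), function(i) {
    cbind(rep(r[i] * cos(angle[i]), 64), jitter[i] + ch_rel,
          rep(r[i] * sin(angle[i]), 64))
  })
  tibble(angle = angle, r = r, jitter = jitter, channel_xyz = channel_xyz)
}

#' Simulate one raw single-unit recording
#'
#' Evaluates the forward model at the 64 channel locations of one probe
#' placement.
#'
#' @param morph A `morphology`.
#' @param templates Matching `current_templates`.
#' @param placement One row of the tibble from [sample_probes()].
#' @param sigma Extracellular conductivity, S/m.
#' @return A `raw_recording`: list with `waveforms` (64 x T uV),
#'   `somatic_vm`, `spike_index` (1-based), `dt`, `meta` (family, variant,
#'   angle, r, jitter).
#' @export
simulate_unit <- function(morph, templates, placement, sigma = 0.3) {
  V <- simulate_extracellular(morph, templates, placement$channel_xyz[[1]],
                              sigma)
  structure(
    list(waveforms = V, somatic_vm = templates$somatic_vm,
         spike_index = templates$spike_index, dt = templates$dt,
         meta = tibble(family = morph$family, variant = morph$variant,
                       angle = placement$angle, r = placement$r,
                       jitter = placement$jitter)),
    class = "raw_recording"
  )
}
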