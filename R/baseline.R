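# linear interpolation of a sampled waveform at continuous time t (ms),
# samples at (i - spike_index) * dt
.wf_at <- function(wf, t, spike_index, dt) {
  pos <- t / dt + spike_index          # fractional 1-based sample
  pos <- min(max(pos, 1), length(wf))
  i <- floor(pos)
  frac <- pos - i
  if (i >= length(wf)) return(wf[length(wf)])
  wf[i] * (1 - frac) + wf[i + 1] * frac
}

#' Baseline single- and multi-channel waveform features
#'
#' The conventional engineered features computed from the center-channel
#' waveform (trough = global minimum; peak = maximum after the trough):
#' peak-to-trough duration, depolarization half-width (time between the
#' crossings of 50% of the trough voltage), peak-to-trough ratio,
#' repolarization and recovery slopes (waveform value 30 us after the
#' trough/peak minus the trough/peak value, over 30 us, with sub-sample
#' linear interpolation), plus two multichannel features: spread (range of
#' channel distances with amplitudes above 12% of the maximum amplitude)
#' and total propagation velocity (|median slope| of channel distance over
#' trough-time difference, above plus below the center; channels whose
#' trough-time difference is under dt/2 are excluded, and a side with no
#' usable channel contributes 0).
#'
#' @param unit A `centered_unit` (31 x 128, center row 16) or a list with
#'   `waveforms`, `spike_index`, `dt`.
#' @param dt Sample interval, ms (defaults to the unit's).
#' @param pitch Channel pitch, um.
#' @return One-row tibble of features; `flagged` is `TRUE` when no peak
#'   follows the trough (peak-dependent features are `NA`).
#' @export
baseline_features <- function(unit, dt = NULL, pitch = 10) {
  wf_all <- unit$waveforms
  if (is.null(dt)) dt <- unit$dt
  spike <- unit$spike_index
  center_row <- (nrow(wf_all) + 1L) %/% 2L
  wf <- wf_all[center_row, ]
  t_of <- function(i) (i - spike) * dt

  trough_i <- which.min(wf)
  trough_v <- wf[trough_i]
  t_trough <- t_of(trough_i)
  flagged <- trough_i >= length(wf)
  if (!flagged) {
    after <- (trough_i + 1L):length(wf)
    peak_i <- after[which.max(wf[after])]
    peak_v <- wf[peak_i]
    t_peak <- t_of(peak_i)
  } else {
    peak_i <- NA_integer_; peak_v <- NA_real_; t_peak <- NA_real_
  }

  duration <- if (flagged) NA_real_ else t_peak - t_trough
  ratio <- if (flagged || trough_v == 0) NA_real_ else abs(peak_v / trough_v)

  # depolarization half-width: crossings of 0.5 * trough voltage
  half <- 0.5 * trough_v
  half_width <- NA_real_
  left <- which(wf[seq_len(trough_i)] > half)
  right_all <- which(wf > half)
  right <- right_all[right_all > trough_i]
  if (length(left) > 0 && length(right) > 0) {
    iL <- max(left)                       # last sample above half before trough
    iR <- min(right)                      # first sample above half after trough
    cross <- function(i0, i1) {           # linear interp crossing time
      t0 <- t_of(i0); t1 <- t_of(i1)
      t0 + (half - wf[i0]) / (wf[i1] - wf[i0]) * (t1 - t0)
    }
    half_width <- cross(iR - 1L, iR) - cross(iL, iL + 1L)
  }

  eps <- 0.030                            # 30 us
  repol_slope <- (.wf_at(wf, t_trough + eps, spike, dt) - trough_v) / eps
  recov_slope <- if (flagged) NA_real_ else
    (.wf_at(wf, t_peak + eps, spike, dt) - peak_v) / eps

  # multichannel spread
  amps <- amplitude_profile(wf_all)
  ch_y <- (seq_len(nrow(wf_all)) - center_row) * pitch
  qual <- amps > 0.12 * max(amps)
  spread <- max(ch_y[qual]) - min(ch_y[qual])

  # propagation velocity from per-channel trough times
  t_tr <- vapply(seq_len(nrow(wf_all)), function(ch)
    t_of(which.min(wf_all[ch, ])), numeric(1))
  side_velocity <- function(rows) {
    if (length(rows) == 0) return(0)
    dts <- t_tr[rows] - t_tr[center_row]
    dists <- abs(ch_y[rows])
    ok <- abs(dts) >= dt / 2              # infinite-slope guard
    if (!any(ok)) return(0)
    abs(median(dists[ok] / dts[ok]))
  }
  vel_above <- side_velocity(which(ch_y > 0))
  vel_below <- side_velocity(which(ch_y < 0))

  tibble(
    peak_to_trough_duration = duration,
    depolarization_half_width = half_width,
    peak_to_trough_ratio = ratio,
    repolarization_slope = repol_slope,
    recovery_slope = recov_slope,
    spread = spread,
    propagation_velocity_above = vel_above,
    propagation_velocity_below = vel_below,
    total_propagation_velocity = vel_above + vel_below,
    flagged = flagged)
}

#' Baseline feature table for a list of centered units
#'
#' @param units List of `centered_unit` objects.
#' @return Tibble with one feature row per unit, metadata prepended.
#' @export
baseline_feature_table <- function(units) {
  dplyr::bind_rows(lapply(units, function(u)
    dplyr::bind_cols(u$meta, baseline_features(u))))
}
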