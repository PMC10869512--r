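#' Extract a spike-aligned 128-sample snippet
#'
#' Cuts a 5.6 ms window (128 samples at dt = 5.6/128 ms) with a 1.4 ms
#' pre-spike interval: samples `spike_index - 32` through
#' `spike_index + 95` (1-based), so the spike lands at snippet sample 33.
#'
#' @param trace Numeric series, uV.
#' @param spike_index_raw 1-based spike sample within `trace`.
#' @param dt Sample interval, ms.
#' @return Numeric vector of length 128.
#' @export
extract_snippet <- function(trace, spike_index_raw, dt = 5.6 / 128) {
  lo <- spike_index_raw - 32L
  hi <- spike_index_raw + 95L
  if (lo < 1L || hi > length(trace)) {
    abort("snippet window exceeds trace bounds", class = "eap_boundary_error")
  }
  trace[lo:hi]
}

#' Noise configuration
#'
#' @param n_avg Number of independent noise draws averaged per channel
#'   (default 200).
#' @param target_rms Root-mean-square level the averaged noise is rescaled
#'   to, uV (default 10).
#' @param spectral_exponent Power-spectrum slope (default -1, i.e. 1/f).
#' @return A named list.
#' @export
noise_config <- function(n_avg = 200L, target_rms = 10,
                         spectral_exponent = -1) {
  if (target_rms < 0) abort("target_rms must be >= 0",
                            class = "eap_config_error")
  if (n_avg < 1) abort("n_avg must be >= 1", class = "eap_config_error")
  list(n_avg = as.integer(n_avg), target_rms = target_rms,
       spectral_exponent = spectral_exponent)
}

#' Gaussian 1/f (pink) background noise
#'
#' Generates `n_avg` independent Gaussian series spectrally shaped so power
#' is proportional to `f^spectral_exponent` (amplitude shaped by
#' `|f|^(exponent/2)`, DC bin zeroed), averages them, and rescales the
#' average to exactly `target_rms`.
#'
#' @param n_samples Series length (>= 2).
#' @param cfg A [noise_config()].
#' @return Numeric series of length `n_samples` with RMS `target_rms`.
#' @export
pink_noise <- function(n_samples, cfg = noise_config()) {
  n <- as.integer(n_samples)
  if (n < 2L) abort("n_samples must be >= 2", class = "eap_config_error")
  if (cfg$target_rms == 0) return(numeric(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / n            # symmetric frequency magnitude
  shape <- ifelse(f > 0, f^(cfg$spectral_exponent / 2), 0)
  acc <- numeric(n)
  for (i in seq_len(cfg$n_avg)) {
    x <- rnorm(n)
    acc <- acc + Re(fft(fft(x) * shape, inverse = TRUE)) / n
  }
  avg <- acc / cfg$n_avg
  rms <- sqrt(mean(avg^2))
  if (rms == 0) return(numeric(n))
  avg * (cfg$target_rms / rms)
}

#' Preprocess one raw recording into a unit recording
#'
#' Per channel: extract the 128-sample spike-aligned snippet, add an
#' independent pink-noise draw, then subtract the channel median (so every
#' returned channel has median exactly zero).
#'
#' @param raw A `raw_recording` from [simulate_unit()].
#' @param cfg A [noise_config()].
#' @return A `unit_recording`: list with `waveforms` (64 x 128 uV),
#'   `spike_index` (= 33), `dt`, `meta`.
#' @export
preprocess_unit <- function(raw, cfg = noise_config()) {
  S <- nrow(raw$waveforms)
  out <- matrix(0, S, 128L)
  for (ch in seq_len(S)) {
    snip <- extract_snippet(raw$waveforms[ch, ], raw$spike_index, raw$dt)
    snip <- snip + pink_noise(128L, cfg)
    out[ch, ] <- snip - median(snip)
  }
  structure(
    list(waveforms = out, spike_index = 33L, dt = raw$dt, meta = raw$meta),
    class = "unit_recording"
  )
}

#' Per-channel peak-to-trough amplitude profile
#'
#' `amplitude[ch] = max(waveform[ch, ]) - min(waveform[ch, ])`, the absolute
#' difference between the trough and peak of the EAP on each channel.
#'
#' @param unit A `unit_recording` (or any object with a `waveforms` matrix).
#' @return Non-negative numeric vector, one entry per channel (uV).
#' @export
amplitude_profile <- function(unit) {
  wf <- if (is.matrix(unit)) unit else unit$waveforms
  apply(wf, 1, function(x) max(x) - min(x))
}
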