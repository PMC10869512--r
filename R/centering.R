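#' Select the probe's center channel from the amplitude profile
#'
#' Collects strict local maxima of the 64-channel amplitude profile that
#' exceed 60% of the maximum amplitude (plateaus are broken toward the lower
#' channel index). A single qualifying peak is taken as the center. With
#' several, the two largest are considered and each is checked for
#' inversion: if the waveform's value at the spike sample exceeds that
#' waveform's median, it is inverted and rejected. The surviving
#' largest-amplitude candidate wins (exact amplitude ties break toward the
#' channel nearer the geometric probe center). A center with fewer than 15
#' channels on either side is invalid.
#'
#' @param profile 64-channel amplitude vector from [amplitude_profile()].
#' @param waveforms 64 x 128 waveform matrix.
#' @param spike_index 1-based spike sample within the snippet (default 33).
#' @return List: `center` (1-based channel index or `NA`), `valid`,
#'   `reason` (`"ok"`, `"both_inverted"`, `"edge"`).
#' @export
select_center_channel <- function(profile, waveforms, spike_index = 33L) {
  stopifnot(length(profile) == nrow(waveforms))
  peaks <- .local_maxima(profile)
  cand <- peaks[profile[peaks] > 0.6 * max(profile)]
  res <- function(center, valid, reason) {
    list(center = center, valid = valid, reason = reason)
  }
  pick <- if (length(cand) == 1L) {
    cand
  } else {
    ord <- order(-profile[cand], abs(cand - (length(profile) + 1) / 2))
    top2 <- cand[ord][seq_len(min(2L, length(cand)))]
    inverted <- vapply(top2, function(ch) {
      waveforms[ch, spike_index] > median(waveforms[ch, ])
    }, logical(1))
    keep <- top2[!inverted]
    if (length(keep) == 0L) return(res(NA_integer_, FALSE, "both_inverted"))
    keep[which.max(profile[keep])]
  }
  if (pick - 15L < 1L || pick + 15L > length(profile)) {
    return(res(NA_integer_, FALSE, "edge"))
  }
  res(as.integer(pick), TRUE, "ok")
}

# strict local maxima over channel index; plateaus break toward lower index
.local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok) out <- c(out, starts[i])
  }
  out
}

#' Classify a center waveform as canonical or not
#'
#' Tolerances are the mean +/- standard deviation of the full 128-sample
#' waveform. The waveform is non-canonical if (1) any sample in the
#' pre-spike interval (-0.21, 0] ms exceeds the upper tolerance, (2) its
#' global minimum occurs earlier than the pre-spike interval, or (3) no
#' sample in the post-spike interval (0 to 0.42 ms) falls below the lower
#' tolerance. The first violated rule is reported.
#'
#' @param waveform Median-shifted 128-sample center waveform, uV.
#' @param spike_index 1-based spike sample (default 33).
#' @param dt Sample interval, ms.
#' @return List: `canonical` (flag), `criterion` (`"none"`,
#'   `"pre_spike_positive"`, `"early_trough"`, `"no_trough"`).
#' @export
classify_canonical <- function(waveform, spike_index = 33L, dt = 5.6 / 128) {
  m <- mean(waveform)
  s <- sd(waveform)
  pre_lo <- spike_index - 5L + 1L        # (-0.21, 0] ms: 4.8 samples -> 5
  pre <- pre_lo:spike_index
  post <- spike_index:(spike_index + 9L) # [0, 0.42] ms: 9.6 samples -> 10
  if (any(waveform[pre] > m + s)) {
    return(list(canonical = FALSE, criterion = "pre_spike_positive"))
  }
  if (which.min(waveform) < pre_lo) {
    return(list(canonical = FALSE, criterion = "early_trough"))
  }
  if (!any(waveform[post] < m - s)) {
    return(list(canonical = FALSE, criterion = "no_trough"))
  }
  list(canonical = TRUE, criterion = "none")
}

#' Crop a 64-channel unit to 31 channels around the center
#'
#' Keeps the center channel with 15 channels above and 15 below, preserving
#' the ascending-Y channel order; the center lands on row 16 (1-based).
#'
#' @param unit A `unit_recording`.
#' @param center_index 1-based center channel, must lie in 16..49.
#' @return A `centered_unit`: list with `waveforms` (31 x 128),
#'   `center_channel_original_index`, `canonical`, `rejection_criterion`,
#'   `spike_index`, `dt`, `meta`.
#' @export
crop_channels <- function(unit, center_index) {
  S <- nrow(unit$waveforms)
  if (center_index - 15L < 1L || center_index + 15L > S) {
    abort("center channel too close to the probe edge to crop 31 channels",
          class = "eap_boundary_error")
  }
  rows <- (center_index - 15L):(center_index + 15L)
  cls <- classify_canonical(unit$waveforms[center_index, ], unit$spike_index,
                            unit$dt)
  structure(
    list(waveforms = unit$waveforms[rows, , drop = FALSE],
         center_channel_original_index = as.integer(center_index),
         canonical = cls$canonical, rejection_criterion = cls$criterion,
         spike_index = unit$spike_index, dt = unit$dt, meta = unit$meta),
    class = "centered_unit"
  )
}

#' Center a batch of unit recordings
#'
#' Applies [select_center_channel()] and [crop_channels()] to each unit;
#' units with no valid center are dropped (counted in the attached summary).
#'
#' @param units List of `unit_recording` objects.
#' @return List of `centered_unit` objects; attribute `"centering_summary"`
#'   is a tibble of counts (valid, edge, both_inverted, non-canonical).
#' @export
center_units <- function(units) {
  out <- list()
  reasons <- character(0)
  for (u in units) {
    prof <- amplitude_profile(u)
    sel <- select_center_channel(prof, u$waveforms, u$spike_index)
    reasons <- c(reasons, sel$reason)
    if (!sel$valid) next
    out[[length(out) + 1L]] <- crop_channels(u, sel$center)
  }
  canon <- vapply(out, function(x) x$canonical, logical(1))
  summ <- tibble(
    n_input = length(units), n_centered = length(out),
    n_edge = sum(reasons == "edge"),
    n_both_inverted = sum(reasons == "both_inverted"),
    n_canonical = sum(canon),
    noncanonical_fraction = if (length(out)) mean(!canon) else NA_real_
  )
  inform(sprintf(
    "centering: %d/%d units centered, non-canonical fraction %.1f%%",
    summ$n_centered, summ$n_input, 100 * summ$noncanonical_fraction))
  attr(out, "centering_summary") <- summ
  out
}

#' Balance canonical units into the EAP data tensor
#'
#' Samples exactly `quota` canonical units per family without replacement
#' and assembles the 31 x 128 x N data tensor `X` (N = quota x families)
#' with a row-aligned metadata table.
#'
#' @param units List of `centered_unit` objects.
#' @param quota Units per family.
#' @param seed Integer seed for the per-family sampling.
#' @param strict If `TRUE` (default) a family below quota is an error; else
#'   it is dropped with a warning.
#' @return List: `X` (31 x 128 x N array), `meta` (tibble with family,
#'   variant, angle, r, jitter, center channel).
#' @export
balance_dataset <- function(units, quota, seed = 0L, strict = TRUE) {
  canon <- Filter(function(u) isTRUE(u$canonical), units)
  fams <- vapply(canon, function(u) u$meta$family, character(1))
  counts <- table(fams)
  short <- names(counts)[counts < quota]
  if (length(short) > 0) {
    msg <- paste0("families below quota (", quota, "): ",
                  paste(short, collapse = ", "))
    if (strict) abort(msg, class = "eap_dataset_error")
    warn(paste(msg, "- dropped"))
  }
  keep_fams <- setdiff(names(counts), short)
  if (length(keep_fams) == 0) abort("no family reaches the quota",
                                    class = "eap_dataset_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sel <- integer(0)
  for (f in sort(keep_fams)) {
    idx <- which(fams == f)
    sel <- c(sel, sort(sample(idx, quota)))
  }
  N <- length(sel)
  X <- array(0, dim = c(31L, 128L, N))
  meta <- vector("list", N)
  for (i in seq_along(sel)) {
    u <- canon[[sel[i]]]
    X[, , i] <- u$waveforms
    meta[[i]] <- dplyr::mutate(
      u$meta, center_channel = u$center_channel_original_index)
  }
  list(X = X, meta = dplyr::bind_rows(meta))
}
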