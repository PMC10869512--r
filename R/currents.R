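#' Default action-potential phase parameters
#'
#' Parameters of the kinematic (prescribed) transmembrane current templates.
#' The somatic action potential is decomposed into four phases relative to
#' the somatic membrane-potential peak (the spike time): capacitive (I),
#' depolarization (II), repolarization (III) and recovery (IV). Amplitudes
#' are in nA, times in ms.
#'
#' @param amp Peak inward (depolarization) current amplitude scale, nA, for
#'   a model with total stem cross-sectional area `csa_ref`; the effective
#'   amplitude scales as `(total_stem_csa / csa_ref)^csa_exponent`,
#'   reflecting that EAP amplitude grows with the summed cross-sectional
#'   area of the neurites meeting the soma.
#' @param csa_ref Reference total stem CSA, um^2.
#' @param csa_exponent Exponent of the CSA amplitude scaling.
#' @param dt Sample interval, ms. The default makes a 5.6 ms snippet exactly
#'   128 samples.
#' @param n_samples Raw template length in samples.
#' @param spike_index 1-based sample of the somatic Vm peak in the raw trace.
#' @param ais_lead Lead of the AIS current relative to the soma, ms.
#' @param velocity Dendritic propagation speed used for per-segment delays,
#'   um/ms.
#' @return A named list of phase parameters.
#' @export
default_ap_params <- function(amp = 9, dt = 5.6 / 128, n_samples = 256L,
                              spike_index = 113L, ais_lead = 0.05,
                              velocity = 150, csa_ref = 50,
                              csa_exponent = 1 / 3) {
  list(
    amp = amp, dt = dt, n_samples = as.integer(n_samples),
    spike_index = as.integer(spike_index), ais_lead = ais_lead,
    velocity = velocity, csa_ref = csa_ref, csa_exponent = csa_exponent,
    # gaussian phase components: (relative amplitude, center ms, width ms);
    # the depolarization trough sits just after the somatic Vm peak so the
    # perisomatic EAP trough follows the intracellular spike time
    cap  = c(a = 0.06, mu = -0.18, sd = 0.05),
    dep  = c(a = -1.00, mu = 0.08, sd = 0.09),
    rep  = c(a = 0.65, mu = 0.33, sd = 0.13),
    rec  = c(a = 0.12, mu = 1.20, sd = 0.60),
    # active backpropagation into the apical dendrite: an inward apical
    # current during the early recovery phase balanced by an outward
    # somatic current (a soma-apical dipole motif, present only in
    # apical-bearing archetypes)
    bap  = c(a = 1.2, mu = 0.35, sd = 0.45),
    bap_velocity = 400,  # active backpropagation speed, um/ms
    # phase windows relative to the spike, ms: [start, end)
    phases = list(I = c(-0.35, 0), II = c(0, 0.21),
                  III = c(0.21, 0.6), IV = c(0.6, 4.2)),
    ais_frac = 0.35,     # AIS current amplitude as a fraction of amp (per seg)
    tau_base = 0.08,     # dendritic low-pass time constant at the soma, ms
    tau_per_um = 3e-3    # added time constant per um of path distance
  )
}

# causal delayed exponential smoothing of a series (area preserving)
.delay_lowpass <- function(x, delay_samp, tau_samp) {
  n <- length(x)
  t <- seq_len(4 * ceiling(tau_samp) + 8) - 1
  k <- exp(-t / tau_samp)
  k <- k / sum(k)
  y <- stats::filter(c(x, numeric(length(k))), k, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)
  y[is.na(y)] <- 0
  y <- y[seq_len(n)]
  d <- round(delay_samp)
  if (d > 0) y <- c(numeric(d), y[seq_len(n - d)])
  y
}

#' Generate phase-structured transmembrane current templates
#'
#' Builds prescribed per-segment transmembrane currents phase-locked to a
#' somatic action potential. The AIS leads the soma; the somatic template is
#' a sum of capacitive, depolarization, repolarization and recovery phase
#' components; dendritic segments carry return currents — delayed and
#' low-pass filtered copies of the negated perisomatic current, distributed
#' in proportion to local membrane area, with delay and smoothing growing
#' with path distance from the soma. The somatic current is defined as the
#' negative sum of every other segment's current, so conservation (sum of
#' currents = 0 at every sample) holds exactly by construction.
#'
#' @param morph A `morphology`.
#' @param ap_params Phase parameters, see [default_ap_params()].
#' @return A `current_templates` object: list with `currents` (segments x
#'   time nA matrix, rows named by segment id), `somatic_vm` (mV),
#'   `spike_index` (1-based), `dt`, `n_samples`, `phases`.
#' @export
generate_current_templates <- function(morph, ap_params = default_ap_params()) {
  p <- ap_params
  n <- p$n_samples
  dt <- p$dt
  t_rel <- (seq_len(n) - p$spike_index) * dt       # ms relative to spike
  if (t_rel[1] > p$phases$I[1] || t_rel[n] < p$phases$IV[2]) {
    abort("n_samples too short to contain all action-potential phases",
          class = "eap_config_error")
  }
  # amplitude scaling with the total stem cross-sectional area
  stem_rows <- which(morph$segments$parent_id %in%
                       morph$segments$id[morph$segments$domain == "soma"])
  csa <- sum(pi * morph$segments$prox_radius[stem_rows]^2)
  amp_eff <- p$amp *
    if (length(stem_rows) > 0 && !is.null(p$csa_ref))
      (csa / p$csa_ref)^p$csa_exponent else 1
  g <- function(prm, lead = 0) {
    amp_eff * prm[["a"]] * exp(-(t_rel + lead - prm[["mu"]])^2 / (2 * prm[["sd"]]^2))
  }
  soma_template <- g(p$cap) + g(p$dep) + g(p$rep) + g(p$rec)

  s <- morph$segments
  n_seg <- nrow(s)
  currents <- matrix(0, n_seg, n, dimnames = list(s$id, NULL))
  soma_row <- which(s$domain == "soma")
  ais_rows <- which(s$domain == "ais")
  dend_rows <- which(s$domain %in% c("basal", "apical"))

  # AIS leads the soma with the same phase structure (scaled)
  for (i in ais_rows) {
    currents[i, ] <- p$ais_frac *
      (g(p$cap, lead = p$ais_lead) + g(p$dep, lead = p$ais_lead) +
         g(p$rep, lead = p$ais_lead))
  }
  total_active <- soma_template + colSums(currents[ais_rows, , drop = FALSE])

  # dendritic return currents: area-weighted, delayed, low-passed copies of
  # the negated perisomatic current
  currents[soma_row, ] <- soma_template
  if (length(dend_rows) > 0) {
    areas <- segment_areas(morph)[dend_rows]
    w <- areas / sum(areas)
    pd <- segment_path_distances(morph)[dend_rows]
    for (k in seq_along(dend_rows)) {
      delay <- pd[k] / p$velocity / dt
      tau <- (p$tau_base + p$tau_per_um * pd[k]) / dt
      currents[dend_rows[k], ] <-
        -w[k] * .delay_lowpass(total_active, delay, tau)
    }
  }
  # active backpropagating spike into the apical dendrite: an inward
  # current localized on the apical trunk (the regenerative hotspot at the
  # main bifurcation), delayed by trunk propagation and exactly balanced
  # by an outward somatic current — a soma-apical dipole present only in
  # apical-bearing archetypes. Being regenerative (all-or-none), its
  # amplitude does not carry the somatic CSA scaling.
  apical_rows <- which(s$domain == "apical")
  if (length(apical_rows) > 0 && p$bap[["a"]] != 0) {
    a_areas <- segment_areas(morph)[apical_rows]
    a_pd <- segment_path_distances(morph)[apical_rows]
    soma_ids <- s$id[s$domain == "soma"]
    is_trunk <- s$parent_id[apical_rows] %in% soma_ids
    # regenerative hotspot on the trunk (return through the soma) plus
    # invasion of the spatially extended tuft, whose return current flows
    # through the trunk membrane: a distal trunk-tuft dipole
    w_bap <- numeric(length(apical_rows))
    w_bap[is_trunk] <- 0.3 / sum(is_trunk)
    if (any(!is_trunk)) {
      w_bap[!is_trunk] <- 0.7 * a_areas[!is_trunk] / sum(a_areas[!is_trunk])
    } else {
      w_bap[is_trunk] <- 1 / sum(is_trunk)
    }
    trunk_idx <- apical_rows[is_trunk]
    v_bap <- if (!is.null(p$bap_velocity)) p$bap_velocity else p$velocity
    for (k in seq_along(apical_rows)) {
      mu_k <- p$bap[["mu"]] + a_pd[k] / v_bap
      i_bap <- (p$bap[["a"]] * p$amp * w_bap[k]) *
        exp(-(t_rel - mu_k)^2 / (2 * p$bap[["sd"]]^2))
      currents[apical_rows[k], ] <- currents[apical_rows[k], ] - i_bap
      if (is_trunk[k] || length(trunk_idx) == 0) {
        currents[soma_row, ] <- currents[soma_row, ] + i_bap
      } else {
        ret <- trunk_idx[1L + (k %% length(trunk_idx))]
        currents[ret, ] <- currents[ret, ] + i_bap
      }
    }
  }

  # exact conservation: the fast residual return (what the delayed smoothed
  # dendritic copies miss) exits through the large proximal basal
  # structures, area-weighted; soma as fallback when none exist
  resid <- colSums(currents)
  basal_rows <- which(morph$segments$domain == "basal")
  sink_rows <- if (length(basal_rows) > 0) basal_rows else
    if (length(dend_rows) > 0) dend_rows else soma_row
  sink_areas <- segment_areas(morph)[sink_rows]
  sink_w <- sink_areas / sum(sink_areas)
  for (k in seq_along(sink_rows)) {
    currents[sink_rows[k], ] <- currents[sink_rows[k], ] - sink_w[k] * resid
  }

  # somatic membrane potential with a unique global maximum at the spike
  vm <- -65 + 95 * exp(-t_rel^2 / (2 * 0.15^2)) -
    8 * exp(-(t_rel - 1.0)^2 / (2 * 0.8^2)) * (t_rel > 0)
  spike_index <- which.max(vm)

  out <- structure(
    list(currents = currents, somatic_vm = vm, spike_index = spike_index,
         dt = dt, n_samples = n, phases = p$phases,
         segment_ids = s$id),
    class = "current_templates"
  )
  resid <- max(abs(colSums(out$currents)))
  if (resid > 1e-9) {
    abort(sprintf("current conservation violated (max |sum| = %.3g nA)", resid),
          class = "eap_internal_error")
  }
  out
}

#' Per-domain current energy within an action-potential phase
#'
#' Integrates squared template currents over one phase window, summed over
#' the segments of one morphological domain. Used to verify the intended
#' phase structure (perisomatic currents dominate phases I-III, dendritic
#' return currents carry their energy into the recovery phase).
#'
#' @param templates A `current_templates`.
#' @param morph The morphology the templates were built from.
#' @param domain One of `"soma"`, `"ais"`, `"basal"`, `"apical"`.
#' @param phase One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return Scalar energy (nA^2 * ms).
#' @export
phase_energy <- function(templates, morph, domain, phase) {
  w <- templates$phases[[phase]]
  t_rel <- (seq_len(templates$n_samples) - templates$spike_index) * templates$dt
  in_win <- t_rel >= w[1] & t_rel < w[2]
  rows <- which(morph$segments$domain == domain)
  sum(templates$currents[rows, in_win, drop = FALSE]^2) * templates$dt
}
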