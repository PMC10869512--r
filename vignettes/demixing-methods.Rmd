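---
title: "Demixing extracellular action potential sources: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixing extracellular action potential sources: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eapdemix)
```

# The problem

A neuron firing an action potential drives transmembrane currents through
its soma, axon initial segment (AIS) and dendrites. A high-density linear
probe records the superposition of the potentials these currents generate —
the extracellular action potential (EAP) — on many channels at once. The
spatiotemporal EAP therefore mixes contributions from distinct
morphological domains, and the mixture depends on the unknown geometry
between cell and probe. `eapdemix` implements a demixing strategy for this
signal: multiresolution Haar features per channel, followed by a
non-negative canonical polyadic (CP) tensor decomposition across channels,
timescales and units, yielding a small set of *EAP sources*. Each recorded
unit is then described by its *prevalences* — its loadings on those
sources — which serve as features for neuron-type classification,
clustering and morphological correlation.

Because ground truth for real recordings does not exist, the package also
contains a forward simulator that generates labeled EAPs from simplified
multicompartment morphologies, so every stage of the pipeline is testable
end to end.

# The forward simulator

## Morphologies

`archetype_table()` defines 21 neuron-type family archetypes (11
excitatory, 10 inhibitory) as simplified labeled trees: a somatic segment,
a two-compartment AIS of equal length and diameter (25 um total), basal
stems that extend to a first branch point and then bifurcate, and — for
excitatory archetypes — an apical trunk with a tuft. Five seeded variants
per family differ only by geometric jitter (lengths within about 10%,
diameters within 5%, plus angular jitter); topology is fixed by the
archetype. The Y axis is the cortical-depth axis (+Y superficial), with the
soma at the origin.

Two geometric choices matter downstream. First, the apical trunk runs only
50–100 um to its first branch, with tuft branches extending roughly 2.2
trunk lengths beyond and spreading laterally; this places apical
first-branch and terminal densities in the channel range where the fitted
apical spatial source peaks (tens of micrometers above the soma). Second,
stem diameters set each model's total stem cross-sectional area (CSA),
which scales the current amplitude below — larger-caliber cells are
detectable farther away, as expected from the known CSA–amplitude
relationship.

## Currents

Membrane biophysics is not simulated. `generate_current_templates()`
prescribes kinematic per-segment currents phase-locked to a somatic action
potential whose membrane-potential peak defines the spike time. Four
Gaussian phase components shape the perisomatic current: a small capacitive
positivity before the spike, a dominant inward (depolarization) current
just after it, an outward repolarization current, and a slow recovery
component. The AIS leads the soma by 0.05 ms. Amplitude is 9 nA scaled by
`(total stem CSA / 50 um^2)^(1/3)`.

Dendritic segments carry *return currents*: delayed, low-pass-filtered
copies of the negated perisomatic current, distributed in proportion to
local membrane area, with delay (150 um/ms propagation) and smoothing (3
ns/nm of path) growing with path distance from the soma. The fast residual
— what the smoothed copies miss at early times — exits through the
proximal basal membrane. Apical-bearing archetypes additionally receive an
active backpropagation motif: an inward current on the trunk and tuft
(delayed at 400 um/ms, a regenerative event whose amplitude does not carry
the CSA scaling), returned through the soma and trunk respectively — a
distal dipole characteristic of excitatory cells. Conservation is exact by
construction: every inward component is paired with an outward counterpart,
and the residual redistribution preserves a zero column sum, asserted at
build time to 1e-9 nA.

The phase timings were set so the perisomatic EAP trough falls just after
the intracellular spike time, which is the premise of the canonical
waveform gate below; with these defaults roughly 5–8% of simulated units
are gated out as non-canonical.

## Extracellular potentials

`line_source_potential()` implements the quasi-static line-source
approximation in a homogeneous, isotropic medium (default conductivity 0.3
S/m): the potential of a uniform line current evaluated in closed form via
`asinh`, with the soma treated as a point source at its center and a 1 um
clamp on the source–electrode distance. `simulate_extracellular()` sums
kernel-weighted segment currents; linearity and superposition are exact.
The kernel converges to the point-source form `I/(4*pi*sigma*r)` as the
segment shrinks (verified against numeric quadrature in the tests).

## Detectability and probe sampling

`detectability_scan()` evaluates the EAP at 1,050 locations — 10 random
angles x 21 radii (10–110 um in 5 um steps) x 5 depth offsets — and
records the peak-to-trough amplitude at each. The detectability limit is
the mean over (angle, offset) rays of the largest radius whose amplitude
still reaches 20 uV; rays that never reach it are excluded from the mean.
An exponential fit `A(r) = A0 exp(-r/lambda)` flags a model undetectable
when the extrapolated amplitude at 1 um is below threshold. Across the
archetype library the limits average near 57 um (SD ~11 um, range 31–79
um; excitatory models reach farther because the slowly-decaying apical
dipole keeps distal amplitudes up), with perisomatic decay constants of
22–33 um, in the range reported for cortical recordings.
`sample_probes()` then draws placements with radius uniform between 10 um
and the limit, uniform angle, and a +/-5 um depth jitter of the
64-channel, 10 um-pitch probe.

# Preprocessing and gating

Each channel is cut to a 128-sample, 5.6 ms snippet with a 1.4 ms
pre-spike interval (the spike lands on sample 33); independent Gaussian
1/f noise — 200 draws averaged, then rescaled to exactly 10 uV RMS — is
added per channel, and the channel median is subtracted. The 10 uV level
is a configurable stand-in for measured probe noise; note that because the
averaged noise is rescaled, the draw count does not change its law, only
compute time (the desk-scale configurations use 50 draws).

The center channel is the largest strict local maximum of the amplitude
profile above 60% of the probe maximum; with several candidates, the two
largest are checked for inversion (potential at the spike time above the
waveform median) and the surviving larger one wins. Units whose center
cannot be cropped to 31 channels (center +/- 15) are dropped. The center
waveform is then gated for canonical shape with tolerances at the waveform
mean +/- SD: a positive pre-spike deflection, a too-early global minimum,
or a missing post-spike trough each reject the unit, in that order.
`balance_dataset()` finally samples an equal quota of canonical units per
family into the S x T x N tensor `X` (31 x 128 x 8,400 at full scale).

# Features and the demix model

Before feature extraction each unit's waveform matrix is divided by its
maximum peak-to-trough amplitude (`normalize_units()`, on by default).
Prevalences then describe what a unit's EAP is *made of* rather than how
large it is: with this convention the noise and dendritic source loadings
grow with recording distance while the perisomatic loading falls — the
behavior expected from the physiology — whereas absolute loadings would
all simply decay with distance and every downstream comparison would be
dominated by amplitude.

`haar_features()` applies a full-depth (7 detail levels + approximation)
orthonormal Haar transform per channel and takes absolute values, making
the representation invariant to waveform inversion — EAPs generated by
opposite poles of a current dipole map to the same features. Coefficients
are ordered coarse to fine; Parseval holds exactly on the pre-absolute
path, and `reconstruct_temporal_source()` inverts a fitted temporal source
back to a time-domain contribution magnitude.

`ncp_bcd()` fits the non-negative CP model
`F[s,w,n] ~ sum_r spatial[s,r] * temporal[w,r] * prevalence[n,r]` by block
coordinate descent with HALS column updates, random non-negative
initialization scaled to the tensor norm, a monotone-objective assertion
each iteration, and stopping when the relative-error change drops below
1e-6 (at most 500 iterations). Spatial and temporal columns are normalized
to unit length with the scale pushed into the prevalences.

Rank selection follows the restart-similarity rule: for each candidate
rank, four independently seeded fits; the lowest-error fit is the
reference; `decomposition_similarity()` scores the rest against it (cosine
products across modes under a Hungarian matching — permutation- and
scale-invariant, and verified against exhaustive matching for small
ranks). Ranks with mean similarity above 0.99 are candidates; candidates
are compared by random-forest accuracy of their prevalences against the
family labels, and the largest candidate with maximal accuracy wins. On
planted four-source benchmark tensors (`simulate_benchmark_tensor()`) the
similarity collapses sharply beyond the true rank and rank 4 is recovered.
Components are finally re-ordered by Gini importance for family
classification (`order_sources()`).

# Downstream analyses

* **Classification** (`rf_classify()`): stratified 20% holdout, grid
  search over tree depth {4, 8, 16, unlimited} and forest size {100, 300,
  500} by out-of-bag score, five-fold cross-validation of the selected
  parameters, Gini importances normalized to sum one. The baseline
  comparison uses `baseline_features()` — trough/peak timing features,
  half-width, slopes 30 us after trough and peak (sub-sample linear
  interpolation), amplitude spread above 12% of maximum, and trough-lag
  propagation velocities with a dt/2 guard against infinite slopes — with
  `max_features = 4` to match the four-source model's feature budget.
* **Morphometrics** (`compute_morphometrics()`): stems are segments whose
  parent is the soma; CSA is `pi*(d/2)^2` at the proximal end; stems
  divide into upper/lower by attachment relative to the soma Y-midpoint
  (ties attach upper); an unbranched stem's first branch is its terminal.
  `domain_density_profile()` pools first-branch, terminal, or
  maximal-extent locations into unit-area histograms along Y for
  comparison with the spatial sources. A minimal NeuroML v2 reader/writer
  round-trips these morphologies.
* **Bootstrapped CCA** (`bootstrap_cca()`): per iteration one variant per
  family is drawn; the morphometric matrix and a families x 50 matrix of
  resampled prevalences are standardized (population variance) and a
  single-component CCA — regularized whitening plus SVD, cross-checked
  against `cancor` on full-rank inputs — links them; correlations between
  each morphometric and the canonical covariate are accumulated over
  1,000 iterations. With 50 prevalence columns and ~21 family rows the
  canonical correlation itself saturates; the morphometric–covariate
  correlations and their permutation null remain informative, and the
  planted-relation and null controls in the tests exercise exactly those.
* **Distance scaling** (`distance_scaling()`): per family and source,
  prevalence changes relative to the nearest-probe unit are regressed on
  distance, with 10 um binned means and coefficients of variation.
* **EI benchmark** (`clustering_benchmark()`): k-means, Ward and
  average-linkage agglomeration, and a Gaussian mixture, each at k = 2 on
  the raw prevalence features, scored by the better of the two label
  permutations.
* **Hierarchy** (`bootstrap_centroids()`, `build_hierarchy()`,
  `exclusion_analysis()`): family centroids are coordinate-wise medians
  over 1,000 draws of 80% resamples; centroid distances are normalized to
  unit maximum and agglomerated with average linkage; the cut threshold is
  configurable, defaulting to the largest value yielding the requested
  class count (six at full scale). The leave-one-out analysis drops one
  morpho-electrophysiological (ME) class, refits the decomposition at the
  same rank and compares it to the original on the two shared modes
  (spatial, temporal), since the unit axes differ between fits.

# Problem sizes and what the synthetic tests do (and do not) show

The full-scale configuration (21 families x 5 variants x 100 probes,
quota 400) is what `default_config()` describes. The packaged analyses and
benchmarks run at desk scale: the EI benchmark configuration
(`ei_benchmark_config()`) uses 8 families x 2 variants x 30 probes with a
40-unit quota (N = 320), and the rank-selection benchmark uses planted
31 x 128 x 150 tensors. These sizes were chosen so a complete run takes
about a minute on one core while leaving every pipeline stage exercised.

At these conditions the pipeline reproduces the qualitative structure the
method is built around: a pervasive noise source whose prevalence grows
with distance, a perisomatic source peaked at the center channel, and an
apical source peaked above the center that separates excitatory from
inhibitory units (supervised random forests reach 96–99% EI accuracy and
the Gaussian mixture 95–99%). Two honest limitations at desk scale: the
family-level classification sits well below the full-scale figure (fewer
units, fewer variants), and the centroid-based clusterers (k-means, Ward,
average linkage) often fail to recover the EI split from the raw 4-D
prevalences even though a one-dimensional threshold on the apical source
alone separates ~95% of units — their Euclidean geometry is dominated by
the distance-dependent spread of the noise-source loading. The Gaussian
mixture, which models per-cluster covariance, is robust to this. Scaling
the simulation up narrows but does not remove that gap in our experiments.

The simulator emulates domain-structured currents, amplitude decay,
probe-placement variability and 1/f background noise. It does not emulate
conductance-based membrane dynamics, spike collisions, drift, spatially
correlated noise, or frequency-dependent media — so passing tests validate
the demixing machinery and its protocol constants, not the biological
fidelity of any particular source waveform.

# Numerical choices

Haar transforms are orthonormal so energy bookkeeping is exact; the CP
objective is tracked in squared form with a roundoff-aware monotonicity
assertion (catastrophic cancellation sets in once the fit is near exact);
HALS skips columns whose Gram diagonal underflows; zero tensors
short-circuit to zero factors with error 0; the line-source kernel clamps
distances at 1 um; plateaus in the amplitude profile break toward the
lower channel index; exact amplitude ties in center selection break toward
the probe's geometric center; stems attached exactly at the soma midpoint
count as upper. All randomness flows through explicit integer seeds, and
pipeline stages derive child seeds from the base seed so any stage can be
rerun in isolation. Tensors and tables are persisted as CSV/JSON
artifact directories (`write_pipeline_artifacts()`).
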