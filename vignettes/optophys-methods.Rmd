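---
title: "Methods: analysis of optogenetically evoked synaptic currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of optogenetically evoked synaptic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optophys)
```

`optophys` implements the analysis chain used to characterize GABAergic and
glutamatergic synapses probed by millisecond optogenetic stimulation in
acute slices: detection of postsynaptic currents (PSCs) in voltage clamp,
a permutation test for stimulus-locked responsiveness, failure-weighted
amplitude and kinetic metrics, per-pulse charge analysis of short-term
plasticity, passive-membrane and spike-train characterization, reversal-
potential analysis with chloride Nernst predictions, and field-potential
(fEPSP / population-spike) analysis. Because studies of this kind rarely
deposit raw sweep data, the package ships ground-truth-annotated simulators
of every recording configuration, and its entire validation strategy is
parameter recovery: simulate at known parameters, analyze, compare.

## Event detection

Events are found as peaks in the low-pass filtered current (< 250 Hz)
whose magnitude exceeds 4 standard deviations of the noise, where the
noise SD is measured on the > 500 Hz high-pass residual of the same sweep.
Both filters are 4th-order Butterworth applied forward-backward (zero
phase), so evoked latencies are not phase-shifted; the cutoffs are the
only externally imposed values. Per-sweep noise estimation keeps the
threshold robust to slow drift between sweeps. Because
`signal::filtfilt()` applies no edge padding, the package extends each
trace by odd reflection before filtering, which preserves the DC level to
within 0.1%.

The onset of an event is the time at which 10% of its maximum amplitude is
reached in the *unfiltered* signal (linear interpolation between samples).
Amplitude is measured on the unfiltered trace relative to a local baseline
(median of the 5 ms preceding the onset). Onset and baseline are mutually
dependent, so they are solved by a two-pass fixed-point iteration starting
from the pre-peak minimum; if an event sits at the very start of a trace,
with less than 2.5 ms of pre-onset data, the minimum-based provisional
baseline is kept. Peaks closer than a 2 ms refractory separation are
merged (the larger wins), which prevents double-counting of filter
ringing; plateau ties resolve to the earliest sample.

At signal-to-noise ratio (SNR, peak amplitude over broadband noise SD) 10
and above, recovery on simulated sweeps is essentially perfect:
sensitivity at or above 95% for isolated events, false positives well
below 1 event/s on pure noise (the 4-SD broadband threshold corresponds to
roughly 25 SD of the 250 Hz-band noise, so chance crossings are rare), and
amplitude bias within ±5%.

## Responsiveness: circular-shift permutation test

A cell is called responsive when events accumulate within a 12 ms window
after the stimulus beyond chance. The observed statistic is the total
in-window event count over all sweeps (window half-open:
`(stimulus, stimulus + 12]`, membership by onset). The null is built with a
2000-step shuffling procedure: per shuffle, each sweep's event train is
circularly shifted by an independent uniform offset with wraparound at the
sweep edge. Circular shifts preserve within-sweep event counts and
inter-event structure, making this the conservative choice among shuffle
schemes; alternatives (permuting inter-event intervals or stimulus times)
would destroy burst structure and can anticonservatively narrow the null.
The p-value uses the add-one estimator `(1 + #{null >= obs}) / (1 + N)`,
so it is never zero, and responsiveness requires strictly `p < 0.05`.

Two properties matter in practice:

* The test is exact but *discrete*. With sparse events and few stimulus
  windows the achievable p-values are coarse and the achieved type-I error
  falls well below the nominal 0.05. Calibration is therefore checked
  under conditions where the count statistic is fine-grained: 1000 null
  cells with 20 two-second sweeps, 5 Hz Poisson spontaneous events, and 5
  stimulus presentations per sweep (expected in-window count ≈ 6). Under
  these conditions the empirical responsive fraction lies in [0.03, 0.07];
  under sparser conditions the test stays valid but conservative.
* For a responsive cell, the earliest in-window event after each pulse is
  labeled evoked; any later in-window events count as spontaneous, so the
  per-trial success flags are well defined and the success probability is
  at most 1 per pulse.

## PSC metrics

Reported peak amplitude is the product of the mean amplitude over success
trials and the success probability (the fraction of trials with an evoked
response); this failure-weighted amplitude is an algebraic identity in the
code, not an approximation. Kinetics are measured on the average of
success trials: rise time from 20% to 80% (EPSC) or 20% to 70% (IPSC) of
peak, decay time from 80% (EPSC) or 70% (IPSC) down to 30%, half-width as
the duration above 50%. Threshold times interpolate linearly between
samples, so on noiseless closed-form kernels the estimates match analytic
values (rise `tau*ln 4` for a saturating exponential; decay `tau*ln(8/3)`
for an EPSC-convention exponential) to within a sample period.

The coefficient of variation of success amplitudes uses the population SD
(n denominator), treating the recorded trials as the set being described.

For train stimulation (typically 5 pulses at 20 Hz), the charge of each
pulse is the baseline-subtracted integral over a window equal to the
inter-pulse interval starting at that pulse; the last pulse uses the same
window length. The baseline is pre-train, not per-pulse, so summation and
depression within the train are integrated as recorded. Ratios are
normalized to the first pulse for inhibitory inputs onto granule cells
(depressing synapses) and to the last pulse for granule-cell outputs onto
interneurons (strongly facilitating synapses, where the first-pulse charge
is often near zero and would be an unstable reference). A variant for
high-frequency (50 Hz) trains in which responses fuse integrates the whole
response over 340 ms and divides by the peak amplitude.

The number of functional synaptic contacts is estimated as the ratio of
the saturating IPSC amplitude to the unitary IPSC amplitude, the latter
measured under minimal stimulation with failures in at least 10% of
trials.

## Intrinsic properties

Input resistance and capacitance come from the current response to a
hyperpolarizing voltage step (10 mV, 100 ms): `R = step / dI_ss`, and
`C = |Q_transient| / |step|` from the integrated transient charge, a
less model-dependent estimator than an exponential fit (a tau-fit estimate
is also reported; `tau = R*C` to within 10% on clean data).

Spike threshold is the point at which dVm/dt reaches 5 mV/ms. The
derivative criterion alone is fragile: with 1 mV of voltage noise the
smoothed-derivative SD is already several mV/ms, and sharp waveform
corners make zero-phase filters ring. Detection is therefore peak-first:
candidate local maxima of the 1 kHz-smoothed voltage are accepted as
spikes only if a suprathreshold derivative precedes them within 3 ms and
the voltage rises at least 15 mV (`min_rise_mv`) from the threshold point
to the peak. The threshold time is then refined against the raw
derivative, which makes the threshold voltage exact on clean data. AP
amplitude runs from threshold to positive peak, AHP from threshold to the
repolarization minimum, ISIs peak to peak, instantaneous frequency is
1000/ISI, and the adaptation ratio is ISI3/ISIlast (defined for at least 4
spikes; the "last" spike is the last within the stimulus step). Rheobase
is the smallest step current evoking at least one spike in an increasing
ladder (10 pA steps for granule cells, 50 pA for interneurons), and the
full profile is evaluated on the step closest to three times rheobase.

## Reversal potentials and synapse localization

I-V curves are ordinary least-squares lines through (holding potential,
peak current); the reversal potential is `-intercept/slope` and the slope
is the synaptic conductance in nS. A fit is flagged undefined when the
slope is indistinguishable from zero and flagged extrapolated when the
reversal lies more than 20 mV outside the sampled holdings.

The chloride Nernst potential is `-(RT/F) ln([Cl]o/[Cl]i)` at the
recording temperature (default 23 °C, room temperature). Chloride totals
come from a stoichiometry table (NaCl, KCl, choline-Cl contribute 1 per
mM; CaCl2, MgCl2 contribute 2; gluconate, phosphate, bicarbonate and the
common organic components contribute none); unknown salts are an error
rather than a silent zero. With a high-chloride internal
(110 K-gluconate / 5 NaCl / 30 KCl / 4 MgCl2, 43 mM Cl) against standard
ACSF (134.1 mM Cl) the predicted reversal is −29 mV — the somatic E_GABA
imposed by the pipette — while a low-chloride K-gluconate internal (9 mM
Cl) predicts −69 mV, the holding potential at which IPSCs reverse and
EPSCs can be recorded in isolation.

Because pipette chloride clamps the soma but not distal dendrites,
proximal and distal GABAergic inputs reverse at different potentials and
produce biphasic currents at intermediate holdings. `separate_components()`
measures per-window peaks (early window 0–10 ms for the fast proximal
component, late window 20–100 ms for the delayed distal one; configurable)
on per-holding average sweeps, fits one I-V per window, and then measures
each component at the holding closest to the other component's fitted
reversal, where the alternate component is silent. Recovery degrades as
the two components' kinetics overlap: the early window then contains
distal current and vice versa, pulling both fitted reversals toward each
other — the windows, not the fit, are the accuracy bottleneck.

## Field potentials

The fEPSP slope is the steepest 20–80% linear fit of the initial rising
phase, measured on the dip-free upper envelope so the pop-spike does not
bias it. The pop-spike area uses the tangent-skim method: the deflection
extremum is located against a two-sided running-max envelope, the flanking
shoulders are the nearest local maxima (found with a 0.5 ms lookahead so
noise wiggles do not stop the walk early), and the area between the chord
joining the shoulders and the raw trace is integrated. The metric is
polarity-agnostic and reported as a magnitude. Deflections below 4 noise
SDs are reported as area 0 with a flag. The chord under-skims a strongly
curved envelope when the deflection is broad; for pop-spike-like widths
(about 2 ms, the generator's default Gaussian SD of 0.4 ms) the bias is
below 1%.

The laser-induced change of field responses is
`100 * (mean_off − mean_on) / mean_off`, applied to the pop-spike area
over alternating laser-off / laser-on trials (at least 5 per condition),
and is scale-invariant by construction. The delay curve evaluates this
percentage over a grid of laser-to-stimulus delays (negative: laser
first). Spike timing relative to the pop-spike peak classifies interneuron
spikes as `before` (direct cortical, feedforward drive) or `after`
(recruited by the granule-cell population discharge, feedback); when the
pop-spike is abolished the delays are undefined while the cell's direct
spikes persist.

## The simulators: what they emulate, and what they do not

Every generator draws all randomness from one seed and restores the
caller's RNG state, so identical calls are bit-identical.

* `simulate_sweepset()` — evoked PSCs as difference-of-exponentials
  kernels, per-pulse Bernoulli transmission failures, zero-truncated
  Gaussian latency (default mean 2 ms, SD 0.3 ms), per-pulse
  multiplicative amplitude factors (`train_scale`) emulating short-term
  depression or facilitation, homogeneous Poisson spontaneous events, and
  white Gaussian noise. `train_scale` acts on amplitude, not on release
  probability: this directly yields programmed charge ratios and lets
  facilitation convert subthreshold responses into detectable ones, the
  phenomenon by which train stimulation reveals connections silent under
  single pulses. Event superposition is linear.
* `simulate_iv_family()` — peak current `g(V − E_rev)` per holding, one or
  several components with their own kinetics and latencies (biphasic
  sweeps at intermediate holdings).
* `simulate_step_response()` — single-exponential relaxation with
  `tau = R*C` toward `step/R`.
* `simulate_spike_train()` — stereotyped APs at programmed ISIs: a
  sub-criterion approach ramp (3 mV/ms), fast upstroke from the programmed
  threshold, downstroke to the AHP, and a trough that rises automatically
  when short ISIs leave too little time for a sub-criterion approach.
* `simulate_field_sweep()` — a positive-going fEPSP (linear rise, then
  exponential decay) with a negative Gaussian pop-spike of programmed
  area, scaled by `1 − suppression` on laser trials; plus a logistic
  recruitment curve mapping stimulus intensity to pop-spike area, used to
  pick intensities in the 30–55% band of maximum.

These simulators deliberately omit: driving-force nonlinearity within a
sweep (except across holdings in the I-V family), overlapping-event
interactions beyond linear summation, series-resistance and space-clamp
errors, slow baseline drift, non-Poisson burstiness of spontaneous events,
and conductance-based spike generation. The per-sweep noise estimate and
local baselines keep the analysis itself robust to drift even though the
generator does not produce it.
Passing the recovery suite therefore shows the *estimators* are correct
and well calibrated under realistic noise — not that real recordings obey
these simplifications; on real data the unmodeled effects (space clamp
above all) bias amplitudes and reversals in ways no analysis-side fix can
remove.

## Numerical and design choices

* Canonical units everywhere: pA, mV, ms, Hz; conversion only at I/O.
  The CSV sweep container stores data plus protocol/metadata sidecars;
  missing required metadata is a format error naming the field.
* QC thresholds are hard-coded per cell class (granule cell: |leak| <
  100 pA, Rs ≤ 25 MΩ; interneuron: |leak| < 250 pA, Rs ≤ 15 MΩ) with an
  override argument.
* Threshold crossings interpolate linearly between samples; plateau ties
  resolve to the earliest sample; degenerate inputs (zero slope I-V, sub-
  noise PSC, spikeless ladder, zero reference charge) return flagged or
  `NA` results rather than errors where the quantity's definition allows.
* Problem sizes in the validation suite: 100-seed detector recovery,
  1000-cell shuffle calibration, 400-trial success recovery, 20-seed
  recovery runs for train ratios and reversals. These sizes give binomial
  or Monte-Carlo error comfortably inside each tolerance while keeping
  the suite quick to run.
* `run_pipeline()` chains simulate → detect → classify → metrics from one
  nested-list config (YAML-compatible); `validate_config()` returns
  violations naming the offending field; reports echo every parameter for
  provenance. The package is an R library: the exported functions are the
  interface, and the config-driven pipeline is the batch entry point.

## Known limitations

* The evoked/spontaneous split attributes at most one event per stimulus;
  genuine polysynaptic multi-event responses inside the window are counted
  as spontaneous beyond the first.
* Component separation assumes the early window is proximal-dominated and
  the late window distal-dominated; inputs with similar kinetics cannot be
  separated by windows at any holding.
* The tangent-skim area is biased low for deflections wide relative to the
  envelope curvature.
* The permutation test's conservatism under sparse-event conditions means
  "not responsive" calls at low spontaneous rates are safe, but power is
  limited when evoked responses are rare and small.
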