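# Ground-truth-annotated simulators of the recording configurations the
# analysis consumes: voltage-clamp PSC sweeps with transmission failures and
# spontaneous events, I-V families around a configurable reversal potential,
# hyperpolarizing-step responses, current-clamp spike trains, and field
# sweeps with an fEPSP and a population spike.
#
# All randomness in a call flows from one seed; the caller's RNG state is
# restored on exit.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Postsynaptic-current waveform shape
#'
#' Difference-of-exponentials kernel parameters. `amplitude` is the peak
#' magnitude in pA; `polarity` is -1 for inward currents (e.g. EPSCs at
#' negative holding, or IPSCs recorded with a high-chloride internal at
#' -70 mV) and +1 for outward currents.
#'
#' @param amplitude Peak magnitude in pA (> 0).
#' @param tau_rise Rise time constant in ms; must be < `tau_decay`.
#' @param tau_decay Decay time constant in ms.
#' @param polarity -1 (inward) or +1 (outward).
#' @return An object of class `"psc_shape"`.
#' @export
psc_shape <- function(amplitude, tau_rise, tau_decay, polarity = -1) {
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop("'amplitude' must be > 0 (magnitude in pA)", call. = FALSE)
  if (tau_rise <= 0 || tau_rise >= tau_decay)
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  if (!polarity %in% c(-1, 1))
    stop("'polarity' must be -1 or +1", call. = FALSE)
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, polarity = polarity),
            class = "psc_shape")
}

# unit-peak biexponential kernel sampled at `rate` over `duration` ms
.psc_kernel <- function(tau_rise, tau_decay, duration, rate) {
  tt <- seq(0, duration, by = 1000 / rate)
  k <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  # analytic peak of e^{-t/td} - e^{-t/tr}
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  k / pk
}

#' Sample a PSC waveform
#'
#' Difference-of-exponentials kernel normalized so its peak equals
#' `shape$amplitude` with the sign of `shape$polarity`; the value at t = 0
#' is 0. The total charge of the unnormalized kernel
#' \eqn{e^{-t/\tau_d} - e^{-t/\tau_r}} over \eqn{[0, \infty)} is
#' \eqn{\tau_d - \tau_r} per unit amplitude.
#'
#' @param shape A [psc_shape()].
#' @param duration Duration in ms; at least `5 * tau_decay` is recommended so
#'   the kernel decays to a negligible tail.
#' @param rate Sampling rate in Hz.
#' @return A [trace()] of kind `"voltage_clamped_current"`.
#' @export
psc_waveform <- function(shape, duration = NULL, rate = 20000) {
  stopifnot(inherits(shape, "psc_shape"))
  if (is.null(duration)) duration <- 8 * shape$tau_decay
  k <- .psc_kernel(shape$tau_rise, shape$tau_decay, duration, rate)
  trace(shape$polarity * shape$amplitude * k, rate,
        "voltage_clamped_current")
}

#' Synapse model for sweep simulation
#'
#' Describes one synaptic connection as seen in voltage clamp: the PSC
#' waveform, the per-trial transmission failure probability, evoked-onset
#' latency (Gaussian, truncated at zero), per-pulse multiplicative amplitude
#' factors emulating short-term depression or facilitation, a Poisson rate of
#' spontaneous events, and white Gaussian recording noise.
#'
#' @param shape A [psc_shape()].
#' @param failure_prob Per-pulse transmission failure probability in `[0, 1]`.
#' @param latency_mean Mean evoked latency in ms after the stimulus onset.
#' @param latency_jitter_sd Latency SD in ms.
#' @param train_scale Per-pulse amplitude factors (all > 0); length must match
#'   the number of pulses in the protocol used for simulation. `NULL` means
#'   no train plasticity.
#' @param spont_rate Spontaneous event rate in events/s (>= 0).
#' @param noise_sd Broadband recording noise SD in pA.
#' @return An object of class `"synapse_model"`.
#' @export
synapse_model <- function(shape, failure_prob = 0, latency_mean = 2,
                          latency_jitter_sd = 0.3, train_scale = NULL,
                          spont_rate = 0, noise_sd = 2) {
  stopifnot(inherits(shape, "psc_shape"))
  if (failure_prob < 0 || failure_prob > 1)
    stop("'failure_prob' must be in [0, 1]", call. = FALSE)
  if (!is.null(train_scale) && any(train_scale <= 0))
    stop("'train_scale' factors must all be > 0", call. = FALSE)
  if (spont_rate < 0) stop("'spont_rate' must be >= 0", call. = FALSE)
  structure(list(shape = shape, failure_prob = failure_prob,
                 latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd,
                 train_scale = train_scale, spont_rate = spont_rate,
                 noise_sd = noise_sd),
            class = "synapse_model")
}

# add a scaled unit kernel into `samples` starting at time `onset` (ms)
.add_kernel <- function(samples, rate, onset, kernel, scale) {
  i0 <- round(onset * rate / 1000) + 1L
  n <- length(samples)
  if (i0 > n) return(samples)
  len <- min(length(kernel), n - i0 + 1L)
  idx <- i0:(i0 + len - 1L)
  samples[idx] <- samples[idx] + scale * kernel[seq_len(len)]
  samples
}

#' Simulate a stimulus-aligned sweep set with ground truth
#'
#' For each sweep and each stimulus pulse, an evoked PSC occurs with
#' probability `1 - failure_prob`, at a latency drawn from a zero-truncated
#' Gaussian, with amplitude scaled by the pulse's `train_scale` factor.
#' Spontaneous PSCs arrive as a homogeneous Poisson process over the whole
#' sweep. Events superpose linearly and white Gaussian noise is added.
#'
#' @param model A [synapse_model()].
#' @param protocol A [stimulus_protocol()].
#' @param n_sweeps Number of sweeps (>= 1).
#' @param seed Integer seed; the same seed reproduces the output bit for bit.
#' @param duration_ms Sweep duration; default covers the last pulse plus
#'   300 ms.
#' @param rate Sampling rate in Hz.
#' @param holding_potential Holding potential recorded in the metadata (mV).
#' @return A list with components `sweeps` (a [sweep_set()]) and `truth`, the
#'   ground truth: `events` (data.frame: sweep, onset_ms, amplitude_pa,
#'   label), and `successes` (n_sweeps x n_pulses logical matrix).
#' @export
simulate_sweepset <- function(model, protocol, n_sweeps, seed = NULL,
                              duration_ms = NULL, rate = 20000,
                              holding_potential = -70) {
  stopifnot(inherits(model, "synapse_model"),
            inherits(protocol, "stimulus_protocol"))
  if (n_sweeps < 1) stop("'n_sweeps' must be >= 1", call. = FALSE)
  n_pulses <- length(protocol$onsets)
  scl <- model$train_scale %||% rep(1, n_pulses)
  if (length(scl) != n_pulses)
    stop("train_scale length must match the number of pulses", call. = FALSE)
  if (is.null(duration_ms)) duration_ms <- max(protocol$onsets) + 300
  .with_seed(seed, {
    n <- round(duration_ms * rate / 1000)
    kernel <- .psc_kernel(model$shape$tau_rise, model$shape$tau_decay,
                          8 * model$shape$tau_decay, rate)
    pol <- model$shape$polarity
    successes <- matrix(FALSE, n_sweeps, n_pulses)
    ev <- vector("list", n_sweeps)
    sweeps <- vector("list", n_sweeps)
    for (s in seq_len(n_sweeps)) {
      x <- numeric(n)
      onsets <- numeric(0); amps <- numeric(0); labels <- character(0)
      succ <- stats::runif(n_pulses) >= model$failure_prob
      successes[s, ] <- succ
      for (j in which(succ)) {
        lat <- -1
        while (lat < 0)
          lat <- stats::rnorm(1, model$latency_mean, model$latency_jitter_sd)
        a <- model$shape$amplitude * scl[j]
        t_on <- protocol$onsets[j] + lat
        x <- .add_kernel(x, rate, t_on, kernel, pol * a)
        onsets <- c(onsets, t_on); amps <- c(amps, a)
        labels <- c(labels, "evoked")
      }
      n_spont <- stats::rpois(1, model$spont_rate * duration_ms / 1000)
      if (n_spont > 0) {
        t_sp <- sort(stats::runif(n_spont, 0, duration_ms))
        for (t_on in t_sp)
          x <- .add_kernel(x, rate, t_on, kernel,
                           pol * model$shape$amplitude)
        onsets <- c(onsets, t_sp)
        amps <- c(amps, rep(model$shape$amplitude, n_spont))
        labels <- c(labels, rep("spontaneous", n_spont))
      }
      if (model$noise_sd > 0)
        x <- x + stats::rnorm(n, 0, model$noise_sd)
      sweeps[[s]] <- trace(x, rate, "voltage_clamped_current")
      ev[[s]] <- if (length(onsets))
        data.frame(sweep = s, onset_ms = onsets, amplitude_pa = amps,
                   label = labels)
      else
        data.frame(sweep = integer(0), onset_ms = numeric(0),
                   amplitude_pa = numeric(0), label = character(0))
    }
    list(
      sweeps = sweep_set(sweeps, protocol,
                         holding_potential = holding_potential),
      truth = list(events = do.call(rbind, ev), successes = successes)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an I-V family of evoked currents
#'
#' At each holding potential V the evoked peak current is
#' `g_syn * (V - e_rev)` pA (conductance in nS, driving force in mV), with a
#' biexponential time course and additive noise; the sign flips across the
#' reversal potential. A multi-component synapse (e.g. a fast proximal input
#' reversing near the somatic chloride potential and a slow, delayed distal
#' input reversing more negative) can be given via `components`, producing
#' biphasic sweeps at intermediate holdings.
#'
#' @param g_syn Synaptic conductance in nS (single-component form).
#' @param e_rev Reversal potential in mV (single-component form).
#' @param holdings Holding potentials in mV; at least 3.
#' @param shape A [psc_shape()]; its `amplitude`/`polarity` are overridden by
#'   the driving force.
#' @param noise_sd Noise SD in pA.
#' @param n_sweeps Sweeps per holding.
#' @param seed Integer seed.
#' @param components Optional list of components, each a list with `g_syn`,
#'   `e_rev`, `shape`, and `latency_ms`; overrides `g_syn`/`e_rev`/`shape`.
#' @param stim_onset_ms Stimulus time within the sweep.
#' @param duration_ms Sweep duration.
#' @param rate Sampling rate (Hz).
#' @return An object of class `"iv_family"`: a list with `holdings` and
#'   `sweepsets` (one [sweep_set()] per holding), plus the generating
#'   parameters.
#' @export
simulate_iv_family <- function(g_syn = NULL, e_rev = NULL, holdings,
                               shape = psc_shape(1, 1, 10), noise_sd = 2,
                               n_sweeps = 10, seed = NULL, components = NULL,
                               stim_onset_ms = 20, duration_ms = 220,
                               rate = 20000) {
  if (length(holdings) < 3)
    stop("need at least 3 holding potentials", call. = FALSE)
  if (is.null(components)) {
    if (is.null(g_syn) || is.null(e_rev))
      stop("give either g_syn + e_rev or 'components'", call. = FALSE)
    components <- list(list(g_syn = g_syn, e_rev = e_rev, shape = shape,
                            latency_ms = 0))
  }
  protocol <- stimulus_protocol(stim_onset_ms, width = 0.2,
                                modality = "laser")
  .with_seed(seed, {
    n <- round(duration_ms * rate / 1000)
    kernels <- lapply(components, function(cp)
      .psc_kernel(cp$shape$tau_rise, cp$shape$tau_decay,
                  8 * cp$shape$tau_decay, rate))
    sets <- lapply(holdings, function(V) {
      sweeps <- lapply(seq_len(n_sweeps), function(s) {
        x <- numeric(n)
        for (ci in seq_along(components)) {
          cp <- components[[ci]]
          peak <- cp$g_syn * (V - cp$e_rev)   # nS * mV = pA, signed
          x <- .add_kernel(x, rate,
                           stim_onset_ms + (cp$latency_ms %||% 0),
                           kernels[[ci]], peak)
        }
        if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
        trace(x, rate, "voltage_clamped_current")
      })
      sweep_set(sweeps, protocol, holding_potential = V)
    })
    structure(list(holdings = as.numeric(holdings), sweepsets = sets,
                   components = components, stim_onset_ms = stim_onset_ms),
              class = "iv_family")
  })
}

#' Simulate the current response to a hyperpolarizing voltage step
#'
#' Single-exponential relaxation with time constant `tau = r_in * c_m`
#' toward the steady-state current `step / r_in`, as used for passive
#' membrane characterization (a 10 mV, 100 ms step by default).
#'
#' @param r_in Input resistance in MOhm (> 0).
#' @param c_m Membrane capacitance in pF (> 0).
#' @param step Step amplitude in mV (default -10).
#' @param duration Step duration in ms.
#' @param seed Integer seed for the additive noise.
#' @param noise_sd Noise SD in pA.
#' @param pre_ms Baseline before the step; the step onset is at `pre_ms`.
#' @param post_ms Recording time after step release.
#' @param rate Sampling rate in Hz.
#' @return A [trace()] with attribute `step_onset_ms`.
#' @export
simulate_step_response <- function(r_in, c_m, step = -10, duration = 100,
                                   seed = NULL, noise_sd = 0, pre_ms = 20,
                                   post_ms = 50, rate = 20000) {
  if (r_in <= 0 || c_m <= 0) stop("r_in and c_m must be > 0", call. = FALSE)
  tau <- r_in * c_m / 1000           # MOhm * pF = us -> ms
  dI <- step / r_in * 1000           # mV / MOhm = nA -> pA
  .with_seed(seed, {
    tt <- seq(0, pre_ms + duration + post_ms, by = 1000 / rate)
    x <- numeric(length(tt))
    on <- tt >= pre_ms & tt < pre_ms + duration
    x[on] <- dI * (1 - exp(-(tt[on] - pre_ms) / tau))
    off <- tt >= pre_ms + duration
    i_end <- dI * (1 - exp(-duration / tau))
    x[off] <- i_end * exp(-(tt[off] - pre_ms - duration) / tau)
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    out <- trace(x, rate, "voltage_clamped_current")
    attr(out, "step_onset_ms") <- pre_ms
    attr(out, "tau_ms") <- tau
    out
  })
}

#' Simulate a current-clamp spike train
#'
#' Places stereotyped action potentials at cumulative inter-spike intervals.
#' Each AP consists of a slow depolarizing approach (below the 5 mV/ms
#' derivative criterion), a fast upstroke from threshold to peak, a
#' repolarizing downstroke to the AHP minimum, and a plateau until the next
#' approach.
#'
#' @param isis Inter-spike intervals in ms (peak to peak); `n` intervals give
#'   `n + 1` spikes.
#' @param threshold Programmed AP threshold in mV.
#' @param peak AP peak in mV.
#' @param ahp AHP minimum in mV.
#' @param baseline Resting/holding potential in mV.
#' @param approach_rate Pre-threshold depolarization rate in mV/ms (must stay
#'   below the 5 mV/ms detection criterion).
#' @param upstroke,downstroke Upstroke / downstroke rates in mV/ms.
#' @param first_peak_ms Time of the first spike peak.
#' @param seed Integer seed for the additive noise.
#' @param noise_sd Voltage noise SD in mV.
#' @param tail_ms Recording time after the last spike.
#' @param rate Sampling rate in Hz.
#' @return A [trace()] of kind `"current_clamped_voltage"` with attribute
#'   `peak_times_ms`.
#' @export
simulate_spike_train <- function(isis, threshold = -40, peak = 20,
                                 ahp = -55, baseline = -70,
                                 approach_rate = 3, upstroke = 400,
                                 downstroke = -300, first_peak_ms = 25,
                                 seed = NULL, noise_sd = 0, tail_ms = 20,
                                 rate = 20000) {
  if (any(isis <= 0)) stop("ISIs must be > 0", call. = FALSE)
  peaks <- first_peak_ms + cumsum(c(0, isis))
  .with_seed(seed, {
    dur <- max(peaks) + tail_ms
    tt <- seq(0, dur, by = 1000 / rate)
    v <- rep(baseline, length(tt))
    du <- (peak - threshold) / upstroke            # upstroke duration
    n_sp <- length(peaks)
    # inter-spike troughs: the AHP minimum, raised when a short ISI leaves
    # too little time for downstroke + sub-criterion approach
    troughs <- rep(baseline, n_sp)
    if (n_sp > 1) for (k in 2:n_sp) {
      isi <- peaks[k] - peaks[k - 1]
      # solve isi - du = (peak - v)/|downstroke| + (threshold - v)/approach
      a <- 1 / abs(downstroke); b <- 1 / approach_rate
      v_fill <- (peak * a + threshold * b - (isi - du)) / (a + b)
      troughs[k] <- max(ahp, v_fill)
      if (troughs[k] > threshold - 2)
        stop("ISI ", isi, " ms too short for the AP shape", call. = FALSE)
    }
    for (k in seq_len(n_sp)) {
      da <- (threshold - troughs[k]) / approach_rate
      t_thr <- peaks[k] - du
      t_app <- t_thr - da
      # plateau at the trough from the previous downstroke end
      if (k > 1) {
        dd_prev <- (troughs[k] - peak) / downstroke
        seg <- tt >= peaks[k - 1] + dd_prev & tt < t_app
        v[seg] <- troughs[k]
      }
      seg <- tt >= t_app & tt < t_thr
      v[seg] <- troughs[k] + approach_rate * (tt[seg] - t_app)
      seg <- tt >= t_thr & tt < peaks[k]
      v[seg] <- threshold + upstroke * (tt[seg] - t_thr)
      dd_k <- ((if (k < n_sp) troughs[k + 1] else ahp) - peak) / downstroke
      seg <- tt >= peaks[k] & tt < peaks[k] + dd_k
      v[seg] <- peak + downstroke * (tt[seg] - peaks[k])
      if (k == n_sp) {
        seg <- tt >= peaks[k] + dd_k
        v[seg] <- ahp + (baseline - ahp) *
          (1 - exp(-(tt[seg] - peaks[k] - dd_k) / 10))
      }
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    out <- trace(v, rate, "current_clamped_voltage")
    attr(out, "peak_times_ms") <- peaks
    attr(out, "threshold_mv") <- threshold
    out
  })
}

#' Simulate a field sweep with fEPSP and population spike
#'
#' A positive-going fEPSP (linear rise at `fepsp_slope` for `rise_ms`, then
#' exponential decay) with a negative-going population-spike deflection of
#' programmed area superimposed near the fEPSP peak. When `laser_on` is set,
#' the pop-spike area is scaled by `1 - laser_suppression`, emulating
#' optogenetic recruitment of inhibition that silences granule-cell firing.
#'
#' @param fepsp_slope fEPSP rising slope in mV/ms.
#' @param popspike_area Pop-spike area in mV*ms (>= 0).
#' @param laser_suppression Fractional suppression in `[0, 1]` applied when
#'   `laser_on`.
#' @param laser_on Logical; is the laser paired on this sweep?
#' @param seed Integer seed.
#' @param noise_sd Noise SD in mV.
#' @param stim_onset_ms Electrical stimulus time.
#' @param rise_ms fEPSP rise duration.
#' @param decay_tau_ms fEPSP decay time constant.
#' @param popspike_latency_ms Pop-spike center relative to the stimulus.
#' @param popspike_width_ms Gaussian SD of the pop-spike deflection.
#' @param duration_ms,rate Sweep duration (ms) and sampling rate (Hz).
#' @return A [trace()] of kind `"field"` with attribute `truth` (the
#'   programmed slope and effective pop-spike area).
#' @export
simulate_field_sweep <- function(fepsp_slope, popspike_area,
                                 laser_suppression = 0, laser_on = FALSE,
                                 seed = NULL, noise_sd = 0.01,
                                 stim_onset_ms = 10, rise_ms = 4,
                                 decay_tau_ms = 15,
                                 popspike_latency_ms = 5.5,
                                 popspike_width_ms = 0.4,
                                 duration_ms = 60, rate = 20000) {
  if (laser_suppression < 0 || laser_suppression > 1)
    stop("'laser_suppression' must be in [0, 1]", call. = FALSE)
  if (popspike_area < 0) stop("'popspike_area' must be >= 0", call. = FALSE)
  .with_seed(seed, {
    tt <- seq(0, duration_ms, by = 1000 / rate)
    x <- numeric(length(tt))
    t_rel <- tt - stim_onset_ms
    peak <- fepsp_slope * rise_ms
    ris <- t_rel >= 0 & t_rel < rise_ms
    x[ris] <- fepsp_slope * t_rel[ris]
    dec <- t_rel >= rise_ms
    x[dec] <- peak * exp(-(t_rel[dec] - rise_ms) / decay_tau_ms)
    area_eff <- popspike_area *
      (if (laser_on) 1 - laser_suppression else 1)
    if (area_eff > 0) {
      amp <- area_eff / (popspike_width_ms * sqrt(2 * pi))
      x <- x - amp *
        exp(-((t_rel - popspike_latency_ms)^2) / (2 * popspike_width_ms^2))
    }
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    out <- trace(x, rate, "field")
    attr(out, "truth") <- list(fepsp_slope = fepsp_slope,
                               popspike_area = area_eff,
                               popspike_peak_ms =
                                 stim_onset_ms + popspike_latency_ms,
                               stim_onset_ms = stim_onset_ms)
    out
  })
}

#' Sigmoidal pop-spike recruitment curve
#'
#' Maps stimulus intensity to pop-spike area through a logistic recruitment
#' model, used to choose stimulus intensities in the 30-55% band of the
#' maximal pop-spike before pairing experiments.
#'
#' @param intensity Stimulus intensity in uA.
#' @param max_area Maximal pop-spike area in mV*ms.
#' @param i50 Intensity of half-maximal recruitment (uA).
#' @param k Recruitment slope parameter (uA).
#' @return Pop-spike area in mV*ms.
#' @export
popspike_recruitment <- function(intensity, max_area = 1, i50 = 60, k = 12) {
  max_area / (1 + exp(-(intensity - i50) / k))
}

#' Simulate a laser-pairing field experiment over a delay grid
#'
#' For each laser-to-stimulus delay, simulates alternating laser-off and
#' laser-on field sweeps (5 trials per condition by default) with the
#' programmed suppression profile. Negative delays mean the laser precedes
#' the electrical stimulus.
#'
#' @param dts Delay grid in ms (e.g. `seq(-50, 10, by = 10)`).
#' @param suppression Fractional pop-spike suppression at each delay (same
#'   length as `dts`).
#' @param n_per_condition Trials per condition at each delay.
#' @param popspike_area Baseline pop-spike area (mV*ms).
#' @param fepsp_slope fEPSP slope (mV/ms).
#' @param noise_sd Noise SD in mV.
#' @param seed Integer seed.
#' @return A list of per-delay records, each with `dt_ms`, `off` and `on`
#'   (lists of field [trace()]s) and `stim_onset_ms`; class
#'   `"pairing_recordings"`.
#' @export
simulate_pairing_experiment <- function(dts, suppression,
                                        n_per_condition = 5,
                                        popspike_area = 0.5,
                                        fepsp_slope = 0.25,
                                        noise_sd = 0.005, seed = NULL) {
  if (length(dts) != length(suppression))
    stop("'dts' and 'suppression' must have equal length", call. = FALSE)
  .with_seed(seed, {
    recs <- lapply(seq_along(dts), function(i) {
      off <- lapply(seq_len(n_per_condition), function(j)
        simulate_field_sweep(fepsp_slope, popspike_area,
                             laser_suppression = 0, laser_on = FALSE,
                             noise_sd = noise_sd))
      on <- lapply(seq_len(n_per_condition), function(j)
        simulate_field_sweep(fepsp_slope, popspike_area,
                             laser_suppression = suppression[i],
                             laser_on = TRUE, noise_sd = noise_sd))
      list(dt_ms = dts[i], off = off, on = on, stim_onset_ms = 10)
    })
    structure(recs, class = "pairing_recordings")
  })
}

#' Simulate simultaneous cell and field recordings
#'
#' Builds a field sweep (with or without a pop-spike) and a current-clamp
#' trace whose spikes occur at programmed delays relative to the pop-spike
#' peak, emulating paired whole-cell/field recordings of interneuron
#' recruitment.
#'
#' @param spike_delays_ms Signed spike-peak delays relative to the pop-spike
#'   peak (negative = before the pop-spike).
#' @param popspike_present Logical; `FALSE` emulates block of granule-cell
#'   firing (the pop-spike is abolished while the direct cortical volley and
#'   its spike persist).
#' @param popspike_area Pop-spike area when present.
#' @param fepsp_slope fEPSP slope (mV/ms).
#' @param seed Integer seed.
#' @param noise_sd Field noise SD (mV).
#' @return List with `cell` (voltage [trace()]), `field` (field [trace()]),
#'   and `truth` (programmed pop-spike peak time and spike times).
#' @export
simulate_paired_spike_field <- function(spike_delays_ms,
                                        popspike_present = TRUE,
                                        popspike_area = 0.5,
                                        fepsp_slope = 0.25, seed = NULL,
                                        noise_sd = 0) {
  .with_seed(seed, {
    fld <- simulate_field_sweep(fepsp_slope,
                                if (popspike_present) popspike_area else 0,
                                noise_sd = noise_sd)
    ps_peak <- attr(fld, "truth")$popspike_peak_ms
    spike_times <- sort(ps_peak + spike_delays_ms)
    isis <- diff(spike_times)
    cell <- simulate_spike_train(
      isis = if (length(isis)) isis else numeric(0),
      first_peak_ms = spike_times[1L], noise_sd = 0,
      tail_ms = max(5, trace_duration(fld) - max(spike_times)),
      rate = fld$sampling_rate)
    # align durations
    list(cell = cell, field = fld,
         truth = list(popspike_peak_ms = ps_peak,
                      spike_times_ms = spike_times))
  })
}
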