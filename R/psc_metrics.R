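# Formula-defined PSC metrics.
#
# Reported peak amplitude is the product of the mean amplitude over success
# trials and the probability of success. Rise time runs from 20% to 80%
# (EPSC) or 70% (IPSC) of peak amplitude; decay time from 80% (EPSC) or 70%
# (IPSC) down to 30%. Half-width is the duration above 50% of peak.
# Threshold times are located by linear interpolation between samples.

# first/last time (ms, fractional) the rectified signal crosses `level`,
# rising phase before peak / falling phase after peak
.cross_time <- function(x, rate, level, peak_idx, side = c("rise", "fall")) {
  side <- match.arg(side)
  dt <- 1000 / rate
  if (side == "rise") {
    seg <- x[seq_len(peak_idx)]
    below <- which(seg < level)
    if (!length(below) || max(below) >= peak_idx) return(NA_real_)
    i <- max(below)
    frac <- (level - seg[i]) / (seg[i + 1L] - seg[i])
    (i - 1 + frac) * dt
  } else {
    seg <- x[peak_idx:length(x)]
    below <- which(seg < level)
    if (!length(below)) return(NA_real_)
    i <- min(below)
    if (i == 1L) return((peak_idx - 1) * dt)
    frac <- (seg[i - 1L] - level) / (seg[i - 1L] - seg[i])
    (peak_idx + i - 3 + frac) * dt
  }
}

#' Kinetic and amplitude metrics of a PSC
#'
#' Operates on the average of success trials (baseline-subtracted). Rise time
#' is measured from 20% to 80% (EPSC) or 20% to 70% (IPSC) of peak amplitude
#' on the rising phase; decay time from 80% (EPSC) or 70% (IPSC) down to 30%
#' on the falling phase; half-width is the duration above 50% of peak. The
#' reported amplitude is `mean success amplitude x success probability`.
#'
#' @param mean_success_trace A [trace()]: the average over success trials,
#'   baseline-subtracted.
#' @param psc_class `"EPSC"` or `"IPSC"` (sets the rise/decay fractions).
#' @param success A [success_record()], or a single success probability.
#' @param stim_onset_ms Stimulus time (ms); the onset latency is reported
#'   relative to it. `NULL` skips the latency.
#' @param noise_floor_pa Peak magnitudes at or below this value are flagged
#'   undefined.
#' @return An object of class `"psc_kinetics"`: list with
#'   `amplitude_pa` (failure-weighted), `mean_success_amplitude_pa`,
#'   `success_probability`, `rise_ms`, `decay_ms`, `half_width_ms`,
#'   `onset_latency_ms`, `defined`.
#' @export
psc_kinetics <- function(mean_success_trace, psc_class = c("IPSC", "EPSC"),
                         success = 1, stim_onset_ms = NULL,
                         noise_floor_pa = 0) {
  stopifnot(inherits(mean_success_trace, "trace"))
  psc_class <- match.arg(psc_class)
  p_succ <- if (inherits(success, "success_record"))
    success$success_probability else as.numeric(success)
  x0 <- mean_success_trace$samples
  rate <- mean_success_trace$sampling_rate
  pol <- if (abs(min(x0)) >= abs(max(x0))) -1 else 1
  x <- pol * x0                              # rectified, peak positive
  peak_idx <- which.max(x)
  peak <- x[peak_idx]
  if (peak <= noise_floor_pa) {
    return(structure(list(amplitude_pa = NA_real_,
                          mean_success_amplitude_pa = NA_real_,
                          success_probability = p_succ, rise_ms = NA_real_,
                          decay_ms = NA_real_, half_width_ms = NA_real_,
                          onset_latency_ms = NA_real_, defined = FALSE),
                     class = "psc_kinetics"))
  }
  hi <- if (psc_class == "EPSC") 0.8 else 0.7
  t20 <- .cross_time(x, rate, 0.2 * peak, peak_idx, "rise")
  thi_r <- .cross_time(x, rate, hi * peak, peak_idx, "rise")
  thi_f <- .cross_time(x, rate, hi * peak, peak_idx, "fall")
  t30 <- .cross_time(x, rate, 0.3 * peak, peak_idx, "fall")
  t50r <- .cross_time(x, rate, 0.5 * peak, peak_idx, "rise")
  t50f <- .cross_time(x, rate, 0.5 * peak, peak_idx, "fall")
  t10 <- .cross_time(x, rate, 0.1 * peak, peak_idx, "rise")
  lat <- if (is.null(stim_onset_ms)) NA_real_
         else mean_success_trace$t0 + t10 - stim_onset_ms
  structure(list(
    amplitude_pa = peak * p_succ,
    mean_success_amplitude_pa = peak,
    success_probability = p_succ,
    rise_ms = thi_r - t20,
    decay_ms = t30 - thi_f,
    half_width_ms = t50f - t50r,
    onset_latency_ms = lat,
    defined = TRUE), class = "psc_kinetics")
}

#' @export
print.psc_kinetics <- function(x, ...) {
  if (!x$defined) { cat("<psc_kinetics: undefined (below noise floor)>\n")
    return(invisible(x)) }
  cat(sprintf(
    paste0("<psc_kinetics: amplitude %.1f pA (success %.1f pA x P %.2f), ",
           "rise %.2f ms, decay %.2f ms, half-width %.2f ms>\n"),
    x$amplitude_pa, x$mean_success_amplitude_pa, x$success_probability,
    x$rise_ms, x$decay_ms, x$half_width_ms))
  invisible(x)
}

#' Per-pulse charge of a train response
#'
#' The charge of each pulse is the baseline-subtracted integral of the
#' current over a window equal to the inter-pulse interval, starting at the
#' corresponding pulse onset; the last pulse uses the same window length.
#' The baseline is the median over `baseline_ms` immediately before the
#' first pulse (a pre-train baseline, so depressing or summating responses
#' within the train are integrated as recorded).
#'
#' @param sweep A [trace()] (typically the average over sweeps).
#' @param protocol A [stimulus_protocol()] with a train of >= 2 pulses at a
#'   constant rate.
#' @param baseline_ms Pre-train baseline window in ms.
#' @return An object of class `"train_response"`: list with `charges_pa_ms`
#'   (signed, one per pulse), `window_ms`, `truncated` (flag: last window ran
#'   past the sweep end), `n_pulses`.
#' @export
pulse_charges <- function(sweep, protocol, baseline_ms = 10) {
  stopifnot(inherits(sweep, "trace"), inherits(protocol, "stimulus_protocol"))
  onsets <- protocol$onsets
  if (length(onsets) < 2)
    stop("'protocol' must be a train of >= 2 pulses", call. = FALSE)
  gaps <- diff(onsets)
  if (max(gaps) - min(gaps) > 1000 / sweep$sampling_rate + 1e-9)
    stop("train must have a constant inter-pulse interval", call. = FALSE)
  ipi <- gaps[1L]
  tt <- trace_times(sweep)
  b_idx <- tt >= onsets[1L] - baseline_ms & tt < onsets[1L]
  baseline <- if (any(b_idx)) stats::median(sweep$samples[b_idx]) else 0
  x <- sweep$samples - baseline
  truncated <- FALSE
  charges <- vapply(onsets, function(on) {
    sel <- tt >= on & tt < on + ipi
    if (on + ipi > max(tt) + 1e-9) truncated <<- TRUE
    pracma::trapz(tt[sel], x[sel])
  }, numeric(1))
  structure(list(charges_pa_ms = charges, window_ms = ipi,
                 truncated = truncated, n_pulses = length(onsets)),
            class = "train_response")
}

#' Normalize train charges for short-term plasticity
#'
#' Inhibitory inputs onto granule cells are normalized to the first pulse
#' (`direction = "IN_to_GC"`); granule-cell outputs onto interneurons, which
#' facilitate, are normalized to the last pulse (`direction = "GC_to_IN"`).
#' The reference-pulse ratio is exactly 1.
#'
#' @param tr A `"train_response"` from [pulse_charges()].
#' @param direction `"IN_to_GC"` (reference = pulse 1) or `"GC_to_IN"`
#'   (reference = last pulse).
#' @return Numeric vector of charge ratios (reference ratio = 1).
#' @export
normalize_train <- function(tr, direction = c("IN_to_GC", "GC_to_IN")) {
  stopifnot(inherits(tr, "train_response"))
  direction <- match.arg(direction)
  ref_idx <- if (direction == "IN_to_GC") 1L else tr$n_pulses
  ref <- tr$charges_pa_ms[ref_idx]
  if (!is.finite(ref) || ref == 0)
    stop("reference pulse charge is zero; ratios undefined", call. = FALSE)
  ratios <- tr$charges_pa_ms / ref
  ratios[ref_idx] <- 1                     # exact by construction
  ratios
}

#' Whole-train charge normalized to peak amplitude
#'
#' Integrates the entire response over `window_ms` from the first pulse and
#' divides by the peak amplitude, as used for high-frequency (50 Hz) trains
#' where individual pulses fuse (charge over 340 ms, normalized to the peak).
#'
#' @param sweep A [trace()].
#' @param protocol A [stimulus_protocol()].
#' @param window_ms Integration window from the first pulse.
#' @param baseline_ms Pre-train baseline window.
#' @return List with `charge_pa_ms`, `peak_pa`, and
#'   `normalized_ms` (= charge / peak, in ms).
#' @export
train_charge_normalized <- function(sweep, protocol, window_ms = 340,
                                    baseline_ms = 10) {
  stopifnot(inherits(sweep, "trace"))
  on <- protocol$onsets[1L]
  tt <- trace_times(sweep)
  b_idx <- tt >= on - baseline_ms & tt < on
  baseline <- if (any(b_idx)) stats::median(sweep$samples[b_idx]) else 0
  x <- sweep$samples - baseline
  sel <- tt >= on & tt < on + window_ms
  q <- pracma::trapz(tt[sel], x[sel])
  pk <- x[sel][which.max(abs(x[sel]))]
  list(charge_pa_ms = q, peak_pa = pk,
       normalized_ms = if (pk != 0) q / pk else NA_real_)
}

#' Coefficient of variation of success amplitudes
#'
#' Population SD (n denominator) over the mean, treating the recorded
#' success trials as the full set of observations being described rather
#' than a sample from a larger one.
#'
#' @param successes Numeric vector of success-trial amplitudes (>= 2).
#' @return SD / mean of the amplitudes.
#' @export
cv_amplitude <- function(successes) {
  n <- length(successes)
  if (n < 2)
    stop("need at least 2 success amplitudes", call. = FALSE)
  m <- mean(successes)
  sqrt(mean((successes - m)^2)) / m
}

#' Functional synapse count from saturating vs. unitary IPSC
#'
#' The number of functional contacts is estimated as the ratio between the
#' IPSC amplitude in saturation (maximal presynaptic recruitment) and the
#' unitary IPSC amplitude, obtained under minimal stimulation where failures
#' occur in at least 10% of trials.
#'
#' @param saturating_ipsc_pa Saturating IPSC amplitude (pA, > 0 magnitude).
#' @param unitary_ipsc_pa Unitary IPSC amplitude (pA, > 0 magnitude).
#' @return List with `count` (unrounded ratio) and `count_rounded`.
#' @export
unitary_synapse_count <- function(saturating_ipsc_pa, unitary_ipsc_pa) {
  if (!is.numeric(unitary_ipsc_pa) || unitary_ipsc_pa <= 0)
    stop("'unitary_ipsc_pa' must be > 0", call. = FALSE)
  if (!is.numeric(saturating_ipsc_pa) || saturating_ipsc_pa <= 0)
    stop("'saturating_ipsc_pa' must be > 0", call. = FALSE)
  r <- saturating_ipsc_pa / unitary_ipsc_pa
  list(count = r, count_rounded = round(r))
}
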