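# Passive-membrane and spike-train characterization.
#
# Input resistance and capacitance come from the current response to a
# hyperpolarizing voltage step (10 mV, 100 ms). Spike threshold is the point
# where dVm/dt reaches 5 mV/ms; AP amplitude runs from threshold to positive
# peak, AHP from threshold to the repolarization minimum, ISIs peak to peak,
# and the adaptation ratio is ISI3 / ISIlast. The full spiking profile is
# evaluated at three times the threshold (rheobase) current.

#' Passive membrane properties from a voltage step
#'
#' Input resistance is `step / dI_ss` where `dI_ss` is the steady-state
#' current change; capacitance comes from the integrated transient charge
#' `C = |Q_transient| / |step|` by default (less model-dependent than a tau
#' fit), with a tau-fit estimate also reported (`tau = R * C`).
#'
#' @param step_response A [trace()] of voltage-clamp current containing the
#'   step.
#' @param step_mV Step amplitude in mV (default -10).
#' @param step_ms Step duration in ms (> 0).
#' @param step_onset_ms Step onset time; taken from the trace attribute
#'   `step_onset_ms` when `NULL`.
#' @return An object of class `"passive_props"`: list with
#'   `input_resistance_mohm`, `capacitance_pf` (charge-based),
#'   `capacitance_tau_pf` (tau-fit), `tau_ms`, `flagged` (no detectable
#'   plateau).
#' @export
passive_props <- function(step_response, step_mV = -10, step_ms = 100,
                          step_onset_ms = NULL) {
  stopifnot(inherits(step_response, "trace"))
  if (!is.numeric(step_ms) || step_ms <= 0)
    stop("'step_ms' must be > 0", call. = FALSE)
  if (step_mV == 0) stop("'step_mV' must be nonzero", call. = FALSE)
  if (is.null(step_onset_ms))
    step_onset_ms <- attr(step_response, "step_onset_ms")
  if (is.null(step_onset_ms))
    stop("step onset unknown; pass 'step_onset_ms'", call. = FALSE)
  tt <- trace_times(step_response)
  x <- step_response$samples
  pre <- x[tt < step_onset_ms]
  if (!length(pre)) stop("no pre-step baseline in trace", call. = FALSE)
  i0 <- mean(pre)
  in_step <- tt >= step_onset_ms & tt < step_onset_ms + step_ms
  # steady state: last 20% of the step
  ss_sel <- tt >= step_onset_ms + 0.8 * step_ms &
            tt < step_onset_ms + step_ms
  i_ss <- mean(x[ss_sel])
  d_iss <- i_ss - i0
  flagged <- FALSE
  if (abs(d_iss) < 4 * stats::sd(x[ss_sel]) / sqrt(sum(ss_sel))) {
    flagged <- TRUE
  }
  r_mohm <- step_mV / d_iss * 1000            # mV/pA = GOhm -> MOhm
  # transient charge relative to the steady state, over the step
  q_tr <- pracma::trapz(tt[in_step], x[in_step] - i_ss)   # pA*ms = fC
  c_pf <- abs(q_tr / step_mV)                 # fC/mV = pF
  # tau fit: log-linear regression on the settling transient
  exc <- x[in_step] - i_ss
  tseg <- tt[in_step] - step_onset_ms
  keep <- abs(exc) > 0.05 * abs(d_iss) & tseg > 0
  tau_ms <- if (sum(keep) > 5) {
    fit <- stats::lm(log(abs(exc[keep])) ~ tseg[keep])
    -1 / stats::coef(fit)[[2L]]
  } else NA_real_
  structure(list(input_resistance_mohm = r_mohm, capacitance_pf = c_pf,
                 capacitance_tau_pf = if (is.finite(tau_ms))
                   tau_ms / r_mohm * 1000 else NA_real_,
                 tau_ms = tau_ms, flagged = flagged),
            class = "passive_props")
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("<passive_props: R %.1f MOhm, C %.1f pF, tau %.2f ms%s>\n",
              x$input_resistance_mohm, x$capacitance_pf, x$tau_ms,
              if (x$flagged) " [flagged: no plateau]" else ""))
  invisible(x)
}

#' Detect action potentials by the dV/dt criterion
#'
#' The threshold point of each spike is the first sample at which the
#' centered-difference derivative of the (lightly smoothed, 1 kHz low-pass)
#' membrane potential reaches `dvdt_thresh` mV/ms; the spike peak is the
#' voltage maximum that follows. Spikes are separated by at least 1 ms.
#'
#' @param v A [trace()] of membrane potential (current clamp).
#' @param dvdt_thresh Derivative criterion in mV/ms.
#' @param smooth_cutoff Low-pass cutoff (Hz) for derivative stabilization.
#' @param min_separation_ms Minimum spike separation.
#' @param min_rise_mv Minimum depolarization from the threshold point to the
#'   peak for a candidate to count as a spike (rejects derivative crossings
#'   produced by noise or filter ringing).
#' @return A data.frame with one row per spike: `peak_ms`, `peak_mv`,
#'   `threshold_ms`, `threshold_mv` (voltages read from the unsmoothed
#'   trace).
#' @export
detect_spikes <- function(v, dvdt_thresh = 5, smooth_cutoff = 1000,
                          min_separation_ms = 1, min_rise_mv = 15) {
  stopifnot(inherits(v, "trace"))
  rate <- v$sampling_rate
  x <- v$samples
  vs <- if (smooth_cutoff < rate / 2)
    lowpass(v, smooth_cutoff)$samples else x
  n <- length(vs)
  dt <- 1000 / rate
  dvdt_s <- c(NA, (vs[3:n] - vs[1:(n - 2)]) / (2 * dt), NA)
  dvdt_r <- c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt), NA)
  empty <- data.frame(peak_ms = numeric(0), peak_mv = numeric(0),
                      threshold_ms = numeric(0), threshold_mv = numeric(0))

  # candidate peaks: local maxima of the smoothed voltage (earliest sample
  # of a plateau)
  d <- diff(vs)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(empty)
  look_back <- round(3 * rate / 1000)
  spikes <- list()
  for (p in cand) {
    w0 <- max(2L, p - look_back)
    w <- w0:max(w0, p - 1L)
    sup <- w[!is.na(dvdt_s[w]) & dvdt_s[w] >= dvdt_thresh]
    if (!length(sup)) next                    # no upstroke before this max
    # first sample of the last contiguous suprathreshold run before the peak
    brk <- which(diff(sup) > 2L)
    i_thr <- if (length(brk)) sup[max(brk) + 1L] else sup[1L]
    # refine against the raw derivative (exact on clean data)
    raw_w <- i_thr:(p - 1L)
    raw_hit <- raw_w[!is.na(dvdt_r[raw_w]) & dvdt_r[raw_w] >= dvdt_thresh]
    if (length(raw_hit)) i_thr <- raw_hit[1L]
    # peak on the raw trace near the smoothed maximum
    pw <- max(1L, p - 6L):min(n, p + 6L)
    p_raw <- pw[which.max(x[pw])]
    if (x[p_raw] - x[i_thr] < min_rise_mv) next
    spikes[[length(spikes) + 1L]] <-
      data.frame(peak_ms = v$t0 + (p_raw - 1) * dt,
                 peak_mv = x[p_raw],
                 threshold_ms = v$t0 + (i_thr - 1) * dt,
                 threshold_mv = x[i_thr])
  }
  if (!length(spikes)) return(empty)
  out <- do.call(rbind, spikes)
  out <- out[order(out$peak_ms), , drop = FALSE]
  # merge candidates closer than the minimum separation (keep the larger)
  keep <- rep(TRUE, nrow(out))
  last <- 1L
  for (i in seq_len(nrow(out))[-1L]) {
    if (out$peak_ms[i] - out$peak_ms[last] < min_separation_ms) {
      if (out$peak_mv[i] > out$peak_mv[last]) keep[last] <- FALSE
      else keep[i] <- FALSE
      if (keep[i]) last <- i
    } else last <- i
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike-train metrics
#'
#' Per-spike and train-level features: AP amplitude (threshold to positive
#' peak), AHP amplitude (threshold to the repolarization minimum before the
#' next spike), peak-to-peak ISIs, instantaneous frequency (1000/ISI), and
#' the adaptation ratio ISI3 / ISIlast (defined for >= 4 spikes).
#'
#' @param v A [trace()] of membrane potential.
#' @param spikes Data.frame from [detect_spikes()].
#' @param window_end_ms Optional end of the stimulus step; spikes after it
#'   are ignored (the "last spike" is the last one within the step).
#' @return An object of class `"spike_train_metrics"`: list with
#'   `n_spikes`, `threshold_mv`, `ap_amplitude_mv`, `ahp_amplitude_mv`
#'   (per-spike vectors), `isis_ms`, `instantaneous_freq_hz`,
#'   `adaptation_ratio` (`NA` with fewer than 4 spikes).
#' @export
spike_features <- function(v, spikes, window_end_ms = NULL) {
  stopifnot(inherits(v, "trace"))
  if (!is.null(window_end_ms))
    spikes <- spikes[spikes$peak_ms <= window_end_ms, , drop = FALSE]
  n_sp <- nrow(spikes)
  if (n_sp == 0)
    return(structure(list(n_spikes = 0L, threshold_mv = numeric(0),
                          ap_amplitude_mv = numeric(0),
                          ahp_amplitude_mv = numeric(0),
                          isis_ms = numeric(0),
                          instantaneous_freq_hz = numeric(0),
                          adaptation_ratio = NA_real_),
                     class = "spike_train_metrics"))
  ahp <- vapply(seq_len(n_sp), function(k) {
    i1 <- .time_to_index(v, spikes$peak_ms[k])
    end_ms <- if (k < n_sp) spikes$peak_ms[k + 1L]
              else min(spikes$peak_ms[k] + 20,
                       v$t0 + trace_duration(v))
    i2 <- .time_to_index(v, end_ms)
    spikes$threshold_mv[k] - min(v$samples[i1:i2])
  }, numeric(1))
  isis <- diff(spikes$peak_ms)
  adapt <- if (n_sp >= 4) isis[3L] / isis[length(isis)] else NA_real_
  structure(list(
    n_spikes = n_sp,
    threshold_mv = spikes$threshold_mv,
    ap_amplitude_mv = spikes$peak_mv - spikes$threshold_mv,
    ahp_amplitude_mv = ahp,
    isis_ms = isis,
    instantaneous_freq_hz = 1000 / isis,
    adaptation_ratio = adapt), class = "spike_train_metrics")
}

#' @export
print.spike_train_metrics <- function(x, ...) {
  cat(sprintf(
    "<spike_train_metrics: %d spikes, AP %.1f mV, mean ISI %.1f ms, adaptation %.2f>\n",
    x$n_spikes, mean(x$ap_amplitude_mv),
    if (length(x$isis_ms)) mean(x$isis_ms) else NA,
    x$adaptation_ratio))
  invisible(x)
}

#' Rheobase and spiking profile from a current-step family
#'
#' Rheobase is the smallest injected current that evokes at least one spike.
#' The full spike-train characterization is computed on the step closest to
#' three times the rheobase. Step ladders are typically 10 pA for granule
#' cells and 50 pA for interneurons.
#'
#' @param step_family List of records, each a list with `current_pa` and
#'   `trace` (a voltage [trace()]); currents must be increasing.
#' @param window_end_ms Optional end of the stimulus step window.
#' @param ... Passed to [detect_spikes()].
#' @return List with `rheobase_pa` (`NA` if no step spikes), `profile_pa`
#'   (the 3x step used), and `metrics` (a `"spike_train_metrics"`).
#' @export
rheobase_and_profile <- function(step_family, window_end_ms = NULL, ...) {
  currents <- vapply(step_family, function(r) r$current_pa, numeric(1))
  if (is.unsorted(currents, strictly = TRUE))
    stop("step currents must be strictly increasing", call. = FALSE)
  counts <- vapply(step_family, function(r)
    nrow(detect_spikes(r$trace, ...)), integer(1))
  first <- which(counts >= 1L)
  if (!length(first))
    return(list(rheobase_pa = NA_real_, profile_pa = NA_real_,
                metrics = NULL))
  rheo <- currents[min(first)]
  target <- 3 * rheo
  prof_idx <- which.min(abs(currents - target))
  tr <- step_family[[prof_idx]]$trace
  sp <- detect_spikes(tr, ...)
  list(rheobase_pa = rheo, profile_pa = currents[prof_idx],
       metrics = spike_features(tr, sp, window_end_ms = window_end_ms))
}
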