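# Field-potential analysis: fEPSP slope, population-spike area, the
# laser-induced change of field responses, and spike timing relative to the
# pop-spike peak.
#
# The pop-spike is the deflection carved into the fEPSP by synchronous
# granule-cell firing; its area (relative to the interpolated fEPSP
# envelope, the tangent-skim method) is proportional to the number of
# spiking neurons.

#' fEPSP slope and pop-spike area of one field sweep
#'
#' The fEPSP slope is the steepest 20-80% linear fit of the initial rising
#' phase. The pop-spike area is the area between the trace and the fEPSP
#' envelope interpolated linearly between the deflection's flanking
#' shoulders (tangent skim); it is polarity-agnostic and reported as a
#' magnitude in mV*ms.
#'
#' @param sweep A field [trace()].
#' @param stim_onset_ms Stimulus time (ms).
#' @param analysis_window_ms Window after the stimulus searched for the
#'   fEPSP and pop-spike.
#' @param noise_sd_mv Noise scale; deflections below `4 * noise_sd_mv` are
#'   reported as area 0 with a flag. `NULL` estimates it from the pre-stimulus
#'   baseline.
#' @return An object of class `"field_metrics"`: list with
#'   `fepsp_slope_mv_per_ms`, `popspike_area_mv_ms`,
#'   `popspike_peak_ms`, `flagged` (no deflection above noise).
#' @export
field_metrics <- function(sweep, stim_onset_ms = 10,
                          analysis_window_ms = 30, noise_sd_mv = NULL) {
  stopifnot(inherits(sweep, "trace"))
  tt <- trace_times(sweep)
  x <- sweep$samples
  rate <- sweep$sampling_rate
  if (is.null(noise_sd_mv)) {
    pre <- x[tt < stim_onset_ms]
    noise_sd_mv <- if (length(pre) > 10) stats::sd(pre) else 0
  }
  sel <- tt >= stim_onset_ms & tt <= stim_onset_ms + analysis_window_ms
  seg <- x[sel]; tseg <- tt[sel]

  # fEPSP polarity from the envelope: the larger smooth excursion
  env_pol <- if (abs(max(seg)) >= abs(min(seg))) 1 else -1
  segp <- env_pol * seg                       # fEPSP positive-going

  # --- pop-spike: deflection opposite to the envelope ---------------------
  # light smoothing for shoulder finding (the raw trace is integrated)
  segs <- if (rate / 2 > 2000)
    .butter_apply(segp, rate, 2000, "low") else segp
  # locate the dip: largest excursion below the two-sided running-max bound
  upper <- pmin(cummax(segs), rev(cummax(rev(segs))))
  dip <- upper - segs
  i_min <- which.max(dip)
  flagged <- FALSE
  area <- 0; ps_peak <- NA_real_
  if (dip[i_min] > 4 * noise_sd_mv && dip[i_min] > 0) {
    # shoulders = nearest flanking local maxima of the smoothed trace
    # (tangent-skim). The walk looks ahead ~0.5 ms so residual noise
    # wiggles do not stop it early.
    look <- max(1L, round(0.5 * rate / 1000))
    climb <- function(i, dir) {
      repeat {
        cand <- if (dir < 0) max(1L, i - look):(i - 1L)
                else (i + 1L):min(length(segs), i + look)
        if (!length(cand) || (dir < 0 && i == 1L) ||
            (dir > 0 && i == length(segs))) break
        j <- cand[which.max(segs[cand])]
        if (segs[j] > segs[i]) i <- j else break
      }
      i
    }
    i1 <- climb(i_min, -1L)
    i2 <- climb(i_min, +1L)
    if (i2 > i1 + 1L) {
      envline <- segs[i1] + (segs[i2] - segs[i1]) *
        (tseg[i1:i2] - tseg[i1]) / (tseg[i2] - tseg[i1])
      area <- pracma::trapz(tseg[i1:i2], envline - segp[i1:i2])
      area <- max(area, 0)
      ps_peak <- tseg[i_min]
    } else flagged <- TRUE
  } else {
    flagged <- TRUE
  }

  # --- fEPSP slope: steepest 20-80% fit of the initial rising phase -------
  # measure on the dip-free envelope so the pop-spike does not bias it
  smooth <- upper - segs[1L]                  # upper envelope, re-zeroed
  pk_idx <- which.max(smooth)
  peak <- smooth[pk_idx]
  rise_sel <- seq_len(pk_idx)
  lo <- 0.2 * peak; hi <- 0.8 * peak
  in_band <- rise_sel[smooth[rise_sel] >= lo & smooth[rise_sel] <= hi]
  slope <- if (length(in_band) >= 2) {
    fit <- stats::lm(smooth[in_band] ~ tseg[in_band])
    env_pol * stats::coef(fit)[[2L]]
  } else NA_real_

  structure(list(fepsp_slope_mv_per_ms = abs(slope),
                 popspike_area_mv_ms = area,
                 popspike_peak_ms = ps_peak,
                 flagged = flagged),
            class = "field_metrics")
}

#' @export
print.field_metrics <- function(x, ...) {
  cat(sprintf("<field_metrics: slope %.3f mV/ms, pop-spike area %.3f mV*ms%s>\n",
              x$fepsp_slope_mv_per_ms, x$popspike_area_mv_ms,
              if (x$flagged) " [no deflection]" else ""))
  invisible(x)
}

#' Laser-induced change of field responses
#'
#' `100 * (mean_off - mean_on) / mean_off`, applied to the pop-spike area
#' (optionally to the fEPSP slope as well), over alternating laser-off /
#' laser-on trials (at least 5 per condition).
#'
#' @param off_sweeps,on_sweeps Lists of field [trace()]s.
#' @param stim_onset_ms Stimulus time.
#' @param what `"area"` (default) or `"slope"`.
#' @param min_trials Minimum trials per condition.
#' @return List with `percent_change`, `mean_off`, `mean_on`, `n_off`,
#'   `n_on`; `percent_change` is `NA` (flagged) when `mean_off` is ~0.
#' @export
laser_change <- function(off_sweeps, on_sweeps, stim_onset_ms = 10,
                         what = c("area", "slope"), min_trials = 5) {
  what <- match.arg(what)
  if (length(off_sweeps) < min_trials || length(on_sweeps) < min_trials)
    stop("need at least ", min_trials, " trials per condition",
         call. = FALSE)
  field <- if (what == "area") function(s)
    field_metrics(s, stim_onset_ms)$popspike_area_mv_ms
  else function(s) field_metrics(s, stim_onset_ms)$fepsp_slope_mv_per_ms
  m_off <- mean(vapply(off_sweeps, field, numeric(1)))
  m_on <- mean(vapply(on_sweeps, field, numeric(1)))
  pc <- if (abs(m_off) < 1e-12) NA_real_ else 100 * (m_off - m_on) / m_off
  list(percent_change = pc, mean_off = m_off, mean_on = m_on,
       n_off = length(off_sweeps), n_on = length(on_sweeps))
}

#' Laser-pairing delay curve
#'
#' Percent change of the pop-spike area per laser-to-stimulus delay, over a
#' grid of delays (negative = laser precedes the electrical stimulus).
#' Delays missing one condition are omitted with a warning.
#'
#' @param recordings A `"pairing_recordings"` object (see
#'   [simulate_pairing_experiment()]) or a list of records with `dt_ms`,
#'   `off`, `on`, `stim_onset_ms`.
#' @param min_trials Minimum trials per condition at each delay.
#' @return An object of class `"pairing_result"`: data.frame with columns
#'   `dt_ms`, `percent_change`, `mean_off`, `mean_on`, `n_off`, `n_on`.
#' @export
delay_curve <- function(recordings, min_trials = 5) {
  rows <- lapply(recordings, function(r) {
    if (!length(r$off) || !length(r$on)) {
      warning("delay ", r$dt_ms, " ms missing a condition; omitted",
              call. = FALSE)
      return(NULL)
    }
    lc <- laser_change(r$off, r$on, stim_onset_ms = r$stim_onset_ms,
                       min_trials = min_trials)
    data.frame(dt_ms = r$dt_ms, percent_change = lc$percent_change,
               mean_off = lc$mean_off, mean_on = lc$mean_on,
               n_off = lc$n_off, n_on = lc$n_on)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("pairing_result", "data.frame"))
}

#' Spike timing relative to the pop-spike peak
#'
#' For simultaneous cell and field recordings on a common time base, reports
#' the signed delay of each spike peak relative to the pop-spike peak and
#' classifies it as occurring before or after it. Spikes before the
#' pop-spike reflect direct (feedforward) cortical drive; spikes after it
#' reflect recruitment by the granule-cell population (feedback).
#'
#' @param cell_trace A current-clamp (or loose-patch) [trace()] with spikes.
#' @param field_trace A simultaneous field [trace()].
#' @param stim_onset_ms Stimulus time.
#' @param ... Passed to [detect_spikes()].
#' @return A data.frame with `spike_ms`, `delay_ms`
#'   (spike peak - pop-spike peak) and `timing` (`"before"`/`"after"`);
#'   zero rows (with a `popspike_missing` attribute) when no pop-spike is
#'   detected.
#' @export
spike_delay_vs_popspike <- function(cell_trace, field_trace,
                                    stim_onset_ms = 10, ...) {
  fm <- field_metrics(field_trace, stim_onset_ms)
  spikes <- detect_spikes(cell_trace, ...)
  if (fm$flagged || !is.finite(fm$popspike_peak_ms)) {
    out <- data.frame(spike_ms = numeric(0), delay_ms = numeric(0),
                      timing = character(0))
    attr(out, "popspike_missing") <- TRUE
    return(out)
  }
  delay <- spikes$peak_ms - fm$popspike_peak_ms
  data.frame(spike_ms = spikes$peak_ms, delay_ms = delay,
             timing = ifelse(delay < 0, "before", "after"))
}
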