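# Zero-phase Butterworth filtering.
#
# Filters are 4th-order Butterworth applied forward-backward so that evoked
# latencies are not phase-shifted. signal::filtfilt() applies no edge padding
# (a constant trace would decay toward zero at both ends), so the input is
# extended by odd reflection about each endpoint before filtering and the
# padding removed afterwards.

.filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  pre  <- 2 * x[1L] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

.butter_apply <- function(samples, sampling_rate, cutoff, type) {
  nyq <- sampling_rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, Nyquist = %g Hz)", nyq),
         call. = FALSE)
  bf <- signal::butter(4, cutoff / nyq, type = type)
  # pad long enough for the filter transient (~3 periods of the cutoff)
  pad <- ceiling(3 * sampling_rate / cutoff)
  .filtfilt_padded(bf, samples, pad)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase). The default
#' 250 Hz cutoff is the band in which postsynaptic-current peaks are sought.
#'
#' @param t A [trace()].
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @return A [trace()] of the same length and rate. The DC level is preserved
#'   to within 0.1%.
#' @export
lowpass <- function(t, cutoff = 250) {
  stopifnot(inherits(t, "trace"))
  y <- .butter_apply(t$samples, t$sampling_rate, cutoff, "low")
  trace(y, t$sampling_rate, t$kind, t$t0)
}

#' Zero-phase high-pass filter
#'
#' @inheritParams lowpass
#' @return A [trace()] containing the high-frequency residual.
#' @export
highpass <- function(t, cutoff = 500) {
  stopifnot(inherits(t, "trace"))
  y <- .butter_apply(t$samples, t$sampling_rate, cutoff, "high")
  trace(y, t$sampling_rate, t$kind, t$t0)
}

#' Noise level of a recording
#'
#' Standard deviation of the high-pass residual (> 500 Hz by default), the
#' noise estimate against which event detection thresholds are set. Computed
#' per sweep, which keeps the estimate robust to slow inter-sweep drift.
#'
#' @inheritParams lowpass
#' @param cutoff High-pass cutoff in Hz.
#' @return Noise SD in the trace's units (pA for currents); non-negative.
#' @export
noise_sd <- function(t, cutoff = 500) {
  stopifnot(inherits(t, "trace"))
  if (stats::sd(t$samples) == 0) return(0)
  stats::sd(highpass(t, cutoff)$samples)
}
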