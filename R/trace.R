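#' Sampled electrophysiology signal
#'
#' A `trace` is one uniformly sampled signal: a voltage-clamp current (pA),
#' a current-clamp voltage (mV), or an extracellular field potential (mV).
#' Internal canonical units are pA, mV, ms and Hz throughout the package;
#' any unit conversion happens at I/O boundaries only.
#'
#' @param samples Numeric vector of samples (pA for current, mV for
#'   voltage/field). Must be finite and of length >= 2.
#' @param sampling_rate Sampling rate in Hz (> 0). Recordings of this kind
#'   are typically acquired at 10-20 kHz.
#' @param kind One of `"voltage_clamped_current"`, `"current_clamped_voltage"`,
#'   `"field"`.
#' @param t0 Time (ms) of the first sample; defaults to 0.
#'
#' @return An object of class `"trace"`.
#' @examples
#' tr <- trace(rnorm(2000), sampling_rate = 20000, kind = "voltage_clamped_current")
#' trace_duration(tr)  # 100 ms
#' @export
trace <- function(samples,
                  sampling_rate,
                  kind = c("voltage_clamped_current", "current_clamped_voltage",
                           "field"),
                  t0 = 0) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("'samples' must contain at least 2 points", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate, kind = kind,
         t0 = as.numeric(t0)),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace: %s, %d samples @ %g kHz, %.1f ms>\n",
              x$kind, length(x$samples), x$sampling_rate / 1000,
              trace_duration(x)))
  invisible(x)
}

#' Sample times of a trace, in ms
#' @param t A [trace()].
#' @return Numeric vector of sample times (ms), starting at `t0`.
#' @export
trace_times <- function(t) {
  stopifnot(inherits(t, "trace"))
  t$t0 + (seq_along(t$samples) - 1L) * 1000 / t$sampling_rate
}

#' Duration of a trace in ms
#' @param t A [trace()].
#' @return Duration in ms (n_samples / rate).
#' @export
trace_duration <- function(t) {
  stopifnot(inherits(t, "trace"))
  length(t$samples) * 1000 / t$sampling_rate
}

# sample index of time x ms (1-based, clamped)
.time_to_index <- function(t, x) {
  i <- round((x - t$t0) * t$sampling_rate / 1000) + 1L
  pmin(pmax(as.integer(i), 1L), length(t$samples))
}

#' Stimulus protocol
#'
#' Ordered stimulus onset times with pulse width and modality. For train
#' protocols (e.g. 5 laser pulses at 20 Hz) `train_rate` gives the
#' within-train rate; `repetition_rate` the sweep repetition rate (trains or
#' single pulses are typically repeated at 0.07 Hz).
#'
#' @param onsets Stimulus onset times in ms, strictly increasing.
#' @param width Pulse width in ms (> 0). Laser pulses here are 0.2-1 ms.
#' @param modality `"laser"` or `"electrical"`.
#' @param train_rate Within-train rate in Hz, or `NULL` for single pulses.
#' @param repetition_rate Sweep repetition rate in Hz (metadata only).
#' @param sample_period_ms Tolerance (ms) used to check train spacing against
#'   `1000/train_rate`; defaults to 0.1 ms.
#' @return An object of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(onsets, width = 1,
                              modality = c("laser", "electrical"),
                              train_rate = NULL, repetition_rate = 0.07,
                              sample_period_ms = 0.1) {
  modality <- match.arg(modality)
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L || any(diff(onsets) <= 0))
    stop("'onsets' must be non-empty and strictly increasing", call. = FALSE)
  if (!is.numeric(width) || width <= 0)
    stop("'width' must be > 0 ms", call. = FALSE)
  if (!is.null(train_rate)) {
    ipi <- 1000 / train_rate
    gaps <- diff(onsets)
    if (length(gaps) && any(abs(gaps - ipi) > sample_period_ms + 1e-9))
      stop("onset spacing inconsistent with train_rate", call. = FALSE)
  }
  structure(
    list(onsets = onsets, width = width, modality = modality,
         train_rate = train_rate, repetition_rate = repetition_rate),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol: %s, %d pulse(s) of %g ms%s>\n",
              x$modality, length(x$onsets), x$width,
              if (!is.null(x$train_rate))
                sprintf(" at %g Hz", x$train_rate) else ""))
  invisible(x)
}

#' Recording quality-control record
#'
#' Holds the per-cell quantities used for inclusion: absolute leak current at
#' the holding potential and series resistance, plus the cell class (granule
#' cell or interneuron) that sets the thresholds.
#'
#' @param leak_current Leak current in pA (signed).
#' @param series_resistance Series resistance in MOhm.
#' @param cell_class `"GC"` (granule cell) or `"IN"` (interneuron).
#' @return An object of class `"qc_record"`.
#' @seealso [qc_pass()]
#' @export
qc_record <- function(leak_current, series_resistance,
                      cell_class = c("GC", "IN")) {
  cell_class <- match.arg(cell_class)
  if (!is.finite(leak_current) || !is.finite(series_resistance))
    stop("QC values must be finite", call. = FALSE)
  structure(
    list(leak_current = leak_current,
         series_resistance = series_resistance,
         cell_class = cell_class),
    class = "qc_record"
  )
}

#' Sweep-level quality control
#'
#' Inclusion criteria by cell class: absolute leak current < 100 pA for
#' granule cells or < 250 pA for interneurons, and series resistance
#' at most 25 MOhm (GC) or 15 MOhm (IN).
#'
#' @param q A [qc_record()].
#' @param thresholds Optional named list overriding the class thresholds:
#'   `leak_pA` and `rs_MOhm`.
#' @return `TRUE` if the recording passes, else `FALSE`.
#' @examples
#' qc_pass(qc_record(-50, 20, "GC"))   # TRUE
#' qc_pass(qc_record(-50, 26, "GC"))   # FALSE
#' @export
qc_pass <- function(q, thresholds = NULL) {
  stopifnot(inherits(q, "qc_record"))
  defaults <- switch(q$cell_class,
    GC = list(leak_pA = 100, rs_MOhm = 25),
    IN = list(leak_pA = 250, rs_MOhm = 15),
    stop("unknown cell_class", call. = FALSE)
  )
  if (!is.null(thresholds)) defaults[names(thresholds)] <- thresholds
  abs(q$leak_current) < defaults$leak_pA &&
    q$series_resistance <= defaults$rs_MOhm
}

#' Set of stimulus-aligned sweeps
#'
#' Repeated sweeps sharing one stimulus protocol and holding potential. All
#' sweeps must have equal length and sampling rate, and every protocol onset
#' must fall inside the sweep duration.
#'
#' @param sweeps List of [trace()] objects of equal length and rate.
#' @param protocol A [stimulus_protocol()].
#' @param holding_potential Holding potential in mV, or `NULL`.
#' @param qc A [qc_record()], or `NULL`.
#' @return An object of class `"sweep_set"`.
#' @export
sweep_set <- function(sweeps, protocol, holding_potential = NULL, qc = NULL) {
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "trace")))
    stop("'sweeps' must be a non-empty list of trace objects", call. = FALSE)
  ns <- vapply(sweeps, function(s) length(s$samples), integer(1))
  rs <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(rs)) != 1L)
    stop("all sweeps must share one length and sampling rate", call. = FALSE)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  dur <- trace_duration(sweeps[[1L]])
  if (any(protocol$onsets < sweeps[[1L]]$t0) ||
      any(protocol$onsets >= sweeps[[1L]]$t0 + dur))
    stop("protocol onsets must fall within the sweep duration", call. = FALSE)
  if (!is.null(qc)) stopifnot(inherits(qc, "qc_record"))
  structure(
    list(sweeps = sweeps, protocol = protocol,
         holding_potential = holding_potential, qc = qc),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set: %d sweeps x %d samples @ %g kHz%s>\n",
              length(x$sweeps), length(x$sweeps[[1L]]$samples),
              x$sweeps[[1L]]$sampling_rate / 1000,
              if (!is.null(x$holding_potential))
                sprintf(", Vh %g mV", x$holding_potential) else ""))
  print(x$protocol)
  invisible(x)
}

#' Average the sweeps of a sweep set
#'
#' @param s A [sweep_set()].
#' @param which Optional integer vector of sweep indices to average
#'   (e.g. success trials only).
#' @return A [trace()] holding the pointwise mean.
#' @export
average_sweeps <- function(s, which = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  idx <- if (is.null(which)) seq_along(s$sweeps) else which
  if (!length(idx)) stop("no sweeps selected", call. = FALSE)
  m <- rowMeans(vapply(s$sweeps[idx], function(x) x$samples,
                       numeric(length(s$sweeps[[1L]]$samples))))
  trace(m, s$sweeps[[1L]]$sampling_rate, s$sweeps[[1L]]$kind,
        s$sweeps[[1L]]$t0)
}
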