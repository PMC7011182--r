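# Postsynaptic-current event detection.
#
# Events are peaks in the low-pass filtered current (< 250 Hz) exceeding
# 4 standard deviations of the noise level (the > 500 Hz high-pass residual,
# computed per sweep). The onset of an event is the time at which 10% of the
# maximum amplitude is reached in the unfiltered signal; amplitude is
# measured on the unfiltered trace relative to a local baseline (median of
# the 5 ms preceding the onset).

#' Detect postsynaptic-current events in one sweep
#'
#' The trace is sign-flipped according to `polarity` so the search is always
#' for positive peaks; events are reported with the original polarity. Peaks
#' closer than `refractory` ms are merged (the larger peak is kept; a plateau
#' tie-break keeps the earliest sample).
#'
#' @param t A [trace()] of voltage-clamped current.
#' @param polarity -1 for inward events, +1 for outward; known from the
#'   holding potential relative to the reversal potential.
#' @param k_sd Detection threshold as a multiple of the noise SD.
#' @param low_cutoff Low-pass cutoff (Hz) of the detection band.
#' @param noise_cutoff High-pass cutoff (Hz) of the noise band.
#' @param refractory Minimum peak separation in ms.
#' @param sweep_index Sweep identifier stored with each event.
#' @return An object of class `"event_table"`: a data.frame with columns
#'   `onset_ms`, `peak_ms`, `amplitude_pa` (baseline-subtracted magnitude),
#'   `polarity`, `sweep`, `label` (initially `"unassigned"`), plus the
#'   detection parameters as attributes.
#' @export
detect_events <- function(t, polarity = -1, k_sd = 4, low_cutoff = 250,
                          noise_cutoff = 500, refractory = 2,
                          sweep_index = 1L) {
  stopifnot(inherits(t, "trace"))
  if (trace_duration(t) < 10)
    stop("trace shorter than 10 ms", call. = FALSE)
  if (!polarity %in% c(-1, 1)) stop("'polarity' must be -1 or +1",
                                    call. = FALSE)
  rate <- t$sampling_rate
  x_raw <- polarity * t$samples               # flipped: events positive
  sdn <- noise_sd(t, noise_cutoff)
  thr <- k_sd * sdn
  lp <- polarity * lowpass(t, low_cutoff)$samples

  peaks <- .find_peaks(lp, thr, refractory * rate / 1000)
  if (!length(peaks))
    return(.event_table(NULL, polarity, sweep_index,
                        k_sd, low_cutoff, noise_cutoff, refractory))

  rows <- lapply(peaks, function(p) {
    m <- .measure_event(x_raw, p, rate)
    data.frame(onset_ms = t$t0 + m$onset_idx_frac * 1000 / rate,
               peak_ms = t$t0 + (p - 1) * 1000 / rate,
               amplitude_pa = m$amplitude,
               onset_flagged = m$flagged)
  })
  .event_table(do.call(rbind, rows), polarity, sweep_index,
               k_sd, low_cutoff, noise_cutoff, refractory)
}

# local maxima of x above thr, separated by >= min_sep samples;
# plateau tie-break keeps the earliest sample
.find_peaks <- function(x, thr, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # rising-to-(flat-or-falling) transitions; first sample of any plateau
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[x[cand] >= thr & thr > 0]
  if (!length(cand)) return(integer(0))
  # greedy merge: keep largest peaks first, drop neighbors within min_sep
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_sep))
      kept <- c(kept, p)
  sort(kept)
}

# amplitude + onset of a peak on the flipped unfiltered signal.
# Baseline = median of the 5 ms preceding the onset. Because the onset is
# itself defined relative to the baseline, the two are solved by a short
# fixed-point iteration: start from the segment minimum as a provisional
# baseline, locate the 10% crossing, re-estimate the baseline from the
# window preceding that crossing, and relocate. When fewer than 2.5 ms of
# pre-onset data exist (event at the very start of a trace) the provisional
# minimum-based baseline is kept.
.measure_event <- function(x, p, rate, baseline_ms = 5, search_ms = 20,
                           avg_ms = 0.25) {
  n <- length(x)
  w_avg <- max(1L, round(avg_ms * rate / 1000))
  pk_val <- mean(x[max(1L, p - w_avg):min(n, p + w_avg)])
  s0 <- if (is.finite(search_ms))
    max(1L, p - round(search_ms * rate / 1000)) else 1L
  seg <- x[s0:p]
  w_base <- max(2L, round(baseline_ms * rate / 1000))
  min_base_samples <- max(2L, round(2.5 * rate / 1000))

  base <- min(seg)
  onset_idx <- s0 - 1; flagged <- FALSE
  for (pass in 1:2) {
    level <- base + 0.1 * (pk_val - base)
    below <- which(seg < level)
    if (!length(below)) { onset_idx <- s0 - 1; flagged <- TRUE; break }
    i_last <- max(below)                 # latest pre-peak crossing
    if (i_last >= length(seg)) { onset_idx <- p - 1; break }
    x1 <- seg[i_last]; x2 <- seg[i_last + 1L]
    frac <- if (x2 > x1) (level - x1) / (x2 - x1) else 0
    onset_idx <- (s0 + i_last - 2) + frac    # 0-based fractional index
    g <- s0 + i_last - 1L                    # last pre-onset sample (1-based)
    b0 <- max(1L, g - w_base + 1L)
    if (g - b0 + 1L >= min_base_samples)
      base <- stats::median(x[b0:g])
    # else: too close to the trace start; keep the minimum-based baseline
  }
  list(onset_idx_frac = onset_idx, amplitude = pk_val - base,
       flagged = flagged)
}

.event_table <- function(df, polarity, sweep_index, k_sd, low_cutoff,
                         noise_cutoff, refractory) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                     amplitude_pa = numeric(0), polarity = numeric(0),
                     sweep = integer(0), label = character(0),
                     onset_flagged = logical(0))
  } else {
    df$polarity <- polarity
    df$sweep <- as.integer(sweep_index)
    df$label <- "unassigned"
    df <- df[order(df$peak_ms),
             c("onset_ms", "peak_ms", "amplitude_pa", "polarity", "sweep",
               "label", "onset_flagged")]
    rownames(df) <- NULL
  }
  structure(df, class = c("event_table", "data.frame"),
            params = list(k_sd = k_sd, low_cutoff = low_cutoff,
                          noise_cutoff = noise_cutoff,
                          refractory = refractory))
}

#' Detect events across all sweeps of a sweep set
#'
#' @param s A [sweep_set()].
#' @inheritParams detect_events
#' @return An `"event_table"` over all sweeps, sorted by sweep then peak
#'   time.
#' @export
detect_events_sweepset <- function(s, polarity = -1, k_sd = 4,
                                   low_cutoff = 250, noise_cutoff = 500,
                                   refractory = 2) {
  stopifnot(inherits(s, "sweep_set"))
  tabs <- lapply(seq_along(s$sweeps), function(i)
    detect_events(s$sweeps[[i]], polarity, k_sd, low_cutoff, noise_cutoff,
                  refractory, sweep_index = i))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  .event_table2(out, attr(tabs[[1L]], "params"))
}

.event_table2 <- function(df, params) {
  structure(df, class = c("event_table", "data.frame"), params = params)
}

#' Event onset by the 10% rule
#'
#' The onset is the latest pre-peak time at which the unfiltered,
#' baseline-subtracted signal crosses 10% of the event's peak amplitude
#' (linear interpolation between samples). If no crossing is found in the
#' pre-peak search window the onset is flagged and set to the window start.
#'
#' @param t The [trace()] on which the event was detected.
#' @param peak_ms Peak time of the event (ms).
#' @param polarity Event polarity (-1 inward, +1 outward).
#' @param search_ms Length of the pre-peak search window in ms; the default
#'   searches the whole trace before the peak. [detect_events()] limits it
#'   to 20 ms so neighbouring events do not contaminate the baseline.
#' @return Onset time in ms (never later than the peak).
#' @export
event_onset <- function(t, peak_ms, polarity = -1, search_ms = Inf) {
  stopifnot(inherits(t, "trace"))
  rate <- t$sampling_rate
  p <- .time_to_index(t, peak_ms)
  m <- .measure_event(polarity * t$samples, p, rate, search_ms = search_ms)
  t$t0 + m$onset_idx_frac * 1000 / rate
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d event(s) in %d sweep(s)>\n",
              nrow(x), length(unique(x$sweep))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
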