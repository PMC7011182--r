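# Shuffle-based classification of stimulus-responsive cells.
#
# A cell is responsive when events accumulate within a 12 ms window after
# the stimulus more than expected by chance, assessed against a null built
# by a 2000-step shuffling procedure: each sweep's event train is circularly
# shifted by an independent uniform offset per shuffle, which preserves
# within-sweep event counts and inter-event structure.

# count of event times falling in any half-open (onset, onset + window]
.count_in_windows <- function(times, onsets, window) {
  if (!length(times)) return(0L)
  bounds <- as.vector(rbind(onsets, onsets + window))
  # interval index is odd inside a window; left-open, right-closed
  idx <- findInterval(times, bounds, left.open = TRUE, rightmost.closed = FALSE)
  sum(idx %% 2L == 1L)
}

#' Permutation test for stimulus-locked responsiveness
#'
#' The observed statistic is the total number of detected events whose onset
#' falls within `(stimulus, stimulus + window]` over all sweeps. The null
#' distribution is built by circularly shifting each sweep's event-onset
#' times by an independent uniform offset (wrapping at the sweep edge) and
#' recounting, `n_shuffles` times. The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`, so it is never zero,
#' and responsiveness requires strict `p < alpha`.
#'
#' @param events An `"event_table"` (see [detect_events()]), or a data.frame
#'   with columns `onset_ms` and `sweep`, from QC-passed sweeps.
#' @param protocol A [stimulus_protocol()]; needs at least 5 stimulus onsets
#'   in total across the sweeps analyzed (`length(onsets) * n_sweeps >= 5`).
#' @param sweep_duration_ms Duration of one sweep (ms); the wrap point of the
#'   circular shift.
#' @param n_sweeps Number of sweeps the events came from (sweeps without
#'   events still contribute stimulus windows).
#' @param window Post-stimulus accumulation window in ms.
#' @param n_shuffles Number of shuffle steps.
#' @param alpha Significance level for the responsiveness call.
#' @param seed Integer seed for the shuffle offsets.
#' @return An object of class `"responsiveness_result"` with fields
#'   `observed_in_window`, `p_value`, `responsive`, `null_counts` (mean, sd,
#'   max), `window_ms`, `n_shuffles`, `alpha`.
#' @export
classify_responsive <- function(events, protocol, sweep_duration_ms,
                                n_sweeps, window = 12, n_shuffles = 2000,
                                alpha = 0.05, seed = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n_stim_total <- length(protocol$onsets) * n_sweeps
  if (n_stim_total < 5)
    stop("need at least 5 stimulus presentations", call. = FALSE)
  df <- as.data.frame(events)
  if (nrow(df) == 0) {
    return(structure(
      list(observed_in_window = 0L, p_value = 1, responsive = FALSE,
           null_counts = c(mean = 0, sd = 0, max = 0),
           window_ms = window, n_shuffles = n_shuffles, alpha = alpha),
      class = "responsiveness_result"))
  }
  by_sweep <- split(df$onset_ms, df$sweep)
  observed <- sum(vapply(by_sweep, .count_in_windows, integer(1),
                         onsets = protocol$onsets, window = window))
  .with_seed(seed, {
    null_counts <- integer(n_shuffles)
    bounds <- as.vector(rbind(protocol$onsets, protocol$onsets + window))
    for (ts in by_sweep) {
      offs <- stats::runif(n_shuffles, 0, sweep_duration_ms)
      shifted <- outer(ts, offs, "+") %% sweep_duration_ms
      idx <- findInterval(shifted, bounds, left.open = TRUE)
      null_counts <- null_counts + colSums(matrix(idx %% 2L == 1L,
                                                  nrow = length(ts)))
    }
    p <- (1 + sum(null_counts >= observed)) / (1 + n_shuffles)
    structure(
      list(observed_in_window = observed, p_value = p,
           responsive = p < alpha,
           null_counts = c(mean = mean(null_counts),
                           sd = stats::sd(null_counts),
                           max = max(null_counts)),
           window_ms = window, n_shuffles = n_shuffles, alpha = alpha),
      class = "responsiveness_result")
  })
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat(sprintf(
    "<responsiveness: observed %d in %g ms window | null %.2f +/- %.2f (max %d) | p = %.4g -> %s>\n",
    x$observed_in_window, x$window_ms, x$null_counts["mean"],
    x$null_counts["sd"], x$null_counts["max"], x$p_value,
    if (x$responsive) "responsive" else "not responsive"))
  invisible(x)
}

#' Label events as evoked or spontaneous
#'
#' For a cell classified responsive, the earliest event with onset in
#' `(stimulus, stimulus + window]` after each stimulus is labeled `evoked`;
#' all other events (including later in-window events after the same pulse)
#' are labeled `spontaneous`. For a non-responsive cell every event is
#' spontaneous.
#'
#' @inheritParams classify_responsive
#' @param responsive Logical responsiveness call for the cell.
#' @return The event table with the `label` column filled in; labels
#'   partition the table.
#' @export
split_evoked <- function(events, protocol, window = 12, responsive = TRUE) {
  df <- as.data.frame(events)
  params <- attr(events, "params")
  if (!nrow(df)) return(.event_table2(df, params))
  df$label <- "spontaneous"
  if (responsive) {
    for (s in unique(df$sweep)) {
      rows <- which(df$sweep == s)
      for (on in protocol$onsets) {
        inw <- rows[df$onset_ms[rows] > on &
                    df$onset_ms[rows] <= on + window &
                    df$label[rows] != "evoked"]
        if (length(inw))
          df$label[inw[which.min(df$onset_ms[inw])]] <- "evoked"
      }
    }
  }
  .event_table2(df, params)
}

#' Per-trial success record
#'
#' One flag per stimulus presentation: `TRUE` when an evoked event followed
#' that pulse. The success probability is the fraction of trials in which an
#' evoked response was observed.
#'
#' @param events A labeled `"event_table"` (see [split_evoked()]).
#' @param protocol A [stimulus_protocol()].
#' @param n_sweeps Number of sweeps (pulses without events count as
#'   failures).
#' @param window Post-stimulus window in ms.
#' @return An object of class `"success_record"`: list with `flags`
#'   (n_sweeps x n_pulses logical matrix) and `success_probability`.
#' @export
success_record <- function(events, protocol, n_sweeps, window = 12) {
  df <- as.data.frame(events)
  n_pulses <- length(protocol$onsets)
  flags <- matrix(FALSE, n_sweeps, n_pulses)
  ev <- df[df$label == "evoked", , drop = FALSE]
  for (r in seq_len(nrow(ev))) {
    j <- which(ev$onset_ms[r] > protocol$onsets &
               ev$onset_ms[r] <= protocol$onsets + window)
    if (length(j)) flags[ev$sweep[r], j[1L]] <- TRUE
  }
  structure(list(flags = flags, success_probability = mean(flags)),
            class = "success_record")
}

#' @export
print.success_record <- function(x, ...) {
  cat(sprintf("<success_record: %d/%d trials, P(success) = %.3f>\n",
              sum(x$flags), length(x$flags), x$success_probability))
  invisible(x)
}

#' Connection proportions by single pulses vs. trains
#'
#' Given per-cell responsiveness results under a single-pulse protocol and a
#' train protocol, reports the fraction of cells connected under each.
#' Short-term facilitation can reveal connections that stay silent under
#' individual stimuli, so the train fraction may exceed the single-pulse
#' fraction, but this is empirical and not asserted.
#'
#' @param single List of `"responsiveness_result"` (one per cell, single
#'   pulses).
#' @param train List of `"responsiveness_result"` (same cells, trains).
#' @return A list with `n_cells`, `n_single`, `n_train`,
#'   `prop_single`, `prop_train` (proportions are `NA` when `n_cells` is 0).
#' @export
connection_summary <- function(single, train) {
  if (length(single) != length(train))
    stop("'single' and 'train' must cover the same cells", call. = FALSE)
  n <- length(single)
  ns <- sum(vapply(single, function(r) isTRUE(r$responsive), logical(1)))
  nt <- sum(vapply(train, function(r) isTRUE(r$responsive), logical(1)))
  list(n_cells = n, n_single = ns, n_train = nt,
       prop_single = if (n) ns / n else NA_real_,
       prop_train = if (n) nt / n else NA_real_)
}
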