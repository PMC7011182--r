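# End-to-end orchestration: simulate -> detect -> classify -> metrics from
# one config, with a parameter manifest for provenance. Configs are plain
# nested lists (readable from YAML via yaml::read_yaml()); every analysis
# default mirrors the printed procedure: 250 Hz detection band, 500 Hz noise
# band, 4 SD threshold, 12 ms window, 2000 shuffles, alpha 0.05.

#' Default pipeline configuration
#'
#' @return A nested list with one block per stage (`simulate`, `detect`,
#'   `classify`, `metrics`) plus `stages`, `seed`, and `out_dir`.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "detect", "classify", "metrics"),
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      amplitude_pa = 50, tau_rise_ms = 1, tau_decay_ms = 10, polarity = -1,
      failure_prob = 0.2, latency_mean_ms = 2, latency_jitter_sd_ms = 0.3,
      train_scale = NULL, spont_rate_hz = 0.5, noise_sd_pa = 2,
      n_sweeps = 20, onsets_ms = 100, width_ms = 0.2, modality = "laser",
      train_rate_hz = NULL, duration_ms = 500, rate_hz = 20000
    ),
    detect = list(polarity = -1, k_sd = 4, low_cutoff_hz = 250,
                  noise_cutoff_hz = 500, refractory_ms = 2),
    classify = list(window_ms = 12, n_shuffles = 2000, alpha = 0.05),
    metrics = list(psc_class = "IPSC",
                   direction = "IN_to_GC")
  )
}

#' Validate a pipeline configuration
#'
#' @param config A nested list as returned by [default_config()].
#' @return Character vector of violations, each naming the offending field;
#'   empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  known <- c("simulate", "detect", "classify", "metrics")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    v <- c(v, paste0("stages: unknown stage '", bad, "'"))
  if (is.null(config$seed) || !is.finite(as.numeric(config$seed)))
    v <- c(v, "seed: must be a finite integer")
  chk_pos <- function(block, field, allow_zero = FALSE) {
    val <- config[[block]][[field]]
    if (is.null(val)) return(invisible())
    ok <- is.numeric(val) && all(is.finite(val)) &&
      if (allow_zero) all(val >= 0) else all(val > 0)
    if (!ok) v <<- c(v, paste0(block, ".", field, ": must be ",
                               if (allow_zero) ">= 0" else "> 0"))
  }
  chk_pos("simulate", "amplitude_pa")
  chk_pos("simulate", "tau_rise_ms")
  chk_pos("simulate", "tau_decay_ms")
  chk_pos("simulate", "n_sweeps")
  chk_pos("simulate", "spont_rate_hz", allow_zero = TRUE)
  chk_pos("simulate", "noise_sd_pa", allow_zero = TRUE)
  fp <- config$simulate$failure_prob
  if (!is.null(fp) && (!is.numeric(fp) || fp < 0 || fp > 1))
    v <- c(v, "simulate.failure_prob: must be in [0, 1]")
  if (!is.null(config$simulate$tau_rise_ms) &&
      !is.null(config$simulate$tau_decay_ms) &&
      is.numeric(config$simulate$tau_rise_ms) &&
      is.numeric(config$simulate$tau_decay_ms) &&
      config$simulate$tau_rise_ms >= config$simulate$tau_decay_ms)
    v <- c(v, "simulate.tau_rise_ms: must be < tau_decay_ms")
  chk_pos("detect", "k_sd")
  chk_pos("detect", "low_cutoff_hz")
  chk_pos("detect", "noise_cutoff_hz")
  chk_pos("detect", "refractory_ms", allow_zero = TRUE)
  chk_pos("classify", "window_ms")
  chk_pos("classify", "n_shuffles")
  al <- config$classify$alpha
  if (!is.null(al) && (!is.numeric(al) || al <= 0 || al >= 1))
    v <- c(v, "classify.alpha: must be in (0, 1)")
  v
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order on one synthetic cell:
#' `simulate` builds the sweep set (with ground truth), `detect` finds
#' events on every sweep, `classify` runs the responsiveness permutation
#' test and splits evoked from spontaneous events, and `metrics` computes
#' the success record and PSC kinetics. Deterministic given `config$seed`.
#'
#' @param config A config list (see [default_config()]); validated before
#'   running.
#' @param sweeps Optionally, an existing [sweep_set()] to analyze instead of
#'   simulating (the `simulate` stage is then skipped).
#' @return A list (`"pipeline_report"`) with per-stage outputs (`sweeps`,
#'   `truth`, `events`, `responsiveness`, `success`, `kinetics`) and a
#'   `manifest` echoing every parameter used.
#' @export
run_pipeline <- function(config = default_config(), sweeps = NULL) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  report <- list(manifest = config)
  truth <- NULL
  seed <- as.integer(config$seed)

  if ("simulate" %in% config$stages && is.null(sweeps)) {
    sc <- config$simulate
    model <- synapse_model(
      psc_shape(sc$amplitude_pa, sc$tau_rise_ms, sc$tau_decay_ms,
                sc$polarity),
      failure_prob = sc$failure_prob, latency_mean = sc$latency_mean_ms,
      latency_jitter_sd = sc$latency_jitter_sd_ms,
      train_scale = sc$train_scale, spont_rate = sc$spont_rate_hz,
      noise_sd = sc$noise_sd_pa)
    protocol <- stimulus_protocol(sc$onsets_ms, width = sc$width_ms,
                                  modality = sc$modality,
                                  train_rate = sc$train_rate_hz)
    sim <- simulate_sweepset(model, protocol, n_sweeps = sc$n_sweeps,
                             seed = seed, duration_ms = sc$duration_ms,
                             rate = sc$rate_hz)
    sweeps <- sim$sweeps
    truth <- sim$truth
    report$truth <- truth
  }
  if (is.null(sweeps))
    stop("stage 'detect' needs sweeps: enable 'simulate' or pass 'sweeps'",
         call. = FALSE)
  report$sweeps <- sweeps

  if (any(c("detect", "classify", "metrics") %in% config$stages)) {
    dc <- config$detect
    events <- detect_events_sweepset(
      sweeps, polarity = dc$polarity, k_sd = dc$k_sd,
      low_cutoff = dc$low_cutoff_hz, noise_cutoff = dc$noise_cutoff_hz,
      refractory = dc$refractory_ms)
    report$events <- events
  }

  if (any(c("classify", "metrics") %in% config$stages)) {
    cc <- config$classify
    dur <- trace_duration(sweeps$sweeps[[1L]])
    resp <- classify_responsive(
      report$events, sweeps$protocol, sweep_duration_ms = dur,
      n_sweeps = length(sweeps$sweeps), window = cc$window_ms,
      n_shuffles = cc$n_shuffles, alpha = cc$alpha, seed = seed + 1L)
    report$responsiveness <- resp
    report$events <- split_evoked(report$events, sweeps$protocol,
                                  window = cc$window_ms,
                                  responsive = resp$responsive)
  }

  if ("metrics" %in% config$stages) {
    mc <- config$metrics
    cc <- config$classify
    succ <- success_record(report$events, sweeps$protocol,
                           n_sweeps = length(sweeps$sweeps),
                           window = cc$window_ms)
    report$success <- succ
    succ_sweeps <- which(apply(succ$flags, 1L, any))
    if (length(succ_sweeps)) {
      avg <- average_sweeps(sweeps, succ_sweeps)
      # baseline-subtract using the pre-stimulus segment
      tt <- trace_times(avg)
      base <- stats::median(avg$samples[tt < sweeps$protocol$onsets[1L]])
      avg$samples <- avg$samples - base
      report$kinetics <- psc_kinetics(
        avg, psc_class = mc$psc_class, success = succ,
        stim_onset_ms = sweeps$protocol$onsets[1L])
    }
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$events))
    cat(sprintf("  events: %d\n", nrow(x$events)))
  if (!is.null(x$responsiveness))
    cat(sprintf("  responsive: %s (p = %.4g)\n",
                x$responsiveness$responsive, x$responsiveness$p_value))
  if (!is.null(x$success))
    cat(sprintf("  P(success): %.3f\n", x$success$success_probability))
  if (!is.null(x$kinetics) && isTRUE(x$kinetics$defined))
    cat(sprintf("  amplitude (failure-weighted): %.1f pA\n",
                x$kinetics$amplitude_pa))
  invisible(x)
}
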