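# Shared fixtures: standard shapes, protocols, and small simulated cells.

std_shape <- function(amplitude = 40) psc_shape(amplitude, 1, 10)

single_pulse <- function(onset = 100) {
  stimulus_protocol(onset, width = 0.2, modality = "laser")
}

train_20hz <- function(first = 100, n = 5) {
  stimulus_protocol(seq(first, by = 50, length.out = n), width = 0.2,
                    modality = "laser", train_rate = 20)
}

# one simulated cell with evoked + spontaneous events
sim_cell <- function(seed, amplitude = 40, noise = 4, failure = 0.3,
                     spont = 0.5, n_sweeps = 20, duration = 500,
                     protocol = single_pulse()) {
  m <- synapse_model(std_shape(amplitude), failure_prob = failure,
                     spont_rate = spont, noise_sd = noise)
  simulate_sweepset(m, protocol, n_sweeps = n_sweeps, seed = seed,
                    duration_ms = duration)
}

# Poisson null-cell event table (no traces needed for the permutation test)
null_cell_events <- function(seed, rate_hz = 5, duration_ms = 2000,
                             n_sweeps = 20) {
  set.seed(seed)
  n_ev <- stats::rpois(n_sweeps, rate_hz * duration_ms / 1000)
  data.frame(onset_ms = stats::runif(sum(n_ev), 0, duration_ms),
             sweep = rep(seq_len(n_sweeps), n_ev))
}

# protocol used for null calibration: 5 presentations per 2 s sweep
null_protocol <- function() {
  stimulus_protocol(c(200, 600, 1000, 1400, 1800), width = 0.2,
                    modality = "laser")
}

# peak (signed extremum) current on the average sweep of one holding
iv_peak <- function(sweepset, stim_onset = 20, window = c(0, 100)) {
  a <- average_sweeps(sweepset)
  tt <- trace_times(a) - stim_onset
  seg <- a$samples[tt >= window[1] & tt < window[2]]
  seg[which.max(abs(seg))]
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g (expected %g +/- %g)", object, expected,
                              tol))
}
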