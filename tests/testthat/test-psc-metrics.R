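test_that("reported amplitude is the success-mean x probability product", {
  fs <- 20000
  w <- psc_waveform(psc_shape(80, 1, 10), duration = 100)
  k <- psc_kinetics(w, "IPSC", success = 0.5)
  expect_equal(k$amplitude_pa, k$mean_success_amplitude_pa *
                 k$success_probability)
  expect_close(k$amplitude_pa, 40, 0.1)
})

test_that("rise and decay times match closed forms for both PSC classes", {
  fs <- 20000
  tt <- seq(0, 80, by = 1000 / fs)
  dt <- 1000 / fs
  tau_r <- 5
  sat <- trace(pmin(1 - exp(-tt / tau_r), 1 - exp(-60 / tau_r)), fs,
               "voltage_clamped_current")
  # EPSC rise 20->80%: tau * ln(0.8/0.2) = tau * ln 4
  expect_close(psc_kinetics(sat, "EPSC")$rise_ms, tau_r * log(4), 2 * dt)
  # IPSC rise 20->70%: tau * ln(0.8/0.3)
  expect_close(psc_kinetics(sat, "IPSC")$rise_ms, tau_r * log(0.8 / 0.3),
               2 * dt)

  tau_d <- 10
  dec <- trace(exp(-tt / tau_d), fs, "voltage_clamped_current")
  # EPSC decay 80->30%: tau * ln(8/3)
  expect_close(psc_kinetics(dec, "EPSC")$decay_ms, tau_d * log(8 / 3),
               2 * dt)
  # IPSC decay 70->30%: tau * ln(7/3)
  expect_close(psc_kinetics(dec, "IPSC")$decay_ms, tau_d * log(7 / 3),
               2 * dt)
})

test_that("half-width matches a numerically computed oracle", {
  # dense-grid oracle for the biexponential half-width, independent of the
  # interpolation path under test
  tr_ <- 1; td <- 10
  tfine <- seq(0, 100, by = 1e-4)
  kf <- exp(-tfine / td) - exp(-tfine / tr_)
  above <- tfine[kf >= 0.5 * max(kf)]
  hw_oracle <- max(above) - min(above)
  w <- psc_waveform(psc_shape(60, tr_, td), duration = 100)
  k <- psc_kinetics(w, "IPSC")
  expect_close(k$half_width_ms, hw_oracle, 0.1)
})

test_that("sub-noise responses are flagged undefined", {
  fs <- 20000
  k <- psc_kinetics(trace(rep(0, 2000) + 1e-9 * c(1:2000), fs,
                          "voltage_clamped_current"),
                    "IPSC", noise_floor_pa = 1)
  expect_false(k$defined)
  expect_true(is.na(k$amplitude_pa))
})

test_that("pulse charges integrate per-pulse windows with shared baseline", {
  fs <- 20000
  prot <- train_20hz(first = 100)
  flat <- trace(rep(0, fs / 2), fs, "voltage_clamped_current")
  tr0 <- pulse_charges(flat, prot)
  expect_equal(tr0$charges_pa_ms, rep(0, 5))
  expect_equal(tr0$window_ms, 50)
  expect_equal(tr0$n_pulses, 5)

  # single kernel inside the first window: closed-form integral
  A <- 40; tr_ <- 1; td <- 8
  tpk <- tr_ * td / (td - tr_) * log(td / tr_)
  kpk <- exp(-tpk / td) - exp(-tpk / tr_)
  q_expected <- -A * (td - tr_) / kpk
  x <- numeric(fs / 2)
  w <- psc_waveform(psc_shape(A, tr_, td), duration = 49.9)
  i0 <- round(100 * fs / 1000) + 1
  x[i0:(i0 + length(w$samples) - 1)] <- w$samples
  tr1 <- pulse_charges(trace(x, fs, "voltage_clamped_current"), prot)
  expect_close(tr1$charges_pa_ms[1], q_expected, abs(q_expected) * 0.02)
  expect_true(all(abs(tr1$charges_pa_ms[3:5]) < abs(q_expected) * 0.02))

  expect_error(pulse_charges(flat, single_pulse()), ">= 2 pulses")
})

test_that("train normalization uses the direction-specific reference", {
  tr <- structure(list(charges_pa_ms = c(100, 80, 70, 60, 50),
                       window_ms = 50, truncated = FALSE, n_pulses = 5L),
                  class = "train_response")
  r_in <- normalize_train(tr, "IN_to_GC")
  expect_identical(r_in[1], 1)
  expect_equal(r_in[5], 0.5)
  r_gc <- normalize_train(tr, "GC_to_IN")
  expect_identical(r_gc[5], 1)
  expect_equal(r_gc[1], 2)

  same <- structure(list(charges_pa_ms = rep(7, 5), window_ms = 50,
                         truncated = FALSE, n_pulses = 5L),
                    class = "train_response")
  expect_equal(normalize_train(same, "IN_to_GC"), rep(1, 5))

  zero <- structure(list(charges_pa_ms = c(0, 1, 1, 1, 1), window_ms = 50,
                         truncated = FALSE, n_pulses = 5L),
                    class = "train_response")
  expect_error(normalize_train(zero, "IN_to_GC"), "zero")
})

test_that("train ratios are invariant under global gain changes", {
  m <- synapse_model(std_shape(40), failure_prob = 0,
                     train_scale = c(1, 0.8, 0.7, 0.6, 0.5),
                     spont_rate = 0, noise_sd = 4)
  sim <- simulate_sweepset(m, train_20hz(), 15, seed = 4, duration_ms = 500)
  avg <- average_sweeps(sim$sweeps)
  r1 <- normalize_train(pulse_charges(avg, train_20hz()), "IN_to_GC")
  gained <- trace(avg$samples * 3.7, avg$sampling_rate, avg$kind)
  r2 <- normalize_train(pulse_charges(gained, train_20hz()), "IN_to_GC")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("depressing trains recover the programmed P5/P1 at SNR 10", {
  ratios <- vapply(1:10, function(s) {
    m <- synapse_model(std_shape(40), failure_prob = 0,
                       train_scale = c(1, 0.8, 0.7, 0.6, 0.5),
                       spont_rate = 0, noise_sd = 4)
    sim <- simulate_sweepset(m, train_20hz(), 15, seed = s,
                             duration_ms = 500)
    avg <- average_sweeps(sim$sweeps)
    normalize_train(pulse_charges(avg, train_20hz()), "IN_to_GC")[5]
  }, numeric(1))
  expect_close(mean(ratios), 0.5, 0.05)
})

test_that("whole-train charge normalization reports charge over peak", {
  fs <- 20000
  prot50 <- stimulus_protocol(seq(50, by = 20, length.out = 5), width = 0.2,
                              train_rate = 50)
  m <- synapse_model(std_shape(40), failure_prob = 0, spont_rate = 0,
                     noise_sd = 0)
  sim <- simulate_sweepset(m, prot50, 3, seed = 2, duration_ms = 450)
  out <- train_charge_normalized(average_sweeps(sim$sweeps), prot50,
                                 window_ms = 340)
  expect_lt(out$charge_pa_ms, 0)            # inward: negative charge
  expect_lt(out$peak_pa, 0)
  expect_gt(out$normalized_ms, 0)           # signs cancel
})

test_that("coefficient of variation follows its definition", {
  expect_equal(cv_amplitude(c(50, 100, 150)),
               sqrt(mean((c(50, 100, 150) - 100)^2)) / 100)
  expect_close(cv_amplitude(c(50, 100, 150)), 0.4082, 1e-3)
  expect_equal(cv_amplitude(rep(30, 10)), 0)
  expect_error(cv_amplitude(5), "at least 2")
  set.seed(8)
  x <- rnorm(200, 100, 30)
  expect_close(cv_amplitude(x), 0.3, 0.05)
})

test_that("unitary synapse count is the saturation/unitary ratio", {
  expect_equal(unitary_synapse_count(500, 50)$count, 10)
  expect_equal(unitary_synapse_count(42, 42)$count, 1)
  expect_error(unitary_synapse_count(500, 0), "unitary")
  expect_error(unitary_synapse_count(-10, 5), "saturating")
})

test_that("a multi-synapse cell yields the programmed contact count", {
  # 8 equal synapses: saturation protocol recruits all, minimal stimulation
  # isolates one (with >= 10% failures)
  uni <- 12
  prot <- single_pulse()
  sat <- simulate_sweepset(
    synapse_model(psc_shape(8 * uni, 1, 10), failure_prob = 0,
                  spont_rate = 0, noise_sd = 3),
    prot, 20, seed = 1, duration_ms = 300)
  mini <- simulate_sweepset(
    synapse_model(psc_shape(uni, 1, 10), failure_prob = 0.3,
                  spont_rate = 0, noise_sd = 3),
    prot, 40, seed = 2, duration_ms = 300)
  amp_of <- function(sim) {
    ev <- split_evoked(detect_events_sweepset(sim$sweeps), prot)
    mean(ev$amplitude_pa[ev$label == "evoked"])
  }
  est <- unitary_synapse_count(amp_of(sat), amp_of(mini))
  expect_close(est$count, 8, 1)
})
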