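test_that("psc_waveform is normalized to the programmed peak", {
  w <- psc_waveform(psc_shape(100, 1, 10), duration = 100)
  expect_close(min(w$samples), -100, 0.1)              # inward peak
  expect_equal(w$samples[1], 0)
  w2 <- psc_waveform(psc_shape(50, 2, 20, polarity = 1), duration = 200)
  expect_close(max(w2$samples), 50, 0.05)
  expect_error(psc_shape(100, 5, 5), "tau_rise")
})

test_that("psc_waveform charge matches the closed-form kernel integral", {
  # unnormalized kernel e^{-t/td} - e^{-t/tr} integrates to td - tr = 9;
  # the sampled waveform's charge must equal amplitude * 9 / kernel_peak
  tr_ <- 1; td <- 10; A <- 100
  tpk <- tr_ * td / (td - tr_) * log(td / tr_)
  kpk <- exp(-tpk / td) - exp(-tpk / tr_)
  expected <- -A * (td - tr_) / kpk                    # inward: negative
  w <- psc_waveform(psc_shape(A, tr_, td), duration = 200)
  q <- pracma::trapz(trace_times(w), w$samples)
  expect_close(q, expected, abs(expected) * 0.01)
})

test_that("simulate_sweepset honours failure probability edge cases", {
  m_all_fail <- synapse_model(std_shape(), failure_prob = 1,
                              spont_rate = 0, noise_sd = 2)
  sim <- simulate_sweepset(m_all_fail, single_pulse(), 5, seed = 1,
                           duration_ms = 300)
  expect_equal(nrow(sim$truth$events), 0)
  expect_false(any(sim$truth$successes))
  # pure noise: no sample deviates far beyond the noise scale
  expect_lt(max(abs(sim$sweeps$sweeps[[1]]$samples)), 2 * 5)

  m_never <- synapse_model(std_shape(), failure_prob = 0, spont_rate = 0,
                           noise_sd = 2)
  sim2 <- simulate_sweepset(m_never, single_pulse(), 50, seed = 2,
                            duration_ms = 300)
  expect_equal(sum(sim2$truth$events$label == "evoked"), 50)
  expect_equal(mean(sim2$truth$successes), 1)
})

test_that("simulate_sweepset is reproducible and seed-sensitive", {
  m <- synapse_model(std_shape(), failure_prob = 0.5, spont_rate = 1,
                     noise_sd = 3)
  a <- simulate_sweepset(m, single_pulse(), 3, seed = 7, duration_ms = 300)
  b <- simulate_sweepset(m, single_pulse(), 3, seed = 7, duration_ms = 300)
  c <- simulate_sweepset(m, single_pulse(), 3, seed = 8, duration_ms = 300)
  expect_identical(a$sweeps$sweeps[[1]]$samples, b$sweeps$sweeps[[1]]$samples)
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(a$sweeps$sweeps[[1]]$samples,
                         c$sweeps$sweeps[[1]]$samples))
})

test_that("empirical success fraction follows the binomial oracle", {
  m <- synapse_model(std_shape(), failure_prob = 0.5, spont_rate = 0,
                     noise_sd = 2)
  fracs <- vapply(1:40, function(s) {
    sim <- simulate_sweepset(m, single_pulse(50), 100, seed = s,
                             duration_ms = 150)
    mean(sim$truth$successes)
  }, numeric(1))
  # binomial(100, 0.5): individual draws within 3 SD of 0.5
  expect_true(all(abs(fracs - 0.5) < 3 * sqrt(0.25 / 100)))
  expect_close(mean(fracs), 0.5, 0.03)
})

test_that("spontaneous event counts are Poisson-consistent", {
  m <- synapse_model(std_shape(), failure_prob = 1, spont_rate = 4,
                     noise_sd = 2)
  sim <- simulate_sweepset(m, single_pulse(50), 50, seed = 5,
                           duration_ms = 1000)
  n <- nrow(sim$truth$events)
  lambda <- 4 * 1 * 50                      # rate * duration * sweeps
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("train_scale scales evoked amplitudes per pulse position", {
  m <- synapse_model(std_shape(40), failure_prob = 0,
                     train_scale = c(1, 0.8, 0.7, 0.6, 0.5),
                     spont_rate = 0, noise_sd = 0)
  sim <- simulate_sweepset(m, train_20hz(), 3, seed = 1, duration_ms = 500)
  ev <- sim$truth$events[order(sim$truth$events$sweep,
                               sim$truth$events$onset_ms), ]
  expect_equal(ev$amplitude_pa[1:5], 40 * c(1, 0.8, 0.7, 0.6, 0.5))
})

test_that("I-V family obeys Ohmic driving-force arithmetic", {
  iv <- simulate_iv_family(g_syn = 1, e_rev = -30,
                           holdings = c(-70, -50, -30), noise_sd = 0,
                           n_sweeps = 1, seed = 1)
  # holding at e_rev: no evoked current
  expect_lt(max(abs(iv$sweepsets[[3]]$sweeps[[1]]$samples)), 1e-9)
  # V = -70, e_rev = -30, g = 1 nS: peak -40 pA
  expect_close(min(iv$sweepsets[[1]]$sweeps[[1]]$samples), -40, 0.05)
  expect_error(simulate_iv_family(1, -30, holdings = c(-70, -50)),
               "3 holding")
})

test_that("two-component I-V gives biphasic currents at -50 mV", {
  comp <- list(
    list(g_syn = 1.5, e_rev = -30, shape = psc_shape(1, 0.8, 6),
         latency_ms = 0),
    list(g_syn = 1, e_rev = -65, shape = psc_shape(1, 4, 30),
         latency_ms = 22))
  iv <- simulate_iv_family(holdings = c(-90, -50, -20), components = comp,
                           noise_sd = 1, n_sweeps = 10, seed = 3,
                           duration_ms = 250)
  a <- average_sweeps(iv$sweepsets[[2]])
  tt <- trace_times(a) - 20
  early <- mean(a$samples[tt >= 0 & tt < 10])
  late <- mean(a$samples[tt >= 22 & tt < 100])
  expect_lt(early, 0)        # proximal: inward at -50 (e_rev -30)
  expect_gt(late, 0)         # distal: outward at -50 (e_rev -65)
})

test_that("step response follows Ohm's law and tau = RC", {
  st <- simulate_step_response(100, 20, seed = 1)
  tt <- trace_times(st)
  ss <- mean(st$samples[tt > 100 & tt < 120])
  expect_close(ss, -100, 1)                 # -10 mV / 100 MOhm
  # at t = tau = 2 ms the transient has settled to 1 - e^{-1}
  i_tau <- st$samples[which.min(abs(tt - 22))]
  expect_close(i_tau, -100 * (1 - exp(-1)), 1)
  expect_error(simulate_step_response(-5, 20), "> 0")
})

test_that("spike trains place peaks at the programmed ISIs", {
  sp <- simulate_spike_train(c(10, 10, 10))
  pk <- attr(sp, "peak_times_ms")
  expect_length(pk, 4)
  expect_equal(diff(pk), c(10, 10, 10))
  # peaks visible in the samples
  tt <- trace_times(sp)
  for (p in pk) {
    i <- which.min(abs(tt - p))
    expect_close(sp$samples[i], 20, 0.5)
  }
})

test_that("field sweeps scale the pop-spike with laser suppression", {
  full <- simulate_field_sweep(0.25, 0.5, laser_suppression = 1,
                               laser_on = TRUE, noise_sd = 0)
  none <- simulate_field_sweep(0.25, 0.5, laser_suppression = 0,
                               laser_on = TRUE, noise_sd = 0)
  base <- simulate_field_sweep(0.25, 0.5, noise_sd = 0)
  expect_equal(attr(full, "truth")$popspike_area, 0)
  expect_equal(none$samples, base$samples)
})
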