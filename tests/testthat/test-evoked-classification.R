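test_that("a perfectly locked cell gets the minimal attainable p-value", {
  # 20 sweeps, one event each, 3 ms after the stimulus; no spontaneous
  df <- data.frame(onset_ms = rep(103, 20), sweep = 1:20)
  r <- classify_responsive(df, single_pulse(), 500, 20, seed = 1)
  expect_equal(r$observed_in_window, 20L)
  expect_equal(r$p_value, 1 / 2001)
  expect_true(r$responsive)
  expect_gte(r$p_value, 1 / (r$n_shuffles + 1))
})

test_that("defaults match the analysis procedure and edge cases hold", {
  df <- data.frame(onset_ms = numeric(0), sweep = integer(0))
  r <- classify_responsive(df, single_pulse(), 500, 20)
  expect_equal(r$p_value, 1)
  expect_false(r$responsive)
  expect_equal(r$window_ms, 12)
  expect_equal(r$n_shuffles, 2000)
  expect_equal(r$alpha, 0.05)
  expect_error(
    classify_responsive(df, single_pulse(), 500, 4),
    "at least 5")
})

test_that("permutation p-values are calibrated under the Poisson null", {
  prot <- null_protocol()
  resp <- vapply(1:300, function(s) {
    df <- null_cell_events(s)
    classify_responsive(df, prot, 2000, 20, seed = s + 5000)$responsive
  }, logical(1))
  # Monte-Carlo bound: alpha + 2 * binomial SE at n = 300
  expect_lte(mean(resp), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("p-value decreases with evoked-event rate", {
  prot <- single_pulse()
  p_at <- function(n_locked, seed) {
    set.seed(seed)
    spont <- data.frame(onset_ms = runif(20, 0, 500), sweep = sample(1:20, 20, TRUE))
    locked <- data.frame(onset_ms = rep(104, n_locked),
                         sweep = seq_len(n_locked))
    classify_responsive(rbind(spont, locked), prot, 500, 20,
                        seed = seed)$p_value
  }
  p_weak <- mean(vapply(1:5, function(s) p_at(3, s), numeric(1)))
  p_strong <- mean(vapply(1:5, function(s) p_at(15, s), numeric(1)))
  expect_lt(p_strong, p_weak)
})

test_that("null mean follows window * rate * n_stimuli closed form", {
  # one sweep, many uniform events: E[null count] =
  # n_events * n_windows * window / duration
  set.seed(42)
  n_ev <- 400
  df <- data.frame(onset_ms = runif(n_ev, 0, 2000), sweep = 1L)
  prot <- null_protocol()
  r <- classify_responsive(df, prot, 2000, 1, n_shuffles = 2000, seed = 9)
  expected <- n_ev * length(prot$onsets) * 12 / 2000
  expect_close(r$null_counts[["mean"]], expected, 0.05 * expected)
})

test_that("evoked/spontaneous split is one per stimulus, window half-open", {
  prot <- single_pulse()
  ev <- data.frame(onset_ms = c(105, 103, 108, 120, 50),
                   peak_ms = c(106, 104, 109, 121, 51),
                   amplitude_pa = rep(30, 5), polarity = -1,
                   sweep = c(1L, 2L, 2L, 3L, 3L), label = "unassigned",
                   onset_flagged = FALSE)
  out <- split_evoked(ev, prot)
  expect_equal(out$label[out$onset_ms == 105], "evoked")    # +5 ms
  expect_equal(out$label[out$onset_ms == 103], "evoked")    # first in window
  expect_equal(out$label[out$onset_ms == 108], "spontaneous") # second event
  expect_equal(out$label[out$onset_ms == 120], "spontaneous") # +20 ms
  expect_equal(out$label[out$onset_ms == 50], "spontaneous")
  expect_setequal(unique(out$label), c("evoked", "spontaneous"))

  # non-responsive cell: everything spontaneous
  out2 <- split_evoked(ev, prot, responsive = FALSE)
  expect_true(all(out2$label == "spontaneous"))
})

test_that("success probability is the fraction of trials with a response", {
  prot <- single_pulse()
  ev <- data.frame(onset_ms = rep(104, 4), peak_ms = rep(105, 4),
                   amplitude_pa = 30, polarity = -1, sweep = 1:4,
                   label = "evoked", onset_flagged = FALSE)
  sr <- success_record(ev, prot, n_sweeps = 10)
  expect_equal(sr$success_probability, 0.4)
  sr0 <- success_record(ev[0, ], prot, n_sweeps = 10)
  expect_equal(sr0$success_probability, 0)
})

test_that("detection recovers the programmed success probability", {
  fracs <- vapply(1:10, function(s) {
    sim <- sim_cell(s, failure = 0.3, spont = 0, n_sweeps = 40,
                    duration = 300)
    ev <- detect_events_sweepset(sim$sweeps)
    ev <- split_evoked(ev, sim$sweeps$protocol)
    success_record(ev, sim$sweeps$protocol, 40)$success_probability
  }, numeric(1))
  # binomial(40, 0.7) per seed: each within 3 SD
  expect_true(all(abs(fracs - 0.7) < 3 * sqrt(0.7 * 0.3 / 40)))
})

test_that("trains reveal connections that single pulses miss", {
  # subthreshold unitary amplitude (2x noise), 4-fold facilitation in trains
  single <- list(); train <- list()
  for (s in 1:6) {
    m1 <- synapse_model(std_shape(8), failure_prob = 0.2, spont_rate = 0.2,
                        noise_sd = 4)
    sim1 <- simulate_sweepset(m1, single_pulse(), 15, seed = s,
                              duration_ms = 400)
    ev1 <- detect_events_sweepset(sim1$sweeps)
    single[[s]] <- classify_responsive(ev1, sim1$sweeps$protocol, 400, 15,
                                       seed = s)
    m2 <- synapse_model(std_shape(8), failure_prob = 0.2, spont_rate = 0.2,
                        train_scale = c(1, 2, 3, 4, 4), noise_sd = 4)
    sim2 <- simulate_sweepset(m2, train_20hz(), 15, seed = s + 100,
                              duration_ms = 500)
    ev2 <- detect_events_sweepset(sim2$sweeps)
    train[[s]] <- classify_responsive(ev2, sim2$sweeps$protocol, 500, 15,
                                      seed = s + 100)
  }
  cs <- connection_summary(single, train)
  expect_gt(cs$prop_train, cs$prop_single)
})

test_that("connection summary arithmetic and empty cohort", {
  mk <- function(resp) structure(list(responsive = resp),
                                 class = "responsiveness_result")
  cs <- connection_summary(lapply(c(T, T, T, F, F, F, F, F, F, F), mk),
                           lapply(c(T, T, T, T, T, T, F, F, F, F), mk))
  expect_equal(cs$prop_single, 0.3)
  expect_equal(cs$prop_train, 0.6)
  cs0 <- connection_summary(list(), list())
  expect_true(is.na(cs0$prop_single))
})
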