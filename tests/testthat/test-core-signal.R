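test_that("trace and protocol constructors enforce their invariants", {
  expect_error(trace(c(1, NA, 3), 20000, "field"), "finite")
  expect_error(trace(1, 20000, "field"), "at least 2")
  expect_error(trace(1:10, -1, "field"), "positive")
  tr <- trace(1:2000, 20000, "voltage_clamped_current")
  expect_equal(trace_duration(tr), 100)
  expect_equal(trace_times(tr)[1], 0)

  expect_error(stimulus_protocol(c(10, 10), width = 1), "increasing")
  expect_error(stimulus_protocol(10, width = 0), "width")
  # train spacing must match 1000/train_rate
  expect_error(stimulus_protocol(c(100, 140), train_rate = 20),
               "train_rate")
  p <- stimulus_protocol(seq(100, 300, 50), train_rate = 20)
  expect_equal(length(p$onsets), 5)
})

test_that("sweep sets require consistent sweeps and in-range onsets", {
  t1 <- trace(rep(0, 2000), 20000, "voltage_clamped_current")
  t2 <- trace(rep(0, 1000), 20000, "voltage_clamped_current")
  expect_error(sweep_set(list(t1, t2), single_pulse(50)), "length")
  expect_error(sweep_set(list(t1), single_pulse(150)), "duration")
  s <- sweep_set(list(t1, t1), single_pulse(50))
  expect_length(s$sweeps, 2)
})

test_that("QC thresholds are class-specific", {
  expect_true(qc_pass(qc_record(-50, 20, "GC")))
  expect_false(qc_pass(qc_record(-50, 26, "GC")))      # Rs over 25 MOhm
  expect_false(qc_pass(qc_record(-150, 20, "GC")))     # leak over 100 pA
  expect_true(qc_pass(qc_record(-200, 10, "IN")))      # IN leak limit 250
  expect_false(qc_pass(qc_record(-200, 16, "IN")))     # IN Rs limit 15
  expect_true(qc_pass(qc_record(-150, 20, "GC"),
                      thresholds = list(leak_pA = 200)))
})

test_that("lowpass preserves DC and attenuates out-of-band content", {
  fs <- 20000
  const <- trace(rep(5, 4000), fs, "voltage_clamped_current")
  lp <- lowpass(const)
  expect_true(all(abs(lp$samples - 5) < 0.005))        # within 0.1%

  tt <- seq(0, 0.2, by = 1 / fs)
  hi <- trace(sin(2 * pi * 2000 * tt), fs, "voltage_clamped_current")
  out <- lowpass(hi)
  expect_lt(max(abs(out$samples[1000:3000])), 0.05)    # < 5% passes

  mix <- trace(sin(2 * pi * 10 * tt) + sin(2 * pi * 2000 * tt), fs,
               "voltage_clamped_current")
  expect_gt(cor(lowpass(mix)$samples, sin(2 * pi * 10 * tt)), 0.99)

  expect_error(lowpass(const, cutoff = fs / 2), "Nyquist")
})

test_that("lowpass is idempotent for band-limited signals", {
  fs <- 20000
  tt <- seq(0, 0.5, by = 1 / fs)
  x <- trace(3 * sin(2 * pi * 20 * tt) + sin(2 * pi * 50 * tt), fs,
             "voltage_clamped_current")
  once <- lowpass(x)
  twice <- lowpass(once)
  rel <- sqrt(mean((twice$samples - once$samples)^2)) /
    sqrt(mean(once$samples^2))
  expect_lt(rel, 0.005)
})

test_that("noise_sd matches the high-pass band's theoretical SD", {
  fs <- 20000
  # oracle: output SD of white noise through the squared-magnitude response
  # of the zero-phase 4th-order Butterworth high-pass
  bh <- signal::butter(4, 500 / (fs / 2), type = "high")
  fr <- signal::freqz(bh, n = 4096, Fs = fs)
  theo <- 4 * sqrt(mean(abs(fr$h)^4))
  est <- vapply(1:100, function(s) {
    set.seed(s)
    noise_sd(trace(rnorm(fs, sd = 4), fs, "voltage_clamped_current"))
  }, numeric(1))
  expect_lt(abs(mean(est) - theo) / theo, 0.1)

  # a noiseless slow PSC contributes almost nothing to the noise band
  w <- psc_waveform(psc_shape(100, 1, 10), duration = 1000)
  expect_lt(noise_sd(w), 2)

  z <- trace(rep(0, 2000), fs, "voltage_clamped_current")
  expect_equal(noise_sd(z), 0)
})

test_that("noise_sd ignores signal band-limited below 250 Hz", {
  fs <- 20000
  set.seed(11)
  tt <- seq(0, 1, by = 1 / fs)
  noise <- rnorm(length(tt), sd = 3)
  base <- noise_sd(trace(noise, fs, "voltage_clamped_current"))
  slow <- 50 * sin(2 * pi * 40 * tt)
  with_sig <- noise_sd(trace(noise + slow, fs, "voltage_clamped_current"))
  expect_lt(abs(with_sig - base) / base, 0.05)
})

test_that("sweep container round-trips through CSV", {
  set.seed(1)
  sweeps <- lapply(1:3, function(i)
    trace(round(rnorm(5000), 4), 20000, "voltage_clamped_current"))
  s <- sweep_set(sweeps, train_20hz(first = 20),
                 holding_potential = -70, qc = qc_record(-40, 15, "GC"))
  path <- file.path(tempdir(), "sw.csv")
  write_sweepset(s, path)
  r <- read_sweepset(path)
  expect_equal(length(r$sweeps), 3)
  expect_equal(r$sweeps[[1]]$sampling_rate, 20000)
  expect_equal(trace_duration(r$sweeps[[1]]), 250)
  for (i in 1:3)
    expect_equal(r$sweeps[[i]]$samples, s$sweeps[[i]]$samples,
                 tolerance = 1e-6)
  expect_equal(r$protocol$onsets, s$protocol$onsets)   # onsets exact
  expect_equal(length(r$protocol$onsets), 5)
  expect_equal(r$holding_potential, -70)
  expect_equal(r$qc$cell_class, "GC")
  expect_true(qc_pass(r$qc))

  # layout arithmetic: 3 sweeps of 2000 samples at 20 kHz span 100 ms
  s2 <- sweep_set(lapply(1:3, function(i)
    trace(rnorm(2000), 20000, "voltage_clamped_current")),
    single_pulse(50))
  p2 <- file.path(tempdir(), "sw2.csv")
  write_sweepset(s2, p2)
  r2 <- read_sweepset(p2)
  expect_length(r2$sweeps, 3)
  expect_equal(trace_duration(r2$sweeps[[1]]), 100)
})

test_that("malformed sweep containers raise named format errors", {
  set.seed(2)
  s <- sweep_set(list(trace(rnorm(2000), 20000, "voltage_clamped_current")),
                 single_pulse(50))
  path <- file.path(tempdir(), "bad.csv")
  write_sweepset(s, path)
  # remove the sampling-rate key from the metadata sidecar
  meta <- read.csv(sub("\\.csv$", "_meta.csv", path))
  write.csv(meta[meta$key != "sampling_rate_hz", ],
            sub("\\.csv$", "_meta.csv", path), row.names = FALSE)
  expect_error(read_sweepset(path), "sampling_rate_hz")

  expect_error(read_sweepset(file.path(tempdir(), "nope.csv")), "not found")

  write_sweepset(s, path)
  file.remove(sub("\\.csv$", "_protocol.csv", path))
  expect_error(read_sweepset(path), "sidecar")
})
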