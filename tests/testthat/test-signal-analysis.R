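test_that("low-pass filter passes the band, attenuates above cutoff, keeps DC", {
  fs <- 1e4
  t <- seq(0, 2, by = 1 / fs)
  sine10 <- counter_trace(sin(2 * pi * 10 * t), fs)
  out10 <- lowpass(sine10, 100)
  mid <- seq(5000, 15000)  # avoid edge transients
  expect_equal(max(abs(out10$samples[mid])), 1, tolerance = 0.01)

  sine500 <- counter_trace(sin(2 * pi * 500 * t), fs)
  out500 <- lowpass(sine500, 100)
  atten_db <- 20 * log10(max(abs(out500$samples[mid])))
  expect_lt(atten_db, -20)

  const <- counter_trace(rep(2.5, 1000), fs)
  expect_equal(lowpass(const, 100)$samples, rep(2.5, 1000), tolerance = 1e-4)

  expect_error(lowpass(sine10, 6000), "Nyquist")
})

test_that("peak detection recovers injected events, rejects noise, merges doublets", {
  fs <- 1e4
  events <- seq(0.5, 5.4, by = 0.1)  # 50 well-separated transits
  tr <- synthesize_trace(events, sampling_rate = fs, snr = 10, seed = 2,
                         duration = 6)
  det <- detect_peaks(lowpass(tr), threshold_sigmas = 5)
  expect_length(det, 50)
  expect_lt(max(abs(det - events)), 2e-3)  # zero-phase: times preserved

  # pure noise at 5 sigma: essentially no false positives over 10 s
  noise <- synthesize_trace(numeric(0), sampling_rate = fs, snr = 0,
                            seed = 3, duration = 10)
  expect_lte(length(detect_peaks(lowpass(noise), 5)), 1)

  # two transits closer than the refractory window count once
  close <- synthesize_trace(c(1, 1.0004), sampling_rate = fs, snr = 10,
                            seed = 4, duration = 2)
  expect_length(detect_peaks(lowpass(close), 5, min_separation = 1e-3), 1)
})

test_that("binning conserves events with right-open bin convention", {
  ev <- runif(100, 0, 10)
  expect_equal(sum(bin_counts(ev, 1)), 100)
  expect_equal(bin_counts(numeric(0), 1, t_max = 5), integer(5))
  # an event exactly on a bin edge belongs to the bin starting there
  expect_equal(bin_counts(c(1, 2), 1, t_max = 3), c(0L, 1L, 1L))
})

test_that("normalization maps the initial window to 1 and finds linear crossings", {
  flat <- normalize_and_smooth(rep(50L, 100))
  expect_equal(flat$ratio, rep(1, 100), tolerance = 1e-12)

  # counts decaying linearly to zero at t = 100: the window mean is the
  # rate at t = 10, so the normalized curve crosses 0.5 at t = 55
  lin <- normalize_and_smooth(as.integer(round(100 * (1 - (0:99) / 100))))
  expect_equal(half_life_from_curve(lin), 55, tolerance = 0.02)

  expect_error(normalize_and_smooth(rep(0L, 30)), "zero initial rate")
  expect_error(normalize_and_smooth(integer(0)), "non-empty")
})

test_that("dead-time estimator recovers a hard refractory period", {
  # Poisson train at 40/s censored with tau = 5 ms
  ev <- sample_arrivals(function(t) rep(40, length(t)), 200, seed = 8)
  keep <- c(TRUE, diff(ev) > 5e-3)
  while (!all(keep)) {          # re-censor until no gap is below tau
    ev <- ev[keep]
    keep <- c(TRUE, diff(ev) > 5e-3)
  }
  tau_hat <- estimate_dead_time(ev)
  expect_equal(tau_hat, 5e-3, tolerance = 0.25)
  # short trains are left uncorrected
  expect_identical(estimate_dead_time(ev[1:50]), 0)
})

test_that("the trace pipeline is deterministic given a trace", {
  ev <- sample_arrivals(function(t) 30 * exp(-t / 40), 80, seed = 5)
  tr <- synthesize_trace(ev, snr = 8, seed = 6, duration = 80)
  r1 <- analyze_trace(tr)
  r2 <- analyze_trace(tr)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$curve$ratio, r2$curve$ratio)
})
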