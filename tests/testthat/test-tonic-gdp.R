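test_that("Gaussian fit of the all-point histogram recovers the baseline", {
  s <- simulate_trace(sim_config(duration = 30000, rate = 0,
                                 baseline_sigma = 3, tonic_offset = -50,
                                 seed = 1))
  tr <- tonic_holding(s$trace)
  expect_equal(nrow(tr$per_window), 3L)
  expect_true(all(abs(tr$per_window$mean_pA + 50) < 0.1))
  expect_true(all(abs(tr$per_window$sd_pA - 3) < 0.2))
  expect_true(all(tr$per_window$stable))
})

test_that("one-sided fit resists contamination by synaptic events", {
  s <- simulate_trace(sim_config(duration = 30000, rate = 3,
                                 baseline_sigma = 3, tonic_offset = -50,
                                 seed = 2))
  tr <- tonic_holding(s$trace)
  expect_true(all(abs(tr$per_window$mean_pA + 50) < 0.5))
})

test_that("a noiseless constant trace gives the exact mean", {
  tr <- tonic_holding(psc_trace(rep(-42.5, 200000)))
  expect_equal(tr$per_window$mean_pA, -42.5)
})

test_that("tonic estimate flips with polarity as the fit side flips", {
  s <- simulate_trace(sim_config(duration = 10000, rate = 3,
                                 baseline_sigma = 3, tonic_offset = -50,
                                 seed = 6))
  inw <- tonic_holding(s$trace)
  flipped <- psc_trace(-s$trace$samples, dt = s$trace$dt)
  outw <- tonic_holding(flipped, polarity = "outward")
  expect_equal(outw$per_window$mean_pA, -inw$per_window$mean_pA,
               tolerance = 0.05)
})

test_that("drug shift recovers an injected outward step", {
  half <- 60000 / 0.05
  s <- simulate_trace(sim_config(duration = 120000, rate = 1,
                                 baseline_sigma = 3,
                                 tonic_offset = c(-50, 54),
                                 offset_step_time = c(0, 60000), seed = 3))
  before <- tonic_holding(psc_trace(s$trace$samples[1:half]))
  after <- tonic_holding(psc_trace(s$trace$samples[(half + 1):(2 * half)]))
  expect_equal(drug_shift(before, after), 54, tolerance = 2)
  expect_identical(drug_shift(before, before), 0)
  # no step: shift stays at noise level
  expect_lt(abs(drug_shift(
    tonic_holding(psc_trace(s$trace$samples[1:(half / 2)])),
    tonic_holding(psc_trace(s$trace$samples[(half / 2 + 1):half])))), 1)
})

test_that("unstable windows are excluded and can exhaust the estimate", {
  ramp <- psc_trace(-50 + seq(0, 40, length.out = 400000) + rnorm(400000),
                    dt = 0.05)
  tr <- tonic_holding(ramp)
  expect_false(any(tr$per_window$stable))
  expect_error(drug_shift(tr, tr), "no stable windows")
})

test_that("injected compound bursts are counted and measured", {
  set.seed(4)
  burst_times <- seq(10000, by = 19000, length.out = 10)
  quanta <- unlist(lapply(burst_times,
                          function(t) t + rexp(40, rate = 1 / 100)))
  s <- simulate_trace(sim_config(duration = 200000, rate = 0,
                                 baseline_sigma = 3,
                                 event_times = quanta, seed = 4))
  g <- detect_gdps(s$trace)
  expect_equal(nrow(g$events), 10L)
  expect_equal(g$frequency_hz, 0.05)
  expect_length(g$iei_ms, 9L)
  expect_true(all(g$events$area_pAms > 0))
  expect_true(all(g$events$offset_ms > g$events$onset_ms))
  # every detected onset sits near an injected burst
  expect_true(all(vapply(g$events$onset_ms, function(o)
    min(abs(burst_times - o)) < 500, logical(1))))
})

test_that("event-free noise contains no network events", {
  s <- simulate_trace(sim_config(duration = 30000, rate = 0,
                                 baseline_sigma = 3, seed = 5))
  g <- detect_gdps(s$trace)
  expect_equal(nrow(g$events), 0L)
  expect_equal(g$frequency_hz, 0)
  expect_error(detect_gdps(psc_trace(rnorm(1000))), "10 s")
})

test_that("burst charge scales linearly with amplitude", {
  set.seed(8)
  burst_times <- seq(10000, by = 25000, length.out = 5)
  quanta <- unlist(lapply(burst_times,
                          function(t) t + rexp(40, rate = 1 / 100)))
  s <- simulate_trace(sim_config(duration = 140000, rate = 0,
                                 baseline_sigma = 3,
                                 event_times = quanta, seed = 8))
  g1 <- detect_gdps(s$trace)
  doubled <- psc_trace(2 * s$trace$samples, dt = s$trace$dt)
  g2 <- detect_gdps(doubled)
  expect_equal(nrow(g2$events), nrow(g1$events))
  expect_equal(g2$events$area_pAms, 2 * g1$events$area_pAms,
               tolerance = 0.05)
})
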