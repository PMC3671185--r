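test_that("template peaks at the closed-form argmax with unit magnitude", {
  tmpl <- build_template(tau_rise = 0.5, tau_decay = 8, dt = 0.05,
                         baseline_pad = 0)
  expect_equal(max(abs(tmpl$samples)), 1)
  t_closed <- 0.5 * 8 / (8 - 0.5) * log(8 / 0.5)
  # fine-grid oracle for the argmax of the difference of exponentials
  tg <- seq(0, 10, by = 1e-4)
  wg <- exp(-tg / 8) - exp(-tg / 0.5)
  expect_equal(t_closed, tg[which.max(wg)], tolerance = 1e-3)
  expect_equal((which.max(abs(tmpl$samples)) - 1) * 0.05, t_closed,
               tolerance = 0.05)
})

test_that("template construction validates its arguments", {
  expect_error(build_template(tau_rise = 8, tau_decay = 0.5), "tau_rise")
  expect_error(build_template(tau_rise = 0.5, tau_decay = 8, length = 1),
               "does not reach")
  n1 <- length(build_template(dt = 0.05)$samples)
  n2 <- length(build_template(dt = 0.1)$samples)
  expect_lte(abs(n1 - 2 * n2), 2)
})

test_that("noiseless injected events are recovered exactly", {
  times <- c(500, 1500, 2700, 3600, 4800)
  tr <- inject_template_trace(times, amp = 30, duration = 6000)
  cat <- detect(tr)
  expect_equal(nrow(cat$events), 5L)
  expect_true(all(abs(cat$events$onset_ms - times) <= 0.05))
  expect_equal(cat$events$amplitude_pA, rep(30, 5), tolerance = 1e-6)
})

test_that("flat traces yield an empty catalog, not an error", {
  tr <- psc_trace(rep(-50, 20000))
  cat <- detect(tr)
  expect_s3_class(cat, "event_catalog")
  expect_equal(nrow(cat$events), 0L)
})

test_that("polarity mismatch between template and params is an error", {
  tr <- psc_trace(rnorm(20000))
  tm <- build_template(dt = 0.05, polarity = "outward")
  expect_error(detect(tr, tm, detection_params(polarity = "inward")),
               "polarity")
  expect_error(detect(psc_trace(rnorm(100)), build_template(dt = 0.05)),
               "shorter")
})

test_that("criterion is invariant to trace scaling and offset", {
  tr <- inject_template_trace(c(700, 2100, 3500), amp = 25,
                              duration = 5000, noise_sd = 2, seed = 3)
  cat0 <- detect(tr)
  tr_scaled <- psc_trace(tr$samples * 3.7, dt = tr$dt)
  tr_offset <- psc_trace(tr$samples - 120, dt = tr$dt)
  cat_s <- detect(tr_scaled)
  cat_o <- detect(tr_offset)
  expect_equal(cat_s$events$onset_ms, cat0$events$onset_ms)
  expect_equal(cat_s$events$score, cat0$events$score, tolerance = 1e-8)
  expect_equal(cat_o$events$onset_ms, cat0$events$onset_ms)
  expect_equal(cat_o$events$score, cat0$events$score, tolerance = 1e-8)
  expect_equal(cat_s$events$amplitude_pA, 3.7 * cat0$events$amplitude_pA,
               tolerance = 1e-8)
})

test_that("detection score grows monotonically with amplitude", {
  amps <- seq(6, 60, length.out = 10)
  times <- seq(500, by = 600, length.out = 10)
  tr <- inject_template_trace(times, amp = amps, duration = 7000,
                              noise_sd = 1, seed = 9)
  cat <- detect(tr)
  sc <- vapply(times, function(t) {
    j <- which.min(abs(cat$events$onset_ms - t))
    cat$events$score[j]
  }, 0)
  expect_gt(stats::cor(sc, amps, method = "spearman"), 0.9)
})

test_that("false positives on pure noise stay rare", {
  fp <- vapply(1:3, function(sd) {
    s <- simulate_trace(sim_config(duration = 50000, rate = 0,
                                   baseline_sigma = 3, seed = sd))
    nrow(detect(s$trace)$events) / 50
  }, 0)
  expect_lt(mean(fp), 0.1)
})

test_that("simulated events at 5x noise SD are found at their times", {
  hit <- unlist(lapply(21:22, function(sd) {
    cfg <- sim_config(duration = 120000, rate = 0.5, min_gap = 60,
                      p_peak = 0.16, amplitude_cv = 0, baseline_sigma = 2,
                      seed = sd)
    s <- simulate_trace(cfg)
    cat <- detect(s$trace)
    vapply(s$truth$event_times,
           function(t) any(abs(cat$events$onset_ms - t) <= 2),
           logical(1))
  }))
  expect_gte(mean(hit), 0.95)
})
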