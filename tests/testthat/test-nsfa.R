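test_that("chord conductance follows gamma = i / (Em - Erev)", {
  expect_equal(conductance(2.6, -70, 0), 1000 * 2.6 / 70)
  expect_equal(signif(conductance(2.6, -70, 0), 2), 37)
  expect_equal(conductance(0, -70, 0), 0)
  expect_equal(conductance(2.0, -70, 0), 28.57, tolerance = 1e-3)
  expect_error(conductance(2, -70, -70), "driving force")
})

test_that("stability screen rejects drifting series and passes iid ones", {
  cat <- iid_catalog(60, seed = 1)
  ev <- cat$events
  ev$amplitude_pA <- seq(20, 60, length.out = nrow(ev))  # monotone drift
  drifting <- event_catalog(ev)
  rep_d <- stability_screen(drifting)
  expect_false(rep_d$passed)
  expect_equal(rep_d$tests$amp_vs_index[["rho"]], 1)
  expect_lt(rep_d$tests$amp_vs_index[["p"]], 1e-6)
  expect_error(stability_screen(event_catalog()), "at least 10")
})

test_that("constant series are treated as stable with a warning", {
  cat <- iid_catalog(30, seed = 2)
  ev <- cat$events
  ev$amplitude_pA <- 30
  w <- capture_warnings(rep_c <- stability_screen(event_catalog(ev)))
  expect_true(any(grepl("degenerate", w)))
  expect_true(is.na(rep_c$tests$amp_vs_index[["rho"]]))
  expect_true(rep_c$passed)
})

test_that("time-stability tests reject at about the nominal rate", {
  rej <- vapply(1:50, function(sd) {
    r <- stability_screen(iid_catalog(50, seed = sd))
    r$tests$amp_vs_index[["p"]] < 0.05
  }, logical(1))
  ci <- 3 * sqrt(0.05 * 0.95 / 50)
  expect_lte(mean(rej), 0.05 + ci)
})

test_that("identical noiseless events average to a single event", {
  times <- seq(500, by = 500, length.out = 25)
  tr <- inject_template_trace(times, amp = 30, duration = 14000)
  cat <- measure_events(tr, times)
  ens <- align_and_average(tr, cat, pre = 5, post = 40)
  expect_equal(nrow(ens$waveforms), 25L)
  expect_equal(ens$mean_waveform, ens$waveforms[1, ], tolerance = 1e-9)
})

test_that("alignment removes sample jitter in the onsets", {
  base <- seq(500, by = 500, length.out = 24)
  set.seed(7)
  jit <- sample(c(-2, -1, 0, 1, 2), 24, replace = TRUE) * 0.05
  tr <- inject_template_trace(base + jit, amp = 30, duration = 13000)
  cat <- measure_events(tr, base + jit)
  ens <- align_and_average(tr, cat, pre = 5, post = 40)
  peaks <- apply(ens$waveforms, 1, which.max)
  expect_lte(diff(range(peaks)), 1)
})

test_that("failed stability blocks alignment unless overridden", {
  times <- seq(500, by = 500, length.out = 25)
  tr <- inject_template_trace(times, amp = seq(10, 58, by = 2),
                              duration = 14000)
  cat <- measure_events(tr, times)
  rep_d <- stability_screen(cat)
  expect_false(rep_d$passed)
  expect_error(align_and_average(tr, cat, stability = rep_d),
               "override")
  expect_s3_class(align_and_average(tr, cat, stability = rep_d,
                                    override = TRUE), "psc_ensemble")
})

test_that("peak-scaled NSFA recovers ground truth on aligned ensembles", {
  ens <- truth_ensemble(seed = 1, n_events = 300)
  r <- peak_scaled_nsfa(ens)
  expect_equal(r$unitary_current_i, 2.5, tolerance = 0.1)
  expect_equal(r$n_channels, 25, tolerance = 0.15)
  expect_equal(r$background_variance, 4, tolerance = 0.25)
  expect_equal(r$conductance_gamma,
               conductance(r$unitary_current_i, -70, 0))
  expect_length(r$bin_means, 50L)
  expect_equal(dim(r$fit_covariance), c(3L, 3L))
})

test_that("fitted parabola satisfies its closed-form identities", {
  r <- peak_scaled_nsfa(truth_ensemble(seed = 2, n_events = 200))
  sb2 <- r$background_variance
  iN <- r$unitary_current_i * r$n_channels
  expect_equal(nsfa_parabola(r, 0), sb2, tolerance = 1e-9)
  expect_equal(nsfa_parabola(r, iN), sb2, tolerance = 1e-9)
  apex <- nsfa_parabola(r, iN / 2)
  expect_equal(apex - sb2, r$unitary_current_i^2 * r$n_channels / 4,
               tolerance = 1e-9)
})

test_that("common amplitude scaling moves i and leaves N invariant", {
  ens <- truth_ensemble(seed = 3, n_events = 250)
  r1 <- peak_scaled_nsfa(ens)
  ens2 <- ens
  ens2$waveforms <- ens$waveforms * 2
  ens2$mean_waveform <- ens$mean_waveform * 2
  r2 <- peak_scaled_nsfa(ens2)
  expect_equal(r2$unitary_current_i / r1$unitary_current_i, 2,
               tolerance = 0.05)
  expect_equal(r2$n_channels / r1$n_channels, 1, tolerance = 0.05)
})

test_that("deterministic events carry no channel variance to fit", {
  # identical noiseless waveforms: the variance-mean curve is flat at
  # zero, there is no parabola, and the fit refuses with the table
  dt <- 0.05
  tt <- seq(-5, 50, by = dt)
  M <- ifelse(tt < 0, 0,
              30 * (exp(-pmax(tt, 0) / 8) - exp(-pmax(tt, 0) / 0.5)))
  W <- matrix(rep(M, 40), nrow = 40, byrow = TRUE)
  ens <- structure(list(waveforms = W, times = tt, mean_waveform = M,
                        events = NULL, dt = dt), class = "psc_ensemble")
  err <- tryCatch(peak_scaled_nsfa(ens), error = function(e) e)
  expect_s3_class(err, "nsfa_fit_error")
  expect_true(is.data.frame(err$table))
  v <- err$table$bin_variance
  expect_lt(max(abs(v[is.finite(v)])), 1e-12)
})

test_that("a convex variance-mean relation is a fit failure with table", {
  # noise SD growing quadratically with the mean has upward curvature:
  # no channel-count interpretation exists and the fit must refuse
  set.seed(9)
  dt <- 0.05
  tt <- seq(-5, 50, by = dt)
  M <- ifelse(tt < 0, 0, 30 * (exp(-pmax(tt, 0) / 8) -
                                 exp(-pmax(tt, 0) / 0.5)) / 0.83)
  W <- t(vapply(1:80, function(k)
    M + rnorm(length(M), 0, 0.5 + 0.01 * M^2), numeric(length(M))))
  ens <- structure(list(waveforms = W, times = tt, mean_waveform = colMeans(W),
                        events = NULL, dt = dt), class = "psc_ensemble")
  err <- tryCatch(peak_scaled_nsfa(ens), error = function(e) e)
  expect_s3_class(err, "nsfa_fit_error")
  expect_true(is.data.frame(err$table))
  expect_named(err$table, c("bin_mean", "bin_variance", "count"))
})

test_that("NSFA estimates are invariant to a DC offset in the trace", {
  gap <- 100
  times <- seq(100, by = gap, length.out = 150)
  cfg <- sim_config(duration = 150 * gap + 200, event_times = times,
                    seed = 5)
  s <- simulate_trace(cfg)
  tr0 <- s$trace
  tr1 <- psc_trace(tr0$samples - 55, dt = tr0$dt)
  c0 <- measure_events(tr0, times)
  c1 <- measure_events(tr1, times)
  r0 <- peak_scaled_nsfa(align_and_average(tr0, c0))
  r1 <- peak_scaled_nsfa(align_and_average(tr1, c1))
  expect_equal(r0$unitary_current_i, r1$unitary_current_i,
               tolerance = 1e-9)
  expect_equal(r0$n_channels, r1$n_channels, tolerance = 1e-9)
})

test_that("ensemble needs at least 20 events", {
  expect_error(peak_scaled_nsfa(truth_ensemble(seed = 6, n_events = 10)),
               "at least 20")
})
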