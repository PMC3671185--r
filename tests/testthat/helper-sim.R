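# Shared fixtures, all generated in code.

# Trace with exact template-shaped events injected on a flat baseline.
inject_template_trace <- function(times, amp, duration, dt = 0.05,
                                  tau_rise = 0.5, tau_decay = 8,
                                  noise_sd = 0, baseline = 0, seed = 1) {
  set.seed(seed)
  n <- round(duration / dt)
  tt <- seq(0, tau_decay * 10, by = dt)
  w <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  w <- w / max(w)
  x <- rep(baseline, n)
  for (j in seq_along(times)) {
    i0 <- round(times[j] / dt) + 1
    idx <- i0:min(n, i0 + length(w) - 1)
    x[idx] <- x[idx] - amp[min(j, length(amp))] * w[seq_along(idx)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  psc_trace(x, dt = dt)
}

# Ground-truth-aligned ensemble straight from the simulator (no detection),
# for isolating the fluctuation-analysis stage.
truth_ensemble <- function(seed, n_events = 300, amplitude_cv = 0.2,
                           n_channels = 25, unitary_current = 2.5,
                           baseline_sigma = 2, p_peak = 0.5,
                           pre = 5, post = 50, dt = 0.05) {
  gap <- 100
  times <- seq(100, by = gap, length.out = n_events)
  cfg <- sim_config(duration = n_events * gap + 200, dt = dt,
                    event_times = times, n_channels = n_channels,
                    unitary_current = unitary_current,
                    baseline_sigma = baseline_sigma,
                    amplitude_cv = amplitude_cv, p_peak = p_peak,
                    seed = seed)
  s <- simulate_trace(cfg)
  pre_n <- round(pre / dt); post_n <- round(post / dt)
  W <- t(vapply(times, function(t0) {
    i0 <- round(t0 / dt) + 1
    -s$trace$samples[(i0 - pre_n):(i0 + post_n)]
  }, numeric(pre_n + post_n + 1)))
  structure(list(waveforms = W, times = seq(-pre, post, by = dt),
                 mean_waveform = colMeans(W), events = NULL, dt = dt),
            class = "psc_ensemble")
}

# Catalog of i.i.d. synthetic event measures (no trace behind it).
iid_catalog <- function(n = 50, seed = 1) {
  set.seed(seed)
  ev <- data.frame(
    onset_ms = sort(runif(n, 0, 60000)),
    amplitude_pA = rlnorm(n, log(30), 0.2),
    rise_10_90_ms = runif(n, 0.3, 0.9),
    weighted_decay_ms = rlnorm(n, log(9), 0.15),
    qc_pass = TRUE)
  ev$peak_ms <- ev$onset_ms + 1
  event_catalog(ev)
}
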