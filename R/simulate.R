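#' Simulation configuration for synthetic voltage-clamp traces
#'
#' Ground-truth parameters for the stochastic channel-gating simulator.
#' Defaults describe a typical neonatal GABAergic recording: ~25 receptor
#' channels per synapse carrying ~2.5 pA each, sub-millisecond rise and
#' ~8 ms decay, quantal miniature events arriving as a Poisson train on a
#' 2 pA-noise baseline sampled at 20 kHz.
#'
#' @param duration trace length in ms.
#' @param dt sampling interval in ms (default 0.05 = 20 kHz).
#' @param rate miniature-event rate in events/s (Poisson).
#' @param n_channels number of postsynaptic channels N.
#' @param unitary_current single-channel current i in pA (magnitude).
#' @param tau_rise,tau_decay event kinetics in ms.
#' @param p_peak open probability at the waveform peak, in (0, 1].
#' @param amplitude_cv coefficient of variation of the per-event
#'   (log-normal) scaling of `p_peak`; models quantal amplitude variability.
#' @param baseline_sigma SD of additive Gaussian baseline noise, pA.
#' @param tonic_offset tonic holding-current offset(s) in pA (signed;
#'   inward negative). A scalar applies to the whole trace; a vector of the
#'   same length as `offset_step_time` applies each offset additively from
#'   its step time onward (mimicking sequential drug applications).
#' @param offset_step_time time(s) in ms at which the corresponding
#'   `tonic_offset` entries switch on, or `NULL` for a constant offset.
#' @param gdp_rate rate of compound network bursts (events/s), 0 for none.
#' @param gdp_n_quanta number of quantal events summed per burst.
#' @param gdp_envelope_tau time constant (ms) of the exponential onset
#'   jitter spreading a burst's quanta.
#' @param min_gap optional refractory gap in ms enforced between miniature
#'   onsets (0 = allow overlap).
#' @param event_times optional explicit onset times in ms; overrides the
#'   Poisson train (useful for deterministic tests).
#' @param holding_potential holding potential recorded in the trace
#'   metadata, mV.
#' @param seed integer RNG seed; identical seed + config give an identical
#'   trace.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration = 60000, dt = 0.05, rate = 0.5,
                       n_channels = 25, unitary_current = 2.5,
                       tau_rise = 0.3, tau_decay = 8, p_peak = 0.5,
                       amplitude_cv = 0.2, baseline_sigma = 2,
                       tonic_offset = 0, offset_step_time = NULL,
                       gdp_rate = 0, gdp_n_quanta = 40,
                       gdp_envelope_tau = 100, min_gap = 0,
                       event_times = NULL, holding_potential = -70,
                       seed = 1L) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (p_peak <= 0 || p_peak > 1)
    stop("`p_peak` must lie in (0, 1]", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (n_channels < 1) stop("`n_channels` must be >= 1", call. = FALSE)
  if (!is.null(offset_step_time) &&
      length(offset_step_time) != length(tonic_offset))
    stop("`tonic_offset` and `offset_step_time` must have equal length",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# Unit-peak difference-of-exponentials waveform on the sample grid.
# Normalised by the *sampled* maximum so the peak sample is exactly 1.
quantal_kernel <- function(tau_rise, tau_decay, dt, tail_frac = 1e-4) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  t_end <- tau_decay * log(1 / tail_frac)
  tt <- seq(0, t_end, by = dt)
  w <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  w / max(w)
}

#' Simulate a voltage-clamp trace with known ground truth
#'
#' Each miniature event at time \eqn{t_k} contributes an open-probability
#' time course \eqn{p_k(t) = s_k\,p_{peak}\,w(t - t_k)} with \eqn{w} a
#' unit-peak difference of exponentials and \eqn{s_k} a log-normal per-event
#' scale (CV = `amplitude_cv`, clipped so \eqn{s_k p_{peak} \le 1}).
#' Probabilities of overlapping events add and are clipped at 1. At every
#' sample each of the N channels opens independently with probability
#' \eqn{p(t)} (a Binomial draw), contributing `unitary_current` pA of inward
#' current; Gaussian noise and the tonic offset(s) are added on top. By
#' construction the ensemble variance of the channel current obeys the
#' parabolic variance-mean relation \eqn{\sigma^2(I) = iI - I^2/N +
#' \sigma_b^2} at every time point, which is what non-stationary fluctuation
#' analysis estimates.
#'
#' Compound network bursts (GDP-like events) are phenomenological: each
#' burst sums `gdp_n_quanta` quantal events whose onsets are exponentially
#' jittered with time constant `gdp_envelope_tau` after the burst time.
#'
#' @param config a [sim_config()].
#' @return a list with components `trace` (a [psc_trace()]) and `truth` (a list
#'   with `event_times`, `per_event_scale`, `gdp_times` and the `config`).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed %% .Machine$integer.max)
  n <- round(cfg$duration / cfg$dt)
  if (n < 2L) stop("duration too short for the sampling interval",
                   call. = FALSE)

  if (cfg$p_peak * (1 + 5 * cfg$amplitude_cv) > 1)
    warning("p_peak * (1 + 5 * amplitude_cv) exceeds 1; ",
            "per-event open probabilities will be clipped at 1",
            call. = FALSE)

  kern <- quantal_kernel(cfg$tau_rise, cfg$tau_decay, cfg$dt)
  # expected time-average open probability; > 1 means the event density is
  # physically impossible for a finite channel pool
  mean_p <- cfg$rate / 1000 * cfg$p_peak * sum(kern) * cfg$dt
  if (mean_p > 1)
    stop("event rate and kinetics imply mean open probability > 1",
         call. = FALSE)

  # miniature-event onsets: Poisson train, optional refractory thinning
  if (!is.null(cfg$event_times)) {
    ev <- sort(as.numeric(cfg$event_times))
  } else {
    n_ev <- stats::rpois(1L, cfg$rate * cfg$duration / 1000)
    ev <- sort(stats::runif(n_ev, 0, cfg$duration))
    if (cfg$min_gap > 0 && length(ev) > 1L) {
      keep <- c(TRUE, diff(ev) >= cfg$min_gap)
      while (!all(keep)) {
        ev <- ev[keep]
        keep <- c(TRUE, diff(ev) >= cfg$min_gap)
      }
    }
  }

  draw_scales <- function(k) {
    if (cfg$amplitude_cv <= 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + cfg$amplitude_cv^2))
    s <- stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    pmin(s, 1 / cfg$p_peak)
  }
  scales <- draw_scales(length(ev))

  # GDP-like bursts: sums of jittered quanta under an exponential envelope
  gdp_times <- numeric(0)
  gdp_onsets <- numeric(0)
  gdp_scales <- numeric(0)
  if (cfg$gdp_rate > 0) {
    n_gdp <- stats::rpois(1L, cfg$gdp_rate * cfg$duration / 1000)
    gdp_times <- sort(stats::runif(n_gdp, 0, cfg$duration))
    for (tg in gdp_times) {
      jit <- stats::rexp(cfg$gdp_n_quanta, rate = 1 / cfg$gdp_envelope_tau)
      gdp_onsets <- c(gdp_onsets, tg + jit)
    }
    gdp_scales <- draw_scales(length(gdp_onsets))
  }

  p <- numeric(n)
  add_event <- function(t_k, s_k) {
    i0 <- floor(t_k / cfg$dt) + 1
    if (i0 > n) return(invisible())
    idx <- i0:min(n, i0 + length(kern) - 1L)
    p[idx] <<- p[idx] + s_k * cfg$p_peak * kern[seq_along(idx)]
    invisible()
  }
  if (length(ev))
    for (k in seq_along(ev)) add_event(ev[k], scales[k])
  if (length(gdp_onsets))
    for (k in seq_along(gdp_onsets)) add_event(gdp_onsets[k], gdp_scales[k])
  p <- pmin(p, 1)

  n_open <- if (any(p > 0)) stats::rbinom(n, cfg$n_channels, p) else
    integer(n)
  current <- -n_open * cfg$unitary_current
  if (cfg$baseline_sigma > 0)
    current <- current + stats::rnorm(n, 0, cfg$baseline_sigma)

  if (is.null(cfg$offset_step_time)) {
    current <- current + sum(cfg$tonic_offset)
  } else {
    tt <- (seq_len(n) - 1) * cfg$dt
    for (k in seq_along(cfg$tonic_offset))
      current <- current +
        cfg$tonic_offset[k] * (tt >= cfg$offset_step_time[k])
  }

  tr <- psc_trace(current, dt = cfg$dt,
              holding_potential = cfg$holding_potential,
              channel_label = "simulated", condition = "simulated")
  list(trace = tr,
       truth = list(event_times = ev, per_event_scale = scales,
                    gdp_times = gdp_times, config = cfg))
}

#' Simulate a labelled cohort of cells
#'
#' Writes one trace bundle per (label, config) pair, with the group label in
#' the trace metadata. Deterministic given the per-config seeds.
#'
#' @param configs named list of [sim_config()] objects; names are the cell /
#'   group labels and must be unique.
#' @param dir output directory (created if needed).
#' @return named character vector of bundle paths; ground truths are
#'   attached as the `"truth"` attribute.
#' @export
simulate_cohort <- function(configs, dir) {
  if (length(configs) < 1L) stop("need at least one config", call. = FALSE)
  labs <- names(configs)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
    stop("configs must be uniquely labelled", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- vector("list", length(configs))
  paths <- character(length(configs))
  for (k in seq_along(configs)) {
    sim <- simulate_trace(configs[[k]])
    sim$trace$condition <- labs[k]
    sim$trace$channel_label <- labs[k]
    paths[k] <- file.path(dir, paste0(labs[k], ".json"))
    write_trace(sim$trace, paths[k])
    truths[[k]] <- sim$truth
  }
  names(paths) <- labs
  names(truths) <- labs
  attr(paths, "truth") <- truths
  paths
}
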