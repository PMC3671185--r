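#' Kinetic-measurement parameters
#'
#' @param baseline_window pre-onset window used for the baseline mean and
#'   its SD, ms.
#' @param max_rise_qc QC cut-off on the 10-90% rise time, ms. Events rising
#'   more slowly are flagged `qc_pass = FALSE`: slow rise indicates
#'   electrotonic (cable) filtering that distorts amplitude and kinetics.
#' @param min_rise_qc lower QC bound on the rise time, ms. An apparent rise
#'   much faster than the acquisition low-pass filter permits (about
#'   0.35/f_c for a cut-off f_c in kHz) cannot be synaptic and marks a
#'   noise artefact.
#' @param charge_window cap on the post-onset charge-integration window, ms.
#' @param peak_search window after the onset searched for the peak, ms.
#' @param interpolate linearly interpolate the 10% / 90% crossings between
#'   samples (recommended: at 20 kHz, sample quantisation would otherwise
#'   dominate sub-millisecond rise times).
#' @param fit_decay also fit a mono-exponential decay time constant
#'   (log-linear fit from the peak down to 20% of the peak).
#' @return an object of class `kinetics_params`.
#' @export
kinetics_params <- function(baseline_window = 5, max_rise_qc = 1,
                            min_rise_qc = 0.1, charge_window = 100,
                            peak_search = 10, interpolate = TRUE,
                            fit_decay = FALSE) {
  if (baseline_window <= 0) stop("`baseline_window` must be positive",
                                 call. = FALSE)
  if (max_rise_qc <= 0) stop("`max_rise_qc` must be positive",
                             call. = FALSE)
  structure(list(baseline_window = baseline_window,
                 max_rise_qc = max_rise_qc, min_rise_qc = min_rise_qc,
                 charge_window = charge_window,
                 peak_search = peak_search, interpolate = interpolate,
                 fit_decay = fit_decay),
            class = "kinetics_params")
}

#' Measure amplitude and kinetics of a single event
#'
#' Baseline is the mean current over `baseline_window` before the onset.
#' The peak is the extreme of the baseline-subtracted current within
#' `peak_search` after the onset (reported as a positive magnitude). The
#' rise time is the 10-90% time on the rising phase, with the crossings
#' linearly interpolated between samples. Charge transfer is the
#' trapezoidal integral of the baseline-subtracted current from onset to
#' the first post-peak return to within one baseline-SD of baseline, capped
#' at `charge_window`. The weighted decay is charge divided by amplitude;
#' for a mono-exponential current it equals the decay time constant.
#' Events failing the rise-time QC (or with no resolvable peak or
#' non-positive charge) are returned with `qc_pass = FALSE` rather than
#' dropped.
#'
#' @param x a [psc_trace()].
#' @param onset event onset time, ms (must leave a full baseline window
#'   before it).
#' @param params a [kinetics_params()].
#' @param polarity `"inward"` or `"outward"`.
#' @return a one-row data.frame with the [event_catalog()] columns.
#' @export
measure_event <- function(x, onset, params = kinetics_params(),
                          polarity = c("inward", "outward")) {
  stopifnot(inherits(x, "trace"), inherits(params, "kinetics_params"))
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "inward") -1 else 1
  dt <- x$dt
  n <- length(x$samples)
  idx_on <- round((onset - x$t0) / dt) + 1L
  bw_n <- round(params$baseline_window / dt)
  if (idx_on - bw_n < 1L || idx_on > n)
    stop("onset leaves no room for the baseline window", call. = FALSE)

  bidx <- (idx_on - bw_n):(idx_on - 1L)
  baseline <- mean(x$samples[bidx])
  sigma_b <- stats::sd(x$samples[bidx])

  ps_n <- min(round(params$peak_search / dt), n - idx_on)
  mseg <- sgn * (x$samples[idx_on:(idx_on + ps_n)] - baseline)
  # raw extreme within the search window; on unfiltered noisy data this
  # carries the extreme-value bias of the noise (see the vignette)
  pk_rel <- which.max(mseg)
  amp <- mseg[pk_rel]
  peak_idx <- idx_on + pk_rel - 1L
  peak_ms <- x$t0 + (peak_idx - 1L) * dt
  peak_found <- amp > 0 && pk_rel < length(mseg)

  out <- data.frame(onset_ms = onset, peak_ms = peak_ms,
                    amplitude_pA = max(amp, 0), baseline_pA = baseline,
                    rise_10_90_ms = NA_real_, charge_pAms = NA_real_,
                    weighted_decay_ms = NA_real_, decay_tau_ms = NA_real_,
                    score = NA_real_, qc_pass = FALSE)
  if (!peak_found) return(out)

  # rising phase, with one pre-onset sample so step-like rises interpolate
  r0 <- max(1L, idx_on - 1L)
  rise_seg <- sgn * (x$samples[r0:peak_idx] - baseline)
  rise_t <- x$t0 + (seq(r0, peak_idx) - 1L) * dt
  # 90%: first upward crossing; 10%: last upward crossing before it.
  # (The last-90 / first-10 alternatives are noise-inflated.)
  up <- which(rise_seg[-length(rise_seg)] <= 0.9 * amp &
                rise_seg[-1L] > 0.9 * amp)
  cross_at <- function(j, level) {
    if (!params$interpolate) return(rise_t[j + 1L])
    frac <- (level - rise_seg[j]) / (rise_seg[j + 1L] - rise_seg[j])
    rise_t[j] + frac * dt
  }
  if (length(up)) {
    j90 <- up[1L]
    lo10 <- which(rise_seg[-length(rise_seg)] <= 0.1 * amp &
                    rise_seg[-1L] > 0.1 * amp)
    lo10 <- lo10[lo10 <= j90]
    t90 <- cross_at(j90, 0.9 * amp)
    t10 <- if (length(lo10)) cross_at(max(lo10), 0.1 * amp) else rise_t[1L]
  } else {
    t90 <- rise_t[length(rise_t)]
    t10 <- rise_t[1L]
  }
  rise <- max(t90 - t10, dt / 100)

  # charge: onset -> first post-peak *sustained* return to within 1 SD of
  # baseline (0.25 ms-smoothed magnitude staying below for >= 0.5 ms; a
  # single noisy sample dipping through baseline must not truncate the
  # integral), capped at charge_window
  cw_n <- min(round(params$charge_window / dt), n - idx_on)
  cseg <- sgn * (x$samples[idx_on:(idx_on + cw_n)] - baseline)
  sm_n <- max(1L, round(0.25 / dt))
  csm <- as.numeric(stats::filter(cseg, rep(1 / sm_n, sm_n), sides = 2))
  csm[!is.finite(csm)] <- Inf
  run_n <- max(1L, round(0.5 / dt))
  post_below <- csm[pk_rel:length(cseg)] <= max(sigma_b, 0, na.rm = TRUE)
  r <- rle(post_below)
  hit <- which(r$values & r$lengths >= run_n)
  end_rel <- if (length(hit)) {
    pk_rel + (cumsum(r$lengths) - r$lengths + 1L)[hit[1L]] - 1L
  } else length(cseg)
  charge <- pracma::trapz(seq_len(end_rel) * dt, cseg[seq_len(end_rel)])
  integ_end <- onset + end_rel * dt

  tau <- NA_real_
  if (params$fit_decay) {
    dseg <- cseg[pk_rel:end_rel]
    keep <- which(dseg >= 0.2 * amp)
    if (length(keep) >= 3L) {
      tt <- (keep - 1L) * dt
      fit <- stats::lm.fit(cbind(1, tt), log(dseg[keep]))
      if (fit$coefficients[2L] < 0) tau <- -1 / fit$coefficients[2L]
    }
  }

  out$rise_10_90_ms <- rise
  out$charge_pAms <- charge
  out$weighted_decay_ms <- if (charge > 0) charge / amp else NA_real_
  out$decay_tau_ms <- tau
  out$qc_pass <- isTRUE(rise <= params$max_rise_qc) &&
    isTRUE(rise >= params$min_rise_qc) && charge > 0
  attr(out, "integration_end") <- integ_end
  out
}

#' Measure a set of onsets into an event catalog
#'
#' Applies [measure_event()] to each onset. An event whose baseline window
#' overlaps the previous event's integration window is flagged
#' `qc_pass = FALSE` (contaminated baseline) rather than baseline-corrected.
#'
#' @param x a [psc_trace()].
#' @param onsets event onset times, ms.
#' @param params a [kinetics_params()].
#' @param polarity event polarity.
#' @return an [event_catalog()].
#' @export
measure_events <- function(x, onsets, params = kinetics_params(),
                           polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  onsets <- sort(onsets)
  rows <- list()
  prev_end <- -Inf
  for (on in onsets) {
    row <- tryCatch(measure_event(x, on, params, polarity),
                    error = function(e) NULL)
    if (is.null(row)) next
    if (on - params$baseline_window < prev_end) row$qc_pass <- FALSE
    prev_end <- attr(row, "integration_end") %||% row$peak_ms
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(event_catalog(NULL, x$channel_label))
  event_catalog(do.call(rbind, rows), x$channel_label)
}

#' Summary statistics of an event catalog
#'
#' @param catalog an [event_catalog()].
#' @param duration_ms recording duration in ms (needed for the frequency).
#' @return a list with `n_events`, `frequency_hz` (events/s), the
#'   inter-event-interval and amplitude vectors, and a `summary` data.frame
#'   of mean and SEM for amplitude, IEI, rise time and weighted decay.
#' @export
catalog_statistics <- function(catalog, duration_ms) {
  stopifnot(inherits(catalog, "event_catalog"))
  ev <- catalog$events
  n <- nrow(ev)
  if (n == 0L)
    return(list(n_events = 0L, frequency_hz = 0, iei_ms = numeric(0),
                amplitude_pA = numeric(0), summary = NULL))
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  iei <- diff(ev$onset_ms)
  meas <- list(amplitude_pA = ev$amplitude_pA, iei_ms = iei,
               rise_10_90_ms = ev$rise_10_90_ms,
               weighted_decay_ms = ev$weighted_decay_ms)
  list(n_events = n,
       frequency_hz = n / (duration_ms / 1000),
       iei_ms = iei,
       amplitude_pA = ev$amplitude_pA,
       summary = data.frame(
         measure = names(meas),
         mean = vapply(meas, function(v) mean(v[is.finite(v)]), 0),
         sem = vapply(meas, sem, 0),
         row.names = NULL))
}

#' Evoked AMPA/NMDA current pair
#'
#' Peak magnitudes of the AMPA-mediated component (recorded at -65 mV) and
#' of the NMDA-mediated component (same neuron at +40 mV after AMPA block),
#' plus the NMDA current area for the weighted decay.
#'
#' @param ampa_peak AMPA peak magnitude, pA.
#' @param nmda_peak NMDA peak magnitude, pA.
#' @param nmda_area NMDA current area, pA*ms.
#' @return an object of class `evoked_pair`.
#' @export
evoked_pair <- function(ampa_peak, nmda_peak, nmda_area = NA_real_) {
  if (ampa_peak < 0 || nmda_peak < 0)
    stop("peaks are magnitudes and must be >= 0", call. = FALSE)
  structure(list(ampa_peak = ampa_peak, nmda_peak = nmda_peak,
                 nmda_area = nmda_area), class = "evoked_pair")
}

#' NMDA/AMPA ratio and NMDA weighted decay
#'
#' The ratio is the NMDA peak divided by the AMPA peak; the NMDA weighted
#' decay is the current area divided by its peak amplitude, independently
#' of any exponential fitting.
#'
#' @param pair an [evoked_pair()].
#' @return list with `ratio` and `nmda_weighted_decay_ms`.
#' @export
nmda_ampa_ratio <- function(pair) {
  stopifnot(inherits(pair, "evoked_pair"))
  if (pair$ampa_peak <= 0)
    stop("NMDA/AMPA ratio is undefined for a zero AMPA peak",
         call. = FALSE)
  list(ratio = pair$nmda_peak / pair$ampa_peak,
       nmda_weighted_decay_ms =
         if (is.finite(pair$nmda_area) && pair$nmda_peak > 0)
           pair$nmda_area / pair$nmda_peak else NA_real_)
}
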