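#' Build a sliding-detection template
#'
#' The template is a difference-of-exponentials waveform
#' \eqn{w(t) = \exp(-t/\tau_d) - \exp(-t/\tau_r)} normalised to unit peak
#' magnitude, preceded by `baseline_pad` ms of zeros that anchor the offset
#' term of the sliding fit. For an inward event the template is
#' negative-going (peak value -1).
#'
#' @param tau_rise,tau_decay template kinetics in ms; `tau_decay` must
#'   exceed `tau_rise`. Defaults (0.5 / 8 ms) match the kinetics scale of
#'   neonatal GABAergic miniature currents.
#' @param length template length in ms, excluding the baseline pad; must at
#'   least reach the waveform peak, and >= 5 `tau_decay` is recommended.
#' @param dt sampling interval in ms.
#' @param baseline_pad leading baseline stretch in ms.
#' @param polarity `"inward"` (negative-going, the default) or `"outward"`.
#' @return an object of class `psc_template`.
#' @export
build_template <- function(tau_rise = 0.5, tau_decay = 8, length = 40,
                           dt = 0.05, baseline_pad = 2,
                           polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  if (length < t_peak)
    stop("template length ", length, " ms does not reach the waveform ",
         "peak at ", signif(t_peak, 4), " ms", call. = FALSE)
  tt <- seq(0, length, by = dt)
  w <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  w <- w / max(w)
  if (polarity == "inward") w <- -w
  structure(
    list(samples = c(numeric(round(baseline_pad / dt)), w),
         tau_rise = tau_rise, tau_decay = tau_decay, length = length,
         baseline_pad = baseline_pad, dt = dt, polarity = polarity,
         t_peak = t_peak),
    class = "psc_template")
}

#' Detection parameters for the sliding-template matcher
#'
#' @param criterion_threshold detection-criterion threshold (dimensionless;
#'   the classic default is 4).
#' @param refractory minimum separation between accepted events, ms.
#' @param peak_search_window window after the onset searched for the event
#'   peak, ms.
#' @param rearm_fraction after an event, the detector re-arms only once
#'   the criterion has fallen below `rearm_fraction *
#'   criterion_threshold`. Along the slow decay of a large event the
#'   criterion hovers near threshold and would otherwise retrigger on
#'   noise; a 0.5 re-arm level is the usual hysteresis cure.
#' @param polarity expected event polarity, `"inward"` or `"outward"`.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(criterion_threshold = 4, refractory = 5,
                             peak_search_window = 10,
                             rearm_fraction = 0.5,
                             polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (criterion_threshold <= 0)
    stop("`criterion_threshold` must be positive", call. = FALSE)
  if (rearm_fraction < 0 || rearm_fraction > 1)
    stop("`rearm_fraction` must lie in [0, 1]", call. = FALSE)
  structure(list(criterion_threshold = criterion_threshold,
                 refractory = refractory,
                 peak_search_window = peak_search_window,
                 rearm_fraction = rearm_fraction,
                 polarity = polarity),
            class = "detection_params")
}

# Sliding optimally-scaled template fit. At every one-sample offset k the
# window D is fitted by least squares to s * T + c; the detection criterion
# is the Clements-Bekkers statistic s / SE(s), SE(s) being the regression
# standard error of the fitted scale. Dimensionless, hence invariant to
# multiplying or offsetting the trace.
sliding_criterion <- function(d, tmpl) {
  m <- length(tmpl)
  n <- length(d)
  if (n <= m) stop("trace shorter than the template", call. = FALSE)
  st <- sum(tmpl)
  stt <- sum(tmpl^2)
  sxx <- stt - st^2 / m          # sum of squared template deviations
  csd <- c(0, cumsum(d))
  csd2 <- c(0, cumsum(d^2))
  nk <- n - m + 1L
  sd_k <- csd[(m + 1):(n + 1)] - csd[1:nk]
  sdd_k <- csd2[(m + 1):(n + 1)] - csd2[1:nk]
  # sliding dot product via FFT cross-correlation, padded to a
  # 2-3-5-smooth length (arbitrary lengths can factor badly)
  L <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  fd <- stats::fft(c(d, numeric(L - n)))
  ft <- stats::fft(c(tmpl, numeric(L - m)))
  std_k <- Re(stats::fft(fd * Conj(ft), inverse = TRUE))[1:nk] / L
  s <- (std_k - st * sd_k / m) / sxx
  cc <- (sd_k - s * st) / m
  sse <- sdd_k + s^2 * stt + cc^2 * m -
    2 * s * std_k - 2 * cc * sd_k + 2 * s * cc * st
  sse <- pmax(sse, 0)
  se <- sqrt(sse / (m - 2) / sxx)
  dc <- ifelse(se > 0, s / se, 0)
  dc[!is.finite(dc)] <- 0
  list(scale = s, criterion = dc)
}

#' Detect miniature events by optimally-scaled sliding-template matching
#'
#' The template is moved along the trace one sample at a time and optimally
#' scaled (with a free offset) to fit the data at each position; the
#' detection criterion at each position is the fitted scale divided by its
#' standard error. Local maxima of the criterion above
#' `criterion_threshold`, separated by at least the refractory period
#' (larger criterion wins, earlier event on ties), become events. Each
#' event's onset is refined to the last pre-peak baseline crossing and its
#' kinetics are measured with [measure_event()].
#'
#' @param x a [psc_trace()].
#' @param template a [build_template()]; its `dt` must match the trace.
#' @param params a [detection_params()].
#' @param kinetics a [kinetics_params()] used to measure the detected
#'   events.
#' @return an [event_catalog()] sorted by onset time; empty when nothing
#'   crosses the criterion (an all-flat trace is not an error).
#' @export
detect <- function(x, template = build_template(dt = x$dt),
                   params = detection_params(),
                   kinetics = kinetics_params()) {
  stopifnot(inherits(x, "trace"), inherits(template, "psc_template"),
            inherits(params, "detection_params"))
  if (abs(template$dt - x$dt) > 1e-9)
    stop("template dt does not match the trace", call. = FALSE)
  if (template$polarity != params$polarity)
    stop("template polarity (", template$polarity,
         ") does not match detection params (", params$polarity, ")",
         call. = FALSE)

  sc <- sliding_criterion(x$samples, template$samples)
  dc <- sc$criterion
  thr <- params$criterion_threshold
  nk <- length(dc)

  # one candidate per excursion above the re-arm level that reaches the
  # threshold (hysteresis: the criterion must fall below rearm_fraction *
  # threshold before a new event can start; it hovers near threshold
  # along the decay of a large event, which must not retrigger), placed
  # at the excursion's criterion maximum
  r <- rle(dc > params$rearm_fraction * thr)
  r_end <- cumsum(r$lengths)
  r_start <- r_end - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs))
    return(event_catalog(NULL, x$channel_label, as.list(params)))
  cand <- vapply(runs, function(j) {
    idx <- r_start[j]:r_end[j]
    idx[which.max(dc[idx])]
  }, 0L)
  cand <- cand[dc[cand] > thr]
  if (!length(cand))
    return(event_catalog(NULL, x$channel_label, as.list(params)))

  # refractory suppression: greedy keep-larger (earlier wins ties)
  ref_n <- round(params$refractory / x$dt)
  ord <- cand[order(-dc[cand], cand)]
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) || all(abs(accepted - k) >= ref_n))
      accepted <- c(accepted, k)
  }
  accepted <- sort(accepted)

  pad_n <- round(template$baseline_pad / x$dt)
  bw_n <- round(kinetics$baseline_window / x$dt)
  ps_n <- round(params$peak_search_window / x$dt)
  sgn <- if (params$polarity == "inward") -1 else 1
  n <- length(x$samples)

  # peak localisation for onset refinement runs on a lightly smoothed
  # magnitude (0.25 ms boxcar): for small events a raw-noise spike later
  # in the decay can masquerade as the peak and drag the onset with it
  sm_n <- max(1L, round(0.25 / x$dt))
  box <- rep(1 / sm_n, sm_n)

  rows <- list()
  prev_end <- -Inf
  for (k in accepted) {
    nominal <- k + pad_n                      # template event-start sample
    if (nominal - bw_n - sm_n < 1L || nominal + ps_n > n) next
    bl <- mean(x$samples[(nominal - bw_n):(nominal - 1L)])
    # a little pre-context so the onset walk-back can cross the baseline
    # even when the criterion argmax lands just past the true onset
    seg0 <- nominal - sm_n
    mseg <- sgn * (x$samples[seg0:(nominal + ps_n)] - bl)
    msm <- as.numeric(stats::filter(mseg, box, sides = 2))
    msm[!is.finite(msm)] <- -Inf
    pk_rel <- which.max(msm)
    # onset: last pre-peak baseline crossing of the smoothed magnitude
    # (raw crossings can jump to noise dips mid-decay), then advanced on
    # the raw segment by at most the boxcar width to undo the smear
    pre_s <- which(msm[seq_len(pk_rel)] <= 0)
    j_s <- if (length(pre_s)) max(pre_s) else 1L
    win <- j_s:min(pk_rel, j_s + sm_n)
    raw_le <- win[mseg[win] <= 0]
    onset_rel <- if (length(raw_le)) max(raw_le) else j_s
    onset_idx <- seg0 + onset_rel - 1L
    onset_ms <- x$t0 + (onset_idx - 1L) * x$dt
    row <- tryCatch(
      measure_event(x, onset_ms, kinetics, polarity = params$polarity),
      error = function(e) NULL)
    if (is.null(row)) next
    row$score <- dc[k]
    if (onset_ms - kinetics$baseline_window < prev_end)
      row$qc_pass <- FALSE                    # contaminated baseline
    prev_end <- max(prev_end, attr(row, "integration_end") %||% row$peak_ms)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    return(event_catalog(NULL, x$channel_label, as.list(params)))
  ev <- do.call(rbind, rows)
  # events that refined onto the same onset collapse to the best-scoring one
  ev <- ev[order(ev$onset_ms, -ev$score), , drop = FALSE]
  ev <- ev[!duplicated(ev$onset_ms), , drop = FALSE]
  event_catalog(ev, x$channel_label, as.list(params))
}
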