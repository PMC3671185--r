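#' Tonic holding current from all-point histograms
#'
#' The trace is cut into windows (10 s by default); each window's raw
#' samples are accumulated into an all-point histogram that is fitted with
#' a Gaussian, whose peak is taken as the mean holding current. Synaptic
#' events skew the histogram towards the event polarity, so the Gaussian
#' is fitted only to the event-free side of the mode (bins at or above the
#' mode for inward events) and mirrored. Windows with a baseline drift
#' larger than `drift_limit` across the window, or whose fit fails, are
#' flagged and excluded from downstream shift estimates.
#'
#' @param x a [psc_trace()].
#' @param window window length in s (default 10).
#' @param polarity polarity of contaminating synaptic events.
#' @param bin_width histogram bin width in pA, or `NULL` for
#'   max(0.2, Freedman-Diaconis).
#' @param drift_limit maximum absolute linear drift across a window for it
#'   to count as stable, pA.
#' @return an object of class `tonic_result`: data.frame `per_window` with
#'   `t_start_ms`, `mean_pA`, `sd_pA`, `rmse`, `stable`, plus the window
#'   length and the trace condition label.
#' @export
tonic_holding <- function(x, window = 10,
                          polarity = c("inward", "outward"),
                          bin_width = NULL, drift_limit = 2) {
  stopifnot(inherits(x, "trace"))
  polarity <- match.arg(polarity)
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  win_n <- round(window * 1000 / x$dt)
  n_win <- floor(length(x$samples) / win_n)
  if (n_win < 1L)
    stop("trace shorter than one analysis window", call. = FALSE)

  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    seg <- x$samples[((w - 1L) * win_n + 1L):(w * win_n)]
    t_start <- x$t0 + (w - 1L) * win_n * x$dt

    # stability: linear drift across the window
    ii <- seq_along(seg)
    slope <- stats::cov(ii, seg) / stats::var(ii)
    drift <- abs(slope * (win_n - 1L))

    bw <- bin_width
    if (is.null(bw)) {
      fd <- 2 * stats::IQR(seg) / length(seg)^(1 / 3)
      bw <- max(0.2, fd)
    }
    fit <- fit_histogram_gaussian(seg, bw, polarity)
    rows[[w]] <- data.frame(
      t_start_ms = t_start,
      mean_pA = fit$mean, sd_pA = fit$sd, rmse = fit$rmse,
      stable = is.finite(fit$mean) && drift < drift_limit)
  }
  structure(list(per_window = do.call(rbind, rows),
                 window_length = window, condition = x$condition),
            class = "tonic_result")
}

# One-sided Gaussian fit of an all-point histogram. For inward events only
# bins at or above the mode (the event-free, less-negative side) are
# fitted; the fitted curve is symmetric, so mean and SD apply to the full
# baseline distribution.
fit_histogram_gaussian <- function(seg, bin_width, polarity) {
  rng <- range(seg)
  if (diff(rng) < bin_width) {
    # essentially constant window: histogram is a single spike
    return(list(mean = stats::median(seg), sd = bin_width / 2, rmse = 0))
  }
  breaks <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  h <- graphics::hist(seg, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  mode_idx <- which.max(counts)
  side <- if (polarity == "inward") centers >= centers[mode_idx] else
    centers <= centers[mode_idx]
  xs <- centers[side]
  ys <- counts[side]
  if (length(xs) < 4L)
    return(list(mean = NA_real_, sd = NA_real_, rmse = NA_real_))
  start <- list(A = max(ys), mu = centers[mode_idx],
                sig = max(stats::mad(seg), bin_width))
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-(xs - mu)^2 / (2 * sig^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = NA_real_, sd = NA_real_, rmse = NA_real_))
  cf <- stats::coef(fit)
  list(mean = unname(cf[["mu"]]), sd = abs(unname(cf[["sig"]])),
       rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Drug-induced shift of the holding current
#'
#' Difference of the mean holding current between two tonic estimates from
#' the same cell (after minus before), using stable windows only. With the
#' physical sign convention (inward negative) a positive shift is outward:
#' blocking a tonic inward GABA-A current with picrotoxin gives a positive
#' value, enhancing it with the GAT-1 blocker NO-711 a negative one.
#'
#' @param before,after [tonic_holding()] results for the two conditions.
#' @return shift in pA (outward positive).
#' @export
drug_shift <- function(before, after) {
  stopifnot(inherits(before, "tonic_result"),
            inherits(after, "tonic_result"))
  pick <- function(r) {
    ok <- r$per_window$stable %in% TRUE
    if (!any(ok))
      stop("no stable windows in the ",
           if (identical(r, before)) "'before'" else "'after'",
           " condition", call. = FALSE)
    mean(r$per_window$mean_pA[ok])
  }
  pick(after) - pick(before)
}

#' Detect compound network events (GDP-like bursts)
#'
#' The trace is low-pass filtered (zero-phase Butterworth), a robust
#' baseline (median) and noise scale (MAD) are taken from the filtered
#' signal, and contiguous excursions beyond `threshold_sd` times the noise
#' scale lasting at least `min_duration` become events. Event boundaries
#' are extended outward to the surrounding baseline crossings so that the
#' measured charge covers the whole burst; overlapping extended regions
#' are merged. Per event the charge (trapezoidal integral of the
#' baseline-subtracted raw current) and peak magnitude are returned.
#'
#' @param x a [psc_trace()] of at least 10 s.
#' @param lowpass_cutoff low-pass corner frequency, Hz (default 20).
#' @param threshold_sd detection threshold in robust SDs (default 4).
#' @param min_duration minimum excursion duration, ms (default 100).
#' @param merge_gap excursions separated by less than this gap, ms, are
#'   counted as one compound event (a burst's quanta can briefly dip the
#'   low-passed current back to baseline).
#' @param polarity burst polarity (inward for immature-network GDP currents
#'   recorded under voltage clamp).
#' @return a list with `events` (data.frame `onset_ms`, `offset_ms`,
#'   `area_pAms`, `peak_pA`), `iei_ms`, and `frequency_hz`.
#' @export
detect_gdps <- function(x, lowpass_cutoff = 20, threshold_sd = 4,
                        min_duration = 100, merge_gap = 200,
                        polarity = c("inward", "outward")) {
  stopifnot(inherits(x, "trace"))
  polarity <- match.arg(polarity)
  if (trace_duration(x) < 10000)
    stop("GDP detection needs at least 10 s of trace", call. = FALSE)
  fs <- 1000 / x$dt
  bf <- signal::butter(2, lowpass_cutoff / (fs / 2), type = "low")
  filt <- as.numeric(signal::filtfilt(bf, x$samples))
  sgn <- if (polarity == "inward") -1 else 1
  m <- sgn * (filt - stats::median(filt))
  noise <- stats::mad(m)
  thr <- threshold_sd * noise

  above <- m > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths * x$dt >= min_duration)
  empty <- list(events = data.frame(onset_ms = numeric(0),
                                    offset_ms = numeric(0),
                                    area_pAms = numeric(0),
                                    peak_pA = numeric(0)),
                iei_ms = numeric(0), frequency_hz = 0)
  if (!length(cand)) return(empty)

  # extend each excursion to the surrounding baseline crossings
  n <- length(m)
  lo <- integer(length(cand)); hi <- integer(length(cand))
  for (j in seq_along(cand)) {
    a <- starts[cand[j]]; b <- ends[cand[j]]
    while (a > 1L && m[a - 1L] > 0) a <- a - 1L
    while (b < n && m[b + 1L] > 0) b <- b + 1L
    lo[j] <- a; hi[j] <- b
  }
  # merge overlapping regions and regions closer than merge_gap
  gap_n <- round(merge_gap / x$dt)
  keep_lo <- lo[1L]; keep_hi <- hi[1L]
  if (length(cand) > 1L) {
    for (j in 2:length(cand)) {
      last <- length(keep_hi)
      if (lo[j] <= keep_hi[last] + gap_n) {
        keep_hi[last] <- max(keep_hi[last], hi[j])
      } else {
        keep_lo <- c(keep_lo, lo[j]); keep_hi <- c(keep_hi, hi[j])
      }
    }
  }

  base_raw <- stats::median(x$samples)
  mraw <- sgn * (x$samples - base_raw)
  ev <- data.frame(
    onset_ms = x$t0 + (keep_lo - 1L) * x$dt,
    offset_ms = x$t0 + (keep_hi - 1L) * x$dt,
    area_pAms = vapply(seq_along(keep_lo), function(j) {
      idx <- keep_lo[j]:keep_hi[j]
      pracma::trapz(idx * x$dt, mraw[idx])
    }, 0),
    peak_pA = vapply(seq_along(keep_lo), function(j)
      max(mraw[keep_lo[j]:keep_hi[j]]), 0))
  list(events = ev,
       iei_ms = diff(ev$onset_ms),
       frequency_hz = nrow(ev) / (trace_duration(x) / 1000))
}
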