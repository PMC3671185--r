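#' Spearman stability screen for an event series
#'
#' Before pooling events for fluctuation analysis the recording must be
#' stationary. Each measured parameter is numbered by event order and
#' tested with Spearman's rank-order correlation against the event index
#' (time stability of amplitude, rise time and decay), and the rise time is
#' additionally tested against amplitude and against decay (a correlation
#' there indicates electrotonic filtering). The screen passes when all
#' five tests are non-significant.
#'
#' @param catalog an [event_catalog()]; at least 10 QC-passing events.
#' @param alpha significance level of the screen (default 0.05).
#' @return an object of class `stability_report`: the five `(rho, p)`
#'   pairs and a `passed` flag. A test on a constant (all-ties) series has
#'   an undefined rho and is treated as a pass, with a warning.
#' @export
stability_screen <- function(catalog, alpha = 0.05) {
  stopifnot(inherits(catalog, "event_catalog"))
  ev <- filter_qc(catalog)$events
  if (nrow(ev) < 10L)
    stop("stability screen needs at least 10 QC-passing events",
         call. = FALSE)
  idx <- seq_len(nrow(ev))
  decay <- ev$weighted_decay_ms
  spear <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 4L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      warning("degenerate (constant) series in stability screen; ",
              "treated as stable", call. = FALSE)
      return(c(rho = NA_real_, p = 1))
    }
    ct <- suppressWarnings(
      stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  tests <- list(
    amp_vs_index = spear(ev$amplitude_pA, idx),
    rise_vs_index = spear(ev$rise_10_90_ms, idx),
    decay_vs_index = spear(decay, idx),
    rise_vs_amp = spear(ev$rise_10_90_ms, ev$amplitude_pA),
    rise_vs_decay = spear(ev$rise_10_90_ms, decay))
  pvals <- vapply(tests, function(z) z[["p"]], 0)
  structure(list(tests = tests, alpha = alpha,
                 passed = all(pvals > alpha), n_events = nrow(ev)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d events, alpha = %g: %s\n",
              x$n_events, x$alpha,
              if (x$passed) "PASSED" else "FAILED"))
  for (nm in names(x$tests))
    cat(sprintf("  %-15s rho = %6.3f  p = %.4g\n", nm,
                x$tests[[nm]][["rho"]], x$tests[[nm]][["p"]]))
  invisible(x)
}

#' Align events at the point of steepest rise and average them
#'
#' Each QC-passing event is cut out of the trace and aligned at its point
#' of steepest rise (the maximum of the smoothed derivative of the
#' baseline-subtracted magnitude on the rising phase, refined by parabolic
#' interpolation to sub-sample precision). The applied shift is rounded to
#' the sample grid: extracting on the original grid keeps the noise
#' process intact, whereas fractional resampling by linear interpolation
#' would shrink the white-noise variance by up to a third and bias any
#' downstream fluctuation analysis. Events whose window exceeds the trace
#' bounds are dropped with a message.
#'
#' @param x a [psc_trace()].
#' @param catalog an [event_catalog()].
#' @param pre,post window before/after the alignment point, ms.
#' @param stability an optional [stability_screen()] report; if supplied
#'   and failed, alignment refuses to proceed unless `override = TRUE`.
#' @param override proceed despite a failed stability screen.
#' @param polarity event polarity.
#' @return an object of class `psc_ensemble`: matrix `waveforms` (events x
#'   samples, baseline-subtracted magnitudes), `times` (ms relative to the
#'   alignment point), `mean_waveform`, and the retained event rows.
#' @export
align_and_average <- function(x, catalog, pre = 5, post = 50,
                              stability = NULL, override = FALSE,
                              polarity = c("inward", "outward")) {
  stopifnot(inherits(x, "trace"), inherits(catalog, "event_catalog"))
  polarity <- match.arg(polarity)
  if (!is.null(stability) && !stability$passed && !override)
    stop("stability screen failed; pass override = TRUE to proceed",
         call. = FALSE)
  sgn <- if (polarity == "inward") -1 else 1
  ev <- filter_qc(catalog)$events
  if (nrow(ev) < 1L) stop("no QC-passing events to align", call. = FALSE)
  dt <- x$dt
  grid <- seq(-pre, post, by = dt)
  n <- length(x$samples)
  tt_all <- trace_times(x)

  waves <- matrix(NA_real_, nrow(ev), length(grid))
  keep <- logical(nrow(ev))
  # smoothing kernel for the derivative (0.25 ms boxcar): per-sample
  # channel noise would otherwise dominate the slope estimate
  sm_n <- max(1L, round(0.25 / dt))
  box <- rep(1 / sm_n, sm_n)
  for (k in seq_len(nrow(ev))) {
    i_on <- round((ev$onset_ms[k] - x$t0) / dt) + 1L
    i_pk <- round((ev$peak_ms[k] - x$t0) / dt) + 1L
    lo <- max(1L, i_on - sm_n)
    hi <- min(n, i_pk + sm_n)
    if (hi - lo < 3L) next
    seg <- sgn * (x$samples[lo:hi] - ev$baseline_pA[k])
    segs <- stats::filter(seg, box, sides = 2)
    dseg <- diff(as.numeric(segs))
    dseg[!is.finite(dseg)] <- -Inf
    j <- which.max(dseg)
    # parabolic refinement of the slope maximum
    frac <- 0
    if (j > 1L && j < length(dseg)) {
      y1 <- dseg[j - 1L]; y2 <- dseg[j]; y3 <- dseg[j + 1L]
      den <- y1 - 2 * y2 + y3
      if (is.finite(den) && den < 0) frac <- 0.5 * (y1 - y3) / den
      frac <- max(-0.5, min(0.5, frac))
    }
    t_align <- tt_all[lo + j - 1L] + (frac + 0.5) * dt
    i_align <- round((t_align - x$t0) / dt) + 1L
    i_lo <- i_align - round(pre / dt)
    i_hi <- i_lo + length(grid) - 1L
    if (i_lo < 1L || i_hi > n) {
      message("event ", k, " window exceeds trace bounds; dropped")
      next
    }
    waves[k, ] <- sgn * (x$samples[i_lo:i_hi] - ev$baseline_pA[k])
    keep[k] <- TRUE
  }
  if (!any(keep)) stop("no events could be aligned", call. = FALSE)
  waves <- waves[keep, , drop = FALSE]
  structure(list(waveforms = waves, times = grid,
                 mean_waveform = colMeans(waves),
                 events = ev[keep, , drop = FALSE], dt = dt),
            class = "psc_ensemble")
}

#' Peak-scaled non-stationary fluctuation analysis
#'
#' The ensemble mean waveform is scaled, for each event, to that event's
#' value at the mean's peak time, and subtracted to form a difference
#' waveform. Over the decay phase the across-event variance of the
#' differences at each time point is paired with the mean current at that
#' point; the mean-current axis is divided into `n_bins` equal-width bins
#' (equal-occupancy available via `equal_count`) and the per-bin mean
#' variance is fitted by weighted least squares to the parabola
#' \deqn{\sigma^2(I) = iI - I^2/N + \sigma_b^2,}
#' giving the unitary current i, the number of channels open at the peak N,
#' and the background variance. The chord conductance follows from
#' [conductance()]. Per-bin weights are count / (2 variance^2), the inverse
#' large-sample variance of a sample variance; bins with fewer than
#' `min_bin_count` time points are excluded.
#'
#' @param ensemble a [align_and_average()] result with at least 20 events.
#' @param holding_Em holding potential, mV.
#' @param reversal_Erev reversal potential of the current, mV.
#' @param n_bins number of amplitude bins (default 50).
#' @param min_bin_count minimum time points per bin entering the fit.
#' @param equal_count bin by equal occupancy instead of equal width.
#' @param scale_window half-width, in ms, of the window around the mean's
#'   peak over which each event's scaling factor is averaged. Scaling by
#'   the single peak sample would inject that sample's noise variance,
#'   multiplied by the squared normalised mean waveform, into the variance
#'   curve - a spurious positive quadratic term that cancels the -I^2/N
#'   curvature the fit estimates. Averaging over ~0.5 ms suppresses it.
#' @return an object of class `nsfa_result` with `unitary_current_i` (pA),
#'   `n_channels`, `background_variance` (pA^2), `conductance_gamma` (pS),
#'   the binned variance-mean table and the 3x3 parameter covariance.
#'   A degenerate fit (non-finite parameters or N <= 0) raises an error
#'   carrying the variance-mean table in its `table` field.
#' @export
peak_scaled_nsfa <- function(ensemble, holding_Em = -70,
                             reversal_Erev = 0, n_bins = 50,
                             min_bin_count = 2, equal_count = FALSE,
                             scale_window = 0.5) {
  stopifnot(inherits(ensemble, "psc_ensemble"))
  W <- ensemble$waveforms
  K <- nrow(W)
  if (K < 20L)
    stop("peak-scaled NSFA needs at least 20 aligned events",
         call. = FALSE)
  M <- ensemble$mean_waveform
  # peak located on a 3-sample boxcar-smoothed mean to dodge noise spikes
  Msm <- stats::filter(M, rep(1 / 3, 3), sides = 2)
  Msm[!is.finite(Msm)] <- -Inf
  pk <- which.max(Msm)

  h <- min(round(scale_window / ensemble$dt), pk - 1L, ncol(W) - pk)
  win <- (pk - h):(pk + h)
  scale_k <- rowMeans(W[, win, drop = FALSE]) / mean(M[win])
  D <- W - outer(scale_k, M)
  # decay phase only, starting past the scale window: samples inside it
  # have their variance partly absorbed by the scaling itself
  if (pk + h + 1L >= ncol(W))
    stop("no decay phase beyond the scale window", call. = FALSE)
  dec <- (pk + h + 1L):ncol(W)
  var_t <- colSums(D[, dec, drop = FALSE]^2) / (K - 1)
  mean_t <- M[dec]

  rng <- range(mean_t)
  if (equal_count) {
    qs <- stats::quantile(mean_t, probs = seq(0, 1, length.out = n_bins + 1))
    breaks <- unique(qs)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin <- factor(cut(mean_t, breaks, include.lowest = TRUE,
                    labels = FALSE),
                levels = seq_len(length(breaks) - 1L))
  tab <- data.frame(
    bin_mean = as.numeric(tapply(mean_t, bin, mean)),
    bin_variance = as.numeric(tapply(var_t, bin, mean)),
    count = as.integer(table(bin)))
  empty <- tab$count == 0L
  tab$bin_mean[empty] <- (breaks[-length(breaks)] + breaks[-1L])[empty] / 2

  use <- tab$count >= min_bin_count & is.finite(tab$bin_variance) &
    tab$bin_variance > 0
  fit_tab <- tab[use, , drop = FALSE]
  fail <- function(msg) {
    cond <- structure(
      class = c("nsfa_fit_error", "error", "condition"),
      list(message = msg, call = sys.call(-1), table = tab))
    stop(cond)
  }
  if (nrow(fit_tab) < 4L) fail("too few populated bins for the NSFA fit")

  # iterated WLS: weights count / (2 sigma^4) use the fitted variance from
  # the previous pass, so sparse bins do not get erratic weights from their
  # own noisy variance estimate
  w <- fit_tab$count / (2 * fit_tab$bin_variance^2)
  for (pass in 1:3) {
    fit <- stats::lm(bin_variance ~ bin_mean + I(bin_mean^2),
                     data = fit_tab, weights = w)
    pred <- pmax(stats::fitted(fit), max(fit_tab$bin_variance) * 1e-3)
    w <- fit_tab$count / (2 * pred^2)
  }
  cf <- stats::coef(fit)
  i_hat <- unname(cf[2L])
  b2 <- unname(cf[3L])
  sb2 <- unname(cf[1L])
  if (!all(is.finite(cf)) || b2 >= 0 || i_hat <= 0)
    fail("degenerate NSFA fit (no downward curvature or negative i)")
  n_hat <- -1 / b2
  structure(list(
    unitary_current_i = i_hat, n_channels = n_hat,
    background_variance = sb2,
    conductance_gamma = conductance(i_hat, holding_Em, reversal_Erev),
    holding_Em = holding_Em, reversal_Erev = reversal_Erev,
    bin_means = tab$bin_mean, bin_variances = tab$bin_variance,
    bin_counts = tab$count, fitted_bins = which(use),
    n_events = K, fit_covariance = stats::vcov(fit),
    peak_mean_pA = M[pk]),
    class = "nsfa_result")
}

#' @export
print.nsfa_result <- function(x, ...) {
  cat(sprintf(paste0("<nsfa_result> %d events\n",
                     "  i  = %.3g pA   N = %.3g channels\n",
                     "  sigma_b^2 = %.3g pA^2   gamma = %.3g pS ",
                     "(Em = %g mV, Erev = %g mV)\n"),
              x$n_events, x$unitary_current_i, x$n_channels,
              x$background_variance, x$conductance_gamma,
              x$holding_Em, x$reversal_Erev))
  invisible(x)
}

#' Evaluate the fitted variance-mean parabola
#'
#' Closed form of the fitted relation, used e.g. to verify the parabola
#' identities: the variance equals the background variance at I = 0 and at
#' I = iN, and the apex at I = iN/2 carries excess variance i^2 N / 4.
#'
#' @param result an `nsfa_result`.
#' @param I mean-current values, pA.
#' @return fitted variance at `I`, pA^2.
#' @export
nsfa_parabola <- function(result, I) {
  stopifnot(inherits(result, "nsfa_result"))
  result$unitary_current_i * I - I^2 / result$n_channels +
    result$background_variance
}

#' Single-channel chord conductance
#'
#' \eqn{\gamma = i / (E_m - E_{rev})}, returned as a magnitude in pS for
#' i in pA and potentials in mV (1 pA/mV = 1 nS = 1000 pS).
#'
#' @param i unitary current, pA.
#' @param Em holding potential, mV.
#' @param Erev reversal potential, mV (0 for chloride currents under a
#'   symmetric-chloride pipette solution).
#' @return conductance magnitude in pS.
#' @export
conductance <- function(i, Em, Erev = 0) {
  if (Em == Erev)
    stop("holding and reversal potential coincide: zero driving force",
         call. = FALSE)
  abs(1000 * i / (Em - Erev))
}
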