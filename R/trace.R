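#' Construct a voltage-clamp current trace
#'
#' A `trace` holds a uniformly sampled whole-cell current recording together
#' with the acquisition metadata every analysis stage needs. Currents are
#' stored in pA with the physical sign convention (inward currents negative);
#' time is in ms throughout the package. The default sampling interval of
#' 0.05 ms corresponds to 20 kHz acquisition.
#'
#' @param samples numeric vector of current values (pA, inward negative).
#' @param dt sampling interval in ms (default 0.05, i.e. 20 kHz).
#' @param t0 start time of the first sample in ms.
#' @param holding_potential holding potential in mV.
#' @param channel_label free-text label identifying the recording.
#' @param condition free-text experimental condition (e.g. "control",
#'   "TPMPA", "NO-711+picrotoxin").
#' @param filter_cutoff low-pass filter cut-off used at acquisition, in kHz,
#'   or `NA` if unknown.
#'
#' @return an object of class `trace`.
#' @export
psc_trace <- function(samples, dt = 0.05, t0 = 0, holding_potential = -70,
                  channel_label = "", condition = "",
                  filter_cutoff = NA_real_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least two samples", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive sampling interval in ms", call. = FALSE)
  structure(
    list(samples = samples, dt = as.numeric(dt), t0 = as.numeric(t0),
         holding_potential = as.numeric(holding_potential),
         channel_label = as.character(channel_label),
         condition = as.character(condition),
         filter_cutoff = as.numeric(filter_cutoff)),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples, dt = %g ms (%.5g s), Vh = %g mV\n",
              length(x$samples), x$dt, trace_duration(x) / 1000,
              x$holding_potential))
  if (nzchar(x$condition)) cat("  condition:", x$condition, "\n")
  if (nzchar(x$channel_label)) cat("  label:", x$channel_label, "\n")
  invisible(x)
}

#' Trace duration in ms
#' @param x a [psc_trace()].
#' @return duration in ms (`n * dt`).
#' @export
trace_duration <- function(x) length(x$samples) * x$dt

#' Sample times of a trace
#' @param x a [psc_trace()].
#' @return numeric vector of sample times in ms.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$samples) - 1) * x$dt

#' Read a current trace from disk
#'
#' Two plain-text formats are supported: the native JSON bundle written by
#' [write_trace()] (dataset `current_pA` plus the acquisition attributes),
#' and a two-column CSV (`t` in ms, `I` in pA) on a uniform time grid, from
#' which `dt` is inferred as the median sample spacing.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"bundle"` or `"csv"`.
#' @return a [psc_trace()].
#' @export
read_trace <- function(path, format = c("auto", "bundle", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "bundle", h5 = "bundle",
                     stop("cannot infer trace format from extension '.",
                          ext, "'", call. = FALSE))
  }
  if (format == "csv") {
    tab <- utils::read.csv(path)
    if (ncol(tab) < 2L) stop("trace CSV needs columns t, I", call. = FALSE)
    dts <- diff(tab[[1L]])
    if (length(dts) == 0L || any(dts <= 0))
      stop("trace CSV times must be strictly increasing", call. = FALSE)
    return(psc_trace(tab[[2L]], dt = stats::median(dts), t0 = tab[[1L]][1L]))
  }
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$current_pA))
    stop("bundle is missing the 'current_pA' dataset", call. = FALSE)
  if (is.null(b$dt_ms))
    stop("bundle is missing the 'dt_ms' sampling-rate attribute",
         call. = FALSE)
  psc_trace(b$current_pA, dt = b$dt_ms,
        t0 = b$t0_ms %||% 0,
        holding_potential = b$holding_mV %||% -70,
        channel_label = b$channel_label %||% "",
        condition = b$condition %||% "",
        filter_cutoff = b$filter_cutoff_kHz %||% NA_real_)
}

#' Write a trace as a plain-text JSON bundle
#'
#' The bundle stores the sample array under `current_pA` and the metadata as
#' sibling attributes (`dt_ms`, `t0_ms`, `holding_mV`, `condition`,
#' `channel_label`, `filter_cutoff_kHz`). Doubles are serialised at full
#' precision so `read_trace(write_trace(x))` round-trips bit-exactly.
#'
#' @param x a [psc_trace()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  b <- list(current_pA = x$samples, dt_ms = x$dt, t0_ms = x$t0,
            holding_mV = x$holding_potential,
            channel_label = x$channel_label, condition = x$condition,
            filter_cutoff_kHz = x$filter_cutoff)
  # digits = I(17): significant-digit mode at full double precision, so
  # the round-trip is bit-exact
  jsonlite::write_json(b, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
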