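#' Construct an event catalog
#'
#' An `event_catalog` is the container every detection and kinetics stage
#' exchanges: one row per detected miniature event, ordered by onset time.
#'
#' Columns of the event table (units fixed package-wide):
#' `onset_ms`, `peak_ms`, `amplitude_pA` (baseline-subtracted magnitude,
#' positive), `baseline_pA`, `rise_10_90_ms`, `charge_pAms`,
#' `weighted_decay_ms` (charge / amplitude), `decay_tau_ms` (mono-exponential
#' fit, `NA` when not fitted), `score` (dimensionless detection criterion)
#' and `qc_pass` (logical).
#'
#' @param events data.frame with the columns listed above (missing columns
#'   are filled with `NA`).
#' @param source_trace_id identifier of the trace the events came from.
#' @param detection_params list of parameters used by the detector, kept for
#'   provenance.
#' @return an object of class `event_catalog`.
#' @export
event_catalog <- function(events = NULL, source_trace_id = "",
                          detection_params = list()) {
  cols <- c("onset_ms", "peak_ms", "amplitude_pA", "baseline_pA",
            "rise_10_90_ms", "charge_pAms", "weighted_decay_ms",
            "decay_tau_ms", "score", "qc_pass")
  if (is.null(events)) {
    events <- as.data.frame(stats::setNames(
      c(rep(list(numeric(0)), 9L), list(logical(0))), cols))
  }
  for (cc in setdiff(cols, names(events)))
    events[[cc]] <- if (cc == "qc_pass") NA else NA_real_
  events <- events[, cols, drop = FALSE]
  if (nrow(events) > 1L) {
    events <- events[order(events$onset_ms), , drop = FALSE]
    if (any(diff(events$onset_ms) <= 0))
      stop("events must have strictly increasing onset times", call. = FALSE)
  }
  rownames(events) <- NULL
  structure(list(events = events, source_trace_id = source_trace_id,
                 detection_params = detection_params),
            class = "event_catalog")
}

#' @export
print.event_catalog <- function(x, ...) {
  n <- nrow(x$events)
  cat(sprintf("<event_catalog> %d events (%d passing QC)\n",
              n, sum(x$events$qc_pass, na.rm = TRUE)))
  if (n) print(utils::head(x$events, 5L))
  invisible(x)
}

#' Keep only QC-passing events
#' @param catalog an [event_catalog()].
#' @return an [event_catalog()] restricted to rows with `qc_pass == TRUE`.
#' @export
filter_qc <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  keep <- which(catalog$events$qc_pass %in% TRUE)
  event_catalog(catalog$events[keep, , drop = FALSE],
                catalog$source_trace_id, catalog$detection_params)
}

#' Write / read an event catalog as CSV
#'
#' One row per event; the column order is exactly the one documented in
#' [event_catalog()]. Numeric values are written at full precision (well
#' beyond 6 significant digits), so the round-trip is lossless.
#'
#' @param catalog an [event_catalog()].
#' @param path destination file.
#' @return `path` invisibly (`write_events`); an [event_catalog()]
#'   (`read_events`).
#' @export
write_events <- function(catalog, path) {
  stopifnot(inherits(catalog, "event_catalog"))
  utils::write.csv(catalog$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("cannot parse event CSV: ", conditionMessage(e),
                         call. = FALSE))
  need <- c("onset_ms", "peak_ms", "amplitude_pA")
  if (!all(need %in% names(tab)))
    stop("event CSV is missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$onset_ms))
  if (length(bad))
    stop("malformed event row ", bad[1L], ": non-numeric onset_ms",
         call. = FALSE)
  tab$qc_pass <- as.logical(tab$qc_pass)
  event_catalog(tab, source_trace_id = "", detection_params = list())
}
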