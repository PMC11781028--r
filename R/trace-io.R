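#' Ionic-current trace container
#'
#' A uniformly sampled current recording plus sampling metadata and the
#' voltage program, either as a [waveform_spec()] (preferred) or a per-sample
#' voltage vector (mV).
#'
#' @param current Numeric vector of current samples (nA), finite.
#' @param sampling_rate Sampling rate (Hz).
#' @param waveform Optional [waveform_spec()] describing the voltage program.
#' @param voltage Optional per-sample voltage (mV), same length as `current`.
#' @param start_time Absolute time of the first sample (s); recording starts
#'   about one minute after reagent mixing, which the kinetic model accounts
#'   for separately via its `start_offset`.
#' @return An object of class `nanopore_trace`.
#' @export
nanopore_trace <- function(current, sampling_rate, waveform = NULL,
                           voltage = NULL, start_time = 0) {
  .check_num(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (!is.numeric(current) || length(current) == 0L) {
    .fail("'current' must be a non-empty numeric vector")
  }
  nf <- which(!is.finite(current))
  if (length(nf)) {
    .fail("non-finite current sample(s), first at index ", nf[1])
  }
  if (!is.null(voltage) && length(voltage) != length(current)) {
    .fail("'voltage' must match 'current' in length")
  }
  if (!is.null(waveform)) stopifnot(inherits(waveform, "waveform_spec"))
  structure(list(current = current, sampling_rate = sampling_rate,
                 waveform = waveform, voltage = voltage,
                 start_time = start_time),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  cat(sprintf("<nanopore_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$current), x$sampling_rate,
              length(x$current) / x$sampling_rate))
  if (!is.null(x$waveform)) {
    wf <- x$waveform
    cat(sprintf("  waveform: %g s @ %+g mV / %g s @ %+g mV x %d loops\n",
                wf$rest_duration, wf$rest_voltage,
                wf$capture_duration, wf$capture_voltage, wf$n_loops))
  }
  invisible(x)
}

# per-sample voltage reconstructed from the waveform program
.waveform_voltage <- function(waveform, n, sampling_rate) {
  period_n <- round(waveform_period(waveform) * sampling_rate)
  rest_n <- round(waveform$rest_duration * sampling_rate)
  phase <- (seq_len(n) - 1L) %% period_n
  ifelse(phase < rest_n, waveform$rest_voltage, waveform$capture_voltage)
}

#' Write a trace in the columnar text format
#'
#' TSV with columns `time_s`, `current_nA`, `voltage_mV`, preceded by a
#' `#`-prefixed metadata block carrying the sampling rate (mandatory on
#' read), start time and, when known, the waveform parameters.
#'
#' @param trace A [nanopore_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nanopore_trace"))
  n <- length(trace$current)
  meta <- c(
    sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate),
    sprintf("# start_time_s: %.10g", trace$start_time),
    "# units: current=nA voltage=mV")
  if (!is.null(trace$waveform)) {
    wf <- trace$waveform
    meta <- c(meta, sprintf(
      "# waveform: rest_mV=%g rest_s=%g capture_mV=%g capture_s=%g n_loops=%d",
      wf$rest_voltage, wf$rest_duration, wf$capture_voltage,
      wf$capture_duration, wf$n_loops))
  }
  writeLines(meta, path)
  volt <- if (!is.null(trace$voltage)) {
    trace$voltage
  } else if (!is.null(trace$waveform)) {
    .waveform_voltage(trace$waveform, n, trace$sampling_rate)
  } else {
    rep(NA_real_, n)
  }
  df <- data.frame(time_s = trace$start_time + (seq_len(n) - 1L) / trace$sampling_rate,
                   current_nA = trace$current, voltage_mV = volt)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a trace from the columnar text format
#'
#' The sampling rate must be present in the metadata block; it is never
#' guessed from the time column. Non-finite current samples are a hard error
#' reported with their index.
#'
#' @param path File written by [write_trace()] (or conforming to the format).
#' @return A [nanopore_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) .fail("trace file not found: ", path)
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  rate <- get_meta("sampling_rate_hz")
  if (is.null(rate)) {
    .fail("trace metadata is missing 'sampling_rate_hz'; refusing to guess")
  }
  rate <- as.numeric(rate)
  start_time <- as.numeric(get_meta("start_time_s") %||% "0")
  wf <- NULL
  wl <- get_meta("waveform")
  if (!is.null(wl)) {
    kv <- strsplit(strsplit(wl, "\\s+")[[1]], "=")
    vals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                     vapply(kv, `[`, "", 1))
    wf <- waveform_spec(capture_voltage = vals[["capture_mV"]],
                        capture_duration = vals[["capture_s"]],
                        rest_voltage = vals[["rest_mV"]],
                        rest_duration = vals[["rest_s"]],
                        n_loops = vals[["n_loops"]])
  }
  df <- data.table::fread(path, sep = "\t", skip = length(meta))
  cur <- df[["current_nA"]]
  if (is.null(cur)) .fail("trace file lacks a 'current_nA' column")
  volt <- df[["voltage_mV"]]
  if (!is.null(volt) && all(is.na(volt))) volt <- NULL
  nanopore_trace(cur, rate, waveform = wf, voltage = volt,
                 start_time = start_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a trace into waveform sweeps
#'
#' One sweep per capture (negative-voltage) phase. Uses the waveform
#' metadata when present, otherwise detects capture phases from the
#' per-sample voltage. A partial trailing sweep is dropped with a message.
#' Sample coordinates are 0-based, half-open.
#'
#' @param trace A [nanopore_trace()] with a known voltage program.
#' @return data.frame with one row per sweep: `index` (1-based),
#'   `sweep_start`, `capture_start`, `capture_end` (0-based sample offsets,
#'   half-open) and `absolute_start_s`.
#' @export
segment_sweeps <- function(trace) {
  stopifnot(inherits(trace, "nanopore_trace"))
  fs <- trace$sampling_rate
  n <- length(trace$current)
  if (!is.null(trace$waveform)) {
    wf <- trace$waveform
    period_n <- round(waveform_period(wf) * fs)
    rest_n <- round(wf$rest_duration * fs)
    n_sweeps <- n %/% period_n
    if (n_sweeps < 1L) .fail("no complete capture phase in trace")
    if (n %% period_n != 0) {
      message(sprintf("dropping partial trailing sweep (%d samples)",
                      n %% period_n))
    }
    s0 <- (seq_len(n_sweeps) - 1L) * period_n
    out <- data.frame(index = seq_len(n_sweeps),
                      sweep_start = s0,
                      capture_start = s0 + rest_n,
                      capture_end = s0 + period_n)
  } else if (!is.null(trace$voltage)) {
    v <- trace$voltage
    thr <- (min(v) + max(v)) / 2
    cap <- v < thr
    if (!any(cap)) .fail("no capture phases found in voltage channel")
    r <- rle(cap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ci <- which(r$values)
    cs <- starts[ci]; ce <- ends[ci]
    # drop a trailing capture run truncated by the end of the recording
    if (length(ci) && ce[length(ce)] == n &&
        r$lengths[ci[length(ci)]] < max(r$lengths[ci])) {
      message("dropping partial trailing sweep (truncated capture phase)")
      cs <- head(cs, -1); ce <- head(ce, -1)
    }
    if (!length(cs)) .fail("no complete capture phase in trace")
    rest_len <- cs - c(1L, head(ce, -1) + 1L)
    full <- rest_len >= max(rest_len) # require a full preceding rest phase
    cs <- cs[full]; ce <- ce[full]; rest_len <- rest_len[full]
    out <- data.frame(index = seq_along(cs),
                      sweep_start = cs - 1L - rest_len,
                      capture_start = cs - 1L,
                      capture_end = ce)
  } else {
    .fail("trace has neither waveform metadata nor a voltage channel")
  }
  out$absolute_start_s <- trace$start_time + out$sweep_start / fs
  out
}

#' Per-sweep analysis windows
#'
#' The assay analyses seconds 4-9 of each waveform period. With the default
#' 3.5 s rest + 6 s capture program this spans capture seconds 0.5-5.5,
#' i.e. the first half-second of each capture phase is discarded as settling
#' time. Set `origin = "capture"` to measure the window from the capture
#' onset instead (only meaningful for long capture phases).
#'
#' @param sweeps Output of [segment_sweeps()].
#' @param sampling_rate Sampling rate (Hz).
#' @param window Two numbers: window start/end in seconds from the origin.
#' @param origin `"sweep"` (default; window measured from the sweep start,
#'   i.e. the rest-phase onset) or `"capture"`.
#' @return data.frame: `sweep_index`, `start`, `end` (0-based half-open
#'   sample offsets) and `start_s` (absolute).
#' @export
analysis_windows <- function(sweeps, sampling_rate, window = c(4, 9),
                             origin = c("sweep", "capture")) {
  origin <- match.arg(origin)
  stopifnot(is.data.frame(sweeps), nrow(sweeps) >= 1L,
            length(window) == 2L, window[1] < window[2])
  base <- if (origin == "sweep") sweeps$sweep_start else sweeps$capture_start
  ws <- base + round(window[1] * sampling_rate)
  we <- base + round(window[2] * sampling_rate)
  if (any(ws < sweeps$capture_start) || any(we > sweeps$capture_end)) {
    .fail("analysis window [", window[1], ", ", window[2],
          ") s does not fit inside the capture phase; capture too short")
  }
  data.frame(sweep_index = sweeps$index, start = ws, end = we,
             start_s = sweeps$absolute_start_s +
               (ws - sweeps$sweep_start) / sampling_rate)
}
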