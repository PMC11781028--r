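#' Robust baseline estimate for an analysis window
#'
#' Median for the level and 1.4826*MAD for sigma, so that events occupying
#' up to ~20% of the window barely perturb the estimate. The threshold rule
#' downstream is `mean + n_sigma * sigma` with `n_sigma = 10` by default.
#'
#' @param x Window samples (nA), at least `min_n` of them.
#' @param min_n Minimum sample count, default 1000.
#' @return List of class `baseline_model`: `mean`, `sigma`, `method`.
#' @export
estimate_baseline <- function(x, min_n = 1000L) {
  if (!is.numeric(x) || length(x) < min_n) {
    .fail("need at least ", min_n, " samples to estimate a baseline")
  }
  m <- median(x)
  s <- mad(x)  # 1.4826 * MAD
  if (s <= 0) .fail("degenerate baseline: MAD-based sigma is zero")
  structure(list(mean = m, sigma = s, method = "median/MAD"),
            class = "baseline_model")
}

# centred boxcar smoother; width forced odd, 1 = identity
.boxcar <- function(y, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(y)
  ys <- stats::filter(y, rep(1 / width, width), sides = 2)
  ys <- as.numeric(ys)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

#' Detect conductive-pulse events in one analysis window
#'
#' Contiguous runs of samples exceeding `baseline$mean + n_sigma *
#' baseline$sigma` in the conductive direction become candidate events;
#' candidates separated by less than `merge_gap_ms` are merged; each event
#' is extended to the nearest baseline crossings. The peak amplitude is the
#' maximum deviation from baseline, read from a lightly smoothed copy of the
#' signal (`smooth_ms` boxcar, default 0.05 ms) to suppress the upward bias
#' of a raw max over noise; thresholding itself always uses raw samples.
#' Dwell is the full width at half maximum by default.
#'
#' @param x Window samples (nA).
#' @param baseline A [estimate_baseline()] result.
#' @param sampling_rate Sampling rate (Hz).
#' @param n_sigma Threshold in baseline sigmas, default 10.
#' @param merge_gap_ms Merge events closer than this (ms), default 0.1.
#' @param t0 Absolute time of the first sample of `x` (s).
#' @param sweep_index Sweep index recorded in the output.
#' @param polarity `+1` if conductive pulses are positive deflections
#'   (default), `-1` otherwise.
#' @param dwell_method `"fwhm"` (default) or `"threshold"` (width of the
#'   threshold-crossing run).
#' @param smooth_ms Boxcar width (ms) for amplitude/dwell measurement;
#'   0 disables smoothing.
#' @return data.frame of events: `sweep`, `onset_s`, `peak_s`, `amp_nA`,
#'   `dwell_ms`, `area_nAms`. Zero rows when nothing crosses the threshold.
#' @export
detect_events <- function(x, baseline, sampling_rate, n_sigma = 10,
                          merge_gap_ms = 0.1, t0 = 0, sweep_index = NA_integer_,
                          polarity = 1, dwell_method = c("fwhm", "threshold"),
                          smooth_ms = 0.05) {
  dwell_method <- match.arg(dwell_method)
  stopifnot(inherits(baseline, "baseline_model"), polarity %in% c(-1, 1))
  empty <- data.frame(sweep = integer(), onset_s = numeric(),
                      peak_s = numeric(), amp_nA = numeric(),
                      dwell_ms = numeric(), area_nAms = numeric())
  y <- polarity * (x - baseline$mean)
  thr <- n_sigma * baseline$sigma
  above <- y > thr
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ai <- which(r$values)
  rs <- starts[ai]; re <- ends[ai]
  gap_n <- merge_gap_ms / 1000 * sampling_rate
  if (length(rs) > 1L) {
    keep_sep <- (rs[-1] - re[-length(re)] - 1L) >= gap_n
    grp <- cumsum(c(TRUE, keep_sep))
    rs <- tapply(rs, grp, min)
    re <- tapply(re, grp, max)
  }

  ys <- .boxcar(y, round(smooth_ms / 1000 * sampling_rate))
  n <- length(y)
  out <- vector("list", length(rs))
  for (e in seq_along(rs)) {
    L <- rs[e]; R <- re[e]
    while (L > 1L && y[L - 1L] > 0) L <- L - 1L
    while (R < n && y[R + 1L] > 0) R <- R + 1L
    seg <- ys[L:R]
    pk <- which.max(seg)
    amp <- seg[pk]
    if (dwell_method == "fwhm") {
      half <- amp / 2
      li <- pk
      while (li > 1L && seg[li - 1L] > half) li <- li - 1L
      xl <- if (li == 1L) 1 else {
        li - (seg[li] - half) / (seg[li] - seg[li - 1L])
      }
      ri <- pk
      len <- length(seg)
      while (ri < len && seg[ri + 1L] > half) ri <- ri + 1L
      xr <- if (ri == len) len else {
        ri + (seg[ri] - half) / (seg[ri] - seg[ri + 1L])
      }
      dwell <- (xr - xl) / sampling_rate * 1000
    } else {
      dwell <- (re[e] - rs[e] + 1L) / sampling_rate * 1000
    }
    out[[e]] <- data.frame(
      sweep = sweep_index,
      onset_s = t0 + (L - 1L) / sampling_rate,
      peak_s = t0 + (L - 1L + pk - 1L) / sampling_rate,
      amp_nA = amp,
      dwell_ms = max(dwell, 1 / sampling_rate * 1000),
      area_nAms = sum(y[L:R]) / sampling_rate * 1000)
  }
  do.call(rbind, out)
}

#' Detect events across a whole recording
#'
#' Segments the trace into sweeps, takes the 4-9 s analysis window of each,
#' estimates a robust baseline per window (baseline drift between sweeps is
#' expected; none is corrected within a window) and runs [detect_events()].
#' An optional Butterworth low-pass (e.g. 20 kHz, matching the recording
#' filter) can be applied per window before detection.
#'
#' @param trace A [nanopore_trace()].
#' @param n_sigma,merge_gap_ms,dwell_method,smooth_ms Passed to
#'   [detect_events()].
#' @param window,origin Passed to [analysis_windows()].
#' @param polarity Conductive-pulse sign, default `+1`.
#' @param lowpass_khz Optional low-pass cutoff (kHz); `NULL` (default) skips
#'   filtering.
#' @return data.frame of events (see [detect_events()]), with absolute
#'   `onset_s`/`peak_s` across the recording.
#' @export
detect_experiment <- function(trace, n_sigma = 10, merge_gap_ms = 0.1,
                              window = c(4, 9), origin = "sweep",
                              polarity = 1, dwell_method = "fwhm",
                              smooth_ms = 0.05, lowpass_khz = NULL) {
  stopifnot(inherits(trace, "nanopore_trace"))
  fs <- trace$sampling_rate
  sweeps <- segment_sweeps(trace)
  wins <- analysis_windows(sweeps, fs, window = window, origin = origin)
  bf <- NULL
  if (!is.null(lowpass_khz)) {
    wc <- 2 * lowpass_khz * 1000 / fs
    if (wc < 1) bf <- signal::butter(4, wc, type = "low")
  }
  res <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    xs <- trace$current[(wins$start[i] + 1L):wins$end[i]]
    if (!is.null(bf)) xs <- as.numeric(signal::filtfilt(bf, xs))
    bl <- estimate_baseline(xs)
    res[[i]] <- detect_events(xs, bl, fs, n_sigma = n_sigma,
                              merge_gap_ms = merge_gap_ms,
                              t0 = trace$start_time + wins$start[i] / fs,
                              sweep_index = wins$sweep_index[i],
                              polarity = polarity,
                              dwell_method = dwell_method,
                              smooth_ms = smooth_ms)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(sweep = integer(), onset_s = numeric(),
                      peak_s = numeric(), amp_nA = numeric(),
                      dwell_ms = numeric(), area_nAms = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Write / read an event table
#'
#' TSV with header `sweep onset_s peak_s amp_nA dwell_ms area_nAms`.
#'
#' @param events Event data.frame from [detect_events()]/[detect_experiment()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   events data.frame.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events),
            identical(names(events),
                      c("sweep", "onset_s", "peak_s", "amp_nA",
                        "dwell_ms", "area_nAms")))
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) .fail("event table not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  expected <- c("sweep", "onset_s", "peak_s", "amp_nA", "dwell_ms", "area_nAms")
  if (!identical(names(df), expected)) {
    .fail("unexpected event-table columns: ", paste(names(df), collapse = ", "))
  }
  df
}
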