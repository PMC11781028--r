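#' Assign events to one-minute bins
#'
#' Minute `k` (1-based) covers onset times in `[(k-1)*60, k*60)` seconds.
#' Empty bins are retained so that unusable minutes propagate as missing,
#' never as zero probability.
#'
#' @param events Event data.frame with columns `onset_s` and `amp_nA`.
#' @param n_minutes Number of bins; defaults to the last occupied minute.
#' @return List of numeric amplitude vectors, one per minute, named "1", "2", ...
#' @export
bin_by_minute <- function(events, n_minutes = NULL) {
  stopifnot(is.data.frame(events),
            all(c("onset_s", "amp_nA") %in% names(events)))
  minute <- floor(events$onset_s / 60) + 1L
  if (is.null(n_minutes)) n_minutes <- if (nrow(events)) max(minute) else 1L
  bins <- vector("list", n_minutes)
  for (k in seq_len(n_minutes)) bins[[k]] <- events$amp_nA[minute == k]
  names(bins) <- as.character(seq_len(n_minutes))
  bins
}

#' Shared amplitude grid for per-minute PDFs
#'
#' A uniform grid over `[0, pad * max(amplitude)]` used by every minute of
#' an experiment, so that fixed boundaries index consistently across PDFs.
#'
#' @param amplitudes All event amplitudes of the experiment (nA).
#' @param n Grid size, default 512.
#' @param pad Upper padding factor, default 1.2.
#' @param upper Optional minimum upper limit (nA), e.g. to guarantee that
#'   externally supplied boundaries stay inside the grid.
#' @return Numeric grid vector.
#' @export
amplitude_grid <- function(amplitudes, n = 512L, pad = 1.2, upper = NULL) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (!length(amplitudes)) .fail("no finite amplitudes to build a grid from")
  seq(0, max(pad * max(amplitudes), upper %||% 0), length.out = n)
}

#' Kernel density estimate of a minute's amplitudes
#'
#' Gaussian-kernel KDE evaluated on a fixed grid; the bandwidth follows
#' Scott's rule `sd(x) * n^(-1/5)` unless overridden. The density is
#' renormalised so its trapezoidal integral over the grid is exactly 1.
#'
#' @param amplitudes Event peak amplitudes (nA) of one minute.
#' @param grid Shared grid from [amplitude_grid()].
#' @param bw Optional fixed bandwidth (nA); `NULL` applies Scott's rule.
#' @param min_events Minimum events for a usable estimate, default 10;
#'   below it the minute is unusable and `NULL` is returned (probability
#'   undefined, not zero).
#' @return List of class `binned_pdf` (`grid`, `density`, `bw`, `n`), or
#'   `NULL` for an unusable minute.
#' @export
estimate_pdf <- function(amplitudes, grid, bw = NULL, min_events = 10L) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < min_events) return(NULL)
  if (is.null(bw)) {
    bw <- sd(amplitudes) * length(amplitudes)^(-1 / 5)
  }
  if (!is.finite(bw) || bw <= 0) {
    .fail("bandwidth must be positive; supply 'bw' for degenerate samples")
  }
  # mean of per-event Gaussian kernels, column-wise over the grid
  d <- vapply(grid, function(g) mean(dnorm(g, amplitudes, bw)), 0)
  z <- pracma::trapz(grid, d)
  if (z <= 0) .fail("degenerate density (zero mass on grid)")
  structure(list(grid = grid, density = d / z, bw = bw,
                 n = length(amplitudes)),
            class = "binned_pdf")
}

# topographic prominence of local maxima of a sampled curve
.peak_prominence <- function(d) {
  n <- length(d)
  idx <- which(diff(sign(diff(d))) < 0) + 1L
  if (d[1] > d[2]) idx <- c(1L, idx)
  if (d[n] > d[n - 1]) idx <- c(idx, n)
  prom <- vapply(idx, function(i) {
    left <- if (i > 1) d[1:(i - 1)] else numeric()
    right <- if (i < n) d[(i + 1):n] else numeric()
    hi_l <- which(left >= d[i])
    base_l <- if (length(hi_l)) min(d[(max(hi_l) + 1):(i)]) else
      if (length(left)) min(left) else d[i]
    hi_r <- which(right >= d[i])
    base_r <- if (length(hi_r)) min(d[i:(i + min(hi_r) - 1)]) else
      if (length(right)) min(right) else d[i]
    d[i] - max(base_l, base_r)
  }, 0)
  data.frame(index = idx, density = d[idx], prominence = prom)
}

#' Locate the reactant reference peak of a PDF
#'
#' The reactant (3 kbp) population always sits at the higher amplitude, so
#' the default rule picks the highest-amplitude local maximum whose
#' topographic prominence is at least `prominence_frac` of the global
#' density maximum — not the globally densest mode, which may already be the
#' product. `rule = "global_max"` selects the densest qualifying mode
#' instead.
#'
#' @param pdf A `binned_pdf` from [estimate_pdf()].
#' @param expected_region Optional `c(lo, hi)` (nA) restricting candidates.
#' @param prominence_frac Prominence floor as a fraction of the global
#'   maximum, default 0.1.
#' @param rule `"highest_amplitude"` (default) or `"global_max"`.
#' @return Peak amplitude location (nA).
#' @export
find_reference_peak <- function(pdf, expected_region = NULL,
                                prominence_frac = 0.1,
                                rule = c("highest_amplitude", "global_max")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pdf, "binned_pdf"))
  cand <- .peak_prominence(pdf$density)
  cand$amp <- pdf$grid[cand$index]
  ok <- cand$prominence >= prominence_frac * max(pdf$density)
  if (!is.null(expected_region)) {
    ok <- ok & cand$amp >= expected_region[1] & cand$amp <= expected_region[2]
  }
  if (!any(ok)) {
    .fail("no qualifying reference peak; candidate maxima (nA @ density): ",
          paste(sprintf("%.4g @ %.3g", cand$amp, cand$density),
                collapse = ", "))
  }
  sel <- cand[ok, ]
  if (rule == "highest_amplitude") sel$amp[which.max(sel$amp)]
  else sel$amp[which.max(sel$density)]
}

#' Fixed integration boundaries around a reference peak
#'
#' The boundaries are `(1 - fraction)` and `(1 + fraction)` times the
#' reference peak (default +-10%), fixed once — from the minute-1 PDF in
#' the standard pipeline — and applied to every minute.
#'
#' @param reference_peak Reference peak amplitude (nA).
#' @param fraction Half-width as a fraction of the peak, default 0.1.
#' @param source_minute Minute the peak came from (metadata), default 1.
#' @return List of class `boundaries`: `lower`, `upper`, `reference_peak`,
#'   `fraction`, `source_minute`.
#' @export
define_boundaries <- function(reference_peak, fraction = 0.1,
                              source_minute = 1L) {
  .check_num(reference_peak, "reference_peak", lower = 0, strict_lower = TRUE)
  .check_num(fraction, "fraction", lower = 0, upper = 1)
  structure(list(lower = (1 - fraction) * reference_peak,
                 upper = (1 + fraction) * reference_peak,
                 reference_peak = reference_peak,
                 fraction = fraction,
                 source_minute = as.integer(source_minute)),
            class = "boundaries")
}

#' Probability mass of a PDF between two boundaries
#'
#' 100 times the trapezoidal integral of the density over
#' `[lower, upper]`, with linear interpolation of the density at the exact
#' boundary positions. Boundaries must lie inside the grid.
#'
#' @param pdf A `binned_pdf`.
#' @param lower,upper Integration boundaries (nA), or pass a `boundaries`
#'   object as `lower`.
#' @return Probability in percent, in \[0, 100\].
#' @export
probability_between <- function(pdf, lower, upper = NULL) {
  stopifnot(inherits(pdf, "binned_pdf"))
  if (inherits(lower, "boundaries")) {
    upper <- lower$upper
    lower <- lower$lower
  }
  g <- pdf$grid
  if (lower < g[1] || upper > g[length(g)]) {
    .fail("boundaries [", lower, ", ", upper, "] fall outside the PDF grid [",
          g[1], ", ", g[length(g)], "]")
  }
  if (upper <= lower) return(0)
  inner <- g[g > lower & g < upper]
  xs <- c(lower, inner, upper)
  ds <- approx(g, pdf$density, xout = xs)$y
  p <- 100 * pracma::trapz(xs, ds)
  min(max(p, 0), 100)
}

#' Per-minute probability of detecting the reactant
#'
#' The core population statistic of the assay: per-minute Gaussian KDEs of
#' event peak amplitudes on a shared grid; boundaries fixed at +-`fraction`
#' of the reference (reactant) peak of the `source_minute` PDF; the reported
#' probability is the AUC between those boundaries for every minute. The
#' starting percentage depends on the boundary width, so the boundaries are
#' carried as metadata. Minutes with fewer than `min_events` events yield
#' `NA` (unusable, not zero).
#'
#' For samples that contain no reactant population at all (e.g. a
#' pre-digested control), pass externally determined `boundaries` — such as
#' those of a matched undigested reference — since no minute of such a
#' sample can define a reactant peak.
#'
#' @param events Event data.frame (`onset_s`, `amp_nA`).
#' @param n_minutes Number of minutes; defaults to the last occupied minute.
#' @param source_minute Minute whose PDF defines the boundaries, default 1.
#' @param fraction Boundary half-width fraction, default 0.1.
#' @param boundaries Optional pre-computed [define_boundaries()] object;
#'   overrides `source_minute`/`fraction`.
#' @param min_events Minimum events per usable minute, default 10.
#' @param bw Optional fixed KDE bandwidth (nA).
#' @param grid_n Grid size, default 512.
#' @param expected_region,peak_rule,prominence_frac Passed to
#'   [find_reference_peak()].
#' @return data.frame of class `probability_series`: `minute`, `n_events`,
#'   `probability_pct` (NA when unusable), `lower_nA`, `upper_nA`; the
#'   `boundaries` and shared `grid` are attached as attributes.
#' @export
probability_series <- function(events, n_minutes = NULL, source_minute = 1L,
                               fraction = 0.1, boundaries = NULL,
                               min_events = 10L, bw = NULL, grid_n = 512L,
                               expected_region = NULL,
                               peak_rule = "highest_amplitude",
                               prominence_frac = 0.1) {
  bins <- bin_by_minute(events, n_minutes = n_minutes)
  grid <- amplitude_grid(events$amp_nA, n = grid_n,
                         upper = if (!is.null(boundaries))
                           1.05 * boundaries$upper)
  pdfs <- lapply(bins, estimate_pdf, grid = grid, bw = bw,
                 min_events = min_events)
  if (is.null(boundaries)) {
    src <- pdfs[[source_minute]]
    if (is.null(src)) {
      usable <- which(!vapply(pdfs, is.null, TRUE))
      .fail("source minute ", source_minute, " has fewer than ", min_events,
            " events; first usable minute is ",
            if (length(usable)) usable[1] else "none")
    }
    pk <- find_reference_peak(src, expected_region = expected_region,
                              prominence_frac = prominence_frac,
                              rule = peak_rule)
    boundaries <- define_boundaries(pk, fraction = fraction,
                                    source_minute = source_minute)
  } else {
    stopifnot(inherits(boundaries, "boundaries"))
  }
  prob <- vapply(pdfs, function(p) {
    if (is.null(p)) NA_real_ else probability_between(p, boundaries)
  }, 0)
  out <- data.frame(minute = seq_along(bins),
                    n_events = vapply(bins, length, 0L),
                    probability_pct = unname(prob),
                    lower_nA = boundaries$lower,
                    upper_nA = boundaries$upper)
  attr(out, "boundaries") <- boundaries
  attr(out, "grid") <- grid
  class(out) <- c("probability_series", "data.frame")
  out
}

#' Write a probability series as TSV
#'
#' Columns `minute, n_events, probability_pct, lower_nA, upper_nA`.
#'
#' @param series A [probability_series()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_series <- function(series, path) {
  stopifnot(inherits(series, "probability_series"))
  data.table::fwrite(as.data.frame(series), path, sep = "\t")
  invisible(path)
}
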