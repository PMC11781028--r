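#' Initial-velocity fit of a probability series
#'
#' Ordinary least squares of probability (%) against minute over a time
#' window — by default the first 15 minutes, the initial-velocity region of
#' the digestion progress curve. The slope (percentage points per minute)
#' is the assay's rate statistic: the change in the probability of
#' detecting the reactant per unit time. Unusable (NA) minutes inside the
#' window are dropped, not interpolated. The reported `rate` is the
#' negated slope, positive for an active digestion.
#'
#' @param series A [probability_series()] result (or data.frame with
#'   `minute` and `probability_pct`).
#' @param window Inclusive minute range, default `c(1, 15)`.
#' @return List of class `kinetic_fit`: `slope`, `intercept`,
#'   `stderr_slope`, `r_squared`, `rate`, `window`, `n_points`,
#'   `degenerate`. A zero-variance response gives slope 0 and
#'   `r_squared = 0` with `degenerate = TRUE`.
#' @export
fit_initial_velocity <- function(series, window = c(1, 15)) {
  stopifnot(is.data.frame(series),
            all(c("minute", "probability_pct") %in% names(series)),
            length(window) == 2L, window[1] <= window[2])
  d <- series[series$minute >= window[1] & series$minute <= window[2] &
                !is.na(series$probability_pct), , drop = FALSE]
  if (nrow(d) < 3L) {
    .fail("initial-velocity fit needs >= 3 usable minutes in [",
          window[1], ", ", window[2], "]; got ", nrow(d))
  }
  degenerate <- var(d$probability_pct) == 0
  if (degenerate) {
    fit <- list(slope = 0, intercept = d$probability_pct[1],
                stderr_slope = 0, r_squared = 0)
  } else {
    m <- lm(probability_pct ~ minute, data = d)
    sm <- summary(m)
    fit <- list(slope = unname(coef(m)[2]),
                intercept = unname(coef(m)[1]),
                stderr_slope = unname(sm$coefficients[2, 2]),
                r_squared = sm$r.squared)
  }
  structure(c(fit, list(rate = -fit$slope, window = window,
                        n_points = nrow(d), degenerate = degenerate)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> slope m = %.3f %%/min (SE %.3f), rate = %.3f, R2 = %.3f, minutes %g-%g (n = %d)%s\n",
    x$slope, x$stderr_slope, x$rate, x$r_squared,
    x$window[1], x$window[2], x$n_points,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Reaction rate versus enzyme concentration
#'
#' Averages the replicate initial-velocity rates (negated slopes) at each
#' enzyme amount, reports the standard error of the mean across replicates,
#' and fits an ordinary least-squares line through (units, mean rate). For
#' a multi-turnover enzyme the cleavage activity is expected to scale with
#' the amount of enzyme.
#'
#' @param units Numeric vector of enzyme amounts, at least 3 distinct.
#' @param fits List (parallel to `units`) of lists of `kinetic_fit`
#'   replicates.
#' @return List of class `rate_curve`: `table` (data.frame `enzyme_units`,
#'   `mean_rate`, `sem_rate`, `n_replicates`), `slope`, `intercept`,
#'   `r_squared`.
#' @export
rate_vs_concentration <- function(units, fits) {
  stopifnot(is.numeric(units), is.list(fits), length(units) == length(fits))
  if (length(unique(units)) < 3L) {
    .fail("need at least 3 distinct enzyme concentrations (got ",
          length(unique(units)), ")")
  }
  rates <- lapply(fits, function(fl) {
    stopifnot(length(fl) >= 1L,
              all(vapply(fl, inherits, TRUE, "kinetic_fit")))
    vapply(fl, `[[`, 0, "rate")
  })
  tab <- data.frame(
    enzyme_units = units,
    mean_rate = vapply(rates, mean, 0),
    sem_rate = vapply(rates, function(r) {
      if (length(r) > 1L) sd(r) / sqrt(length(r)) else NA_real_
    }, 0),
    n_replicates = vapply(rates, length, 0L))
  m <- lm(mean_rate ~ enzyme_units, data = tab)
  structure(list(table = tab,
                 slope = unname(coef(m)[2]),
                 intercept = unname(coef(m)[1]),
                 r_squared = summary(m)$r.squared),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate_curve> rate = %.4f * units %+.4f, R2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Classify a condition from its fitted slope
#'
#' Mirrors the slope criteria used to read the progress curves: a condition
#' is `inactive` when the fitted slope m exceeds -0.1 (controls), `active`
#' when m is below -1 (efficient cleavage), and `weakly_active` in between
#' (detectable but slow cleavage). Thresholds are configurable.
#'
#' @param fit A `kinetic_fit`, or a bare slope value.
#' @param inactive_above Slope above which the condition is inactive,
#'   default -0.1.
#' @param active_below Slope below which the condition is active, default -1.
#' @return One of `"inactive"`, `"weakly_active"`, `"active"`.
#' @export
classify_condition <- function(fit, inactive_above = -0.1, active_below = -1) {
  m <- if (inherits(fit, "kinetic_fit")) fit$slope else fit
  .check_num(m, "slope")
  if (m > inactive_above) "inactive"
  else if (m < active_below) "active"
  else "weakly_active"
}
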