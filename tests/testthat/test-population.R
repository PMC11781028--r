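# per-minute KDE probability densities and boundary-bounded AUC

test_that("minute binning follows the half-open convention", {
  ev <- data.frame(onset_s = c(10, 59.999, 60, 70, 150), amp_nA = 1:5 / 10)
  bins <- bin_by_minute(ev)
  expect_identical(length(bins), 3L)
  expect_equal(bins[["1"]], c(0.1, 0.2))
  expect_equal(bins[["2"]], c(0.3, 0.4))  # an event at exactly 60 s -> bin 2
  expect_equal(bins[["3"]], 0.5)
  # empty bins are retained
  bins4 <- bin_by_minute(ev, n_minutes = 5L)
  expect_identical(length(bins4), 5L)
  expect_identical(bins4[["4"]], numeric(0))
})

test_that("uniform arrivals spread evenly over minute bins", {
  set.seed(201)
  ev <- data.frame(onset_s = runif(600, 0, 600), amp_nA = rnorm(600, 0.2, 0.02))
  counts <- vapply(bin_by_minute(ev, 10L), length, 0L)
  expect_true(all(abs(counts - 60) < 4 * sqrt(60)))
})

test_that("KDE recovers a known generating distribution", {
  set.seed(202)
  amps <- rnorm(5000, 0.25, 0.02)
  grid <- amplitude_grid(amps)
  pdf <- estimate_pdf(amps, grid)
  expect_s3_class(pdf, "binned_pdf")
  mode <- grid[which.max(pdf$density)]
  expect_lt(abs(mode - 0.25), 0.005)
  # Scott's rule bandwidth
  expect_equal(pdf$bw, sd(amps) * 5000^(-1 / 5), tolerance = 1e-12)
})

test_that("every usable PDF integrates to one; sparse minutes are unusable", {
  set.seed(203)
  for (rep in 1:20) {
    n <- sample(10:500, 1)
    amps <- abs(rnorm(n, runif(1, 0.1, 0.3), runif(1, 0.005, 0.05)))
    grid <- amplitude_grid(amps)
    pdf <- estimate_pdf(amps, grid)
    expect_lt(abs(pracma::trapz(pdf$grid, pdf$density) - 1), 1e-3)
    expect_true(all(pdf$density >= 0))
  }
  expect_null(estimate_pdf(rnorm(5, 0.2, 0.01), seq(0, 1, length.out = 512)))
})

test_that("a repeated value with a fixed bandwidth gives the kernel back", {
  pdf <- estimate_pdf(rep(0.2, 50), seq(0, 0.4, length.out = 512), bw = 0.01)
  mode <- pdf$grid[which.max(pdf$density)]
  expect_lt(abs(mode - 0.2), diff(pdf$grid[1:2]))
  # symmetric around the value
  left <- probability_between(pdf, 0.15, 0.2)
  right <- probability_between(pdf, 0.2, 0.25)
  expect_lt(abs(left - right), 0.5)
  # and Scott's rule alone cannot handle the degenerate sample
  expect_error(estimate_pdf(rep(0.2, 50), pdf$grid), "bandwidth")
})

test_that("reference peak follows the higher-amplitude-mode rule", {
  set.seed(204)
  grid <- seq(0, 0.4, length.out = 512)
  mk <- function(n_r, n_p) {
    estimate_pdf(c(rnorm(n_r, 0.25, 0.02), rnorm(n_p, 0.15, 0.015)),
                 grid, bw = 0.008)
  }
  # balanced mixture: reactant mode wins by amplitude
  expect_lt(abs(find_reference_peak(mk(2000, 2000)) - 0.25), 0.01)
  # product-dominated mixture: still the reactant mode (amplitude rule,
  # not density rule) ...
  pdf_dom <- mk(800, 3200)
  expect_lt(abs(find_reference_peak(pdf_dom) - 0.25), 0.01)
  # ... while the global-max rule would pick the product mode
  expect_lt(abs(find_reference_peak(pdf_dom, rule = "global_max") - 0.15),
            0.01)
  # unimodal sample: its own mode
  pdf_uni <- estimate_pdf(rnorm(3000, 0.30, 0.02), grid, bw = 0.008)
  expect_lt(abs(find_reference_peak(pdf_uni) - 0.30), 0.01)
  # no qualifying peak in a restricted region -> informative error
  expect_error(find_reference_peak(pdf_uni, expected_region = c(0.01, 0.05)),
               "candidate maxima")
})

test_that("boundaries sit at +-10% of the reference peak", {
  b <- define_boundaries(0.25)
  expect_equal(b$lower, 0.225)
  expect_equal(b$upper, 0.275)
  b2 <- define_boundaries(0.30, fraction = 0.2)
  expect_equal(c(b2$lower, b2$upper), c(0.24, 0.36))
})

test_that("full-support probability is 100%, zero width is 0%", {
  set.seed(205)
  amps <- rnorm(2000, 0.25, 0.02)
  pdf <- estimate_pdf(amps, amplitude_grid(amps))
  g <- pdf$grid
  expect_lt(abs(probability_between(pdf, g[1], g[length(g)]) - 100), 0.1)
  expect_identical(probability_between(pdf, 0.25, 0.25), 0)
  expect_error(probability_between(pdf, -0.1, 0.2), "outside the PDF grid")
})

test_that("boundary AUC matches the Gaussian CDF oracle", {
  set.seed(206)
  amps <- rnorm(5000, 0.25, 0.02)
  pdf <- estimate_pdf(amps, amplitude_grid(amps))
  p <- probability_between(pdf, 0.225, 0.275)
  # N(0.25, 0.02) mass in +-1.25 sd, KDE smoothing widens slightly
  expect_lt(abs(p - 100 * (2 * pnorm(1.25) - 1)), 1)
})

test_that("probability_between agrees with the kernel-CDF mass oracle", {
  set.seed(207)
  amps <- c(rnorm(1500, 0.25, 0.02), rnorm(1500, 0.15, 0.015))
  pdf <- estimate_pdf(amps, amplitude_grid(amps))
  g <- pdf$grid
  for (i in 1:100) {
    b <- sort(runif(2, g[1], g[length(g)]))
    expect_lt(abs(probability_between(pdf, b[1], b[2]) -
                    kernel_mass_pct(amps, pdf$bw, b[1], b[2])),
              0.1)
  }
})

test_that("widening the boundaries never decreases the probability", {
  set.seed(208)
  amps <- rnorm(800, 0.2, 0.03)
  pdf <- estimate_pdf(amps, amplitude_grid(amps))
  widths <- seq(0.005, 0.12, by = 0.005)
  probs <- vapply(widths,
                  function(w) probability_between(pdf, 0.2 - w, 0.2 + w), 0)
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("the pipeline is equivariant under amplitude rescaling", {
  ev <- synth_events(80, 10, reactant_share = 0.6, seed = 209)
  s1 <- probability_series(ev)
  ev2 <- ev
  ev2$amp_nA <- 3 * ev2$amp_nA
  s2 <- probability_series(ev2)
  b1 <- attr(s1, "boundaries"); b2 <- attr(s2, "boundaries")
  expect_equal(b2$reference_peak, 3 * b1$reference_peak, tolerance = 1e-9)
  expect_equal(s2$probability_pct, s1$probability_pct, tolerance = 1e-6)
})

test_that("product-only events stay below the reactant boundaries", {
  ev <- synth_events(100, 10, reactant_share = 0, seed = 210)
  b <- define_boundaries(0.25)
  ser <- probability_series(ev, boundaries = b)
  expect_true(all(ser$probability_pct <= 15))
})

test_that("a digesting mixture gives a monotonically falling series", {
  u <- uncleaved_fraction(
    kinetics_spec("first_order_multi_turnover", k = 0.1, enzyme_units = 1),
    (1:30) - 0.5)
  ev <- synth_events(150, 30, reactant_share = reactant_molar_share(u),
                     seed = 211)
  ser <- probability_series(ev)
  rho <- suppressWarnings(
    stats::cor(ser$minute, ser$probability_pct, method = "spearman"))
  expect_lt(rho, -0.9)
})

test_that("a stationary mixture shows no trend beyond sampling noise", {
  n_per_min <- 200
  ev <- synth_events(n_per_min, 30, reactant_share = 0.6, seed = 212)
  ser <- probability_series(ev)
  p_hat <- mean(ser$probability_pct) / 100
  # band-mass noise is binomial-like: range over 30 minutes within 6 sd
  binom_sd <- 100 * sqrt(p_hat * (1 - p_hat) / n_per_min)
  expect_lt(diff(range(ser$probability_pct)), 6 * binom_sd)
  fit <- fit_initial_velocity(ser, window = c(1, 30))
  expect_lt(abs(fit$slope), 3 * fit$stderr_slope)
})

test_that("an unusable source minute is reported with an alternative", {
  ev <- synth_events(50, 5, reactant_share = 0.6, seed = 213)
  ev <- ev[ev$onset_s >= 60, ]  # empty minute 1
  expect_error(probability_series(ev, n_minutes = 5),
               "first usable minute is 2")
})

test_that("probability series round-trips as TSV", {
  ev <- synth_events(60, 5, reactant_share = 0.7, seed = 214)
  ser <- probability_series(ev)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probability_series(ser, path)
  back <- as.data.frame(data.table::fread(path))
  expect_identical(names(back),
                   c("minute", "n_events", "probability_pct",
                     "lower_nA", "upper_nA"))
  expect_equal(back$probability_pct, ser$probability_pct, tolerance = 1e-12)
})
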