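# baseline estimation and conductive-pulse detection

test_that("baseline estimator recovers known noise parameters", {
  set.seed(101)
  x <- rnorm(1e5, 0, 0.01)
  bl <- estimate_baseline(x)
  expect_lt(abs(bl$mean), 0.001)
  expect_lt(abs(bl$sigma - 0.01), 0.001)
  expect_error(estimate_baseline(rnorm(500)), "at least 1000")
  expect_error(estimate_baseline(rep(1, 2000)), "degenerate")
})

test_that("baseline sigma is robust to a large event, unlike a plain SD", {
  set.seed(102)
  x <- rnorm(1e5, 0, 0.01)
  x[40000:40999] <- x[40000:40999] + 0.5   # 50 sigma, 1% duty
  bl <- estimate_baseline(x)
  expect_lt(abs(bl$sigma - 0.01) / 0.01, 0.10)
  expect_gt(sd(x) / 0.01, 1.5)  # the naive estimator is blown up
})

test_that("a single injected pulse is measured accurately", {
  fs <- 1e5
  set.seed(103)
  x <- rnorm(fs, 0, 0.01)  # 1 s window
  sd_n <- 0.2e-3 * fs / (2 * sqrt(2 * log(2)))  # FWHM 0.2 ms
  i0 <- 50000
  x <- x + 0.2 * exp(-0.5 * ((seq_along(x) - i0) / sd_n)^2)  # 20 sigma
  bl <- estimate_baseline(x)
  ev <- detect_events(x, bl, fs)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$amp_nA - 0.2) / 0.2, 0.10)
  expect_lt(abs(ev$dwell_ms - 0.2) / 0.2, 0.15)
  expect_lt(abs(ev$peak_s - (i0 - 1) / fs), 1e-4)
  expect_gt(ev$area_nAms, 0)
})

test_that("pure baseline yields zero events at the 10-sigma threshold", {
  set.seed(104)
  for (rep in 1:5) {
    x <- rnorm(5e5, 5, 0.01)  # one full 5 s window at 100 kHz
    ev <- detect_events(x, estimate_baseline(x), 1e5)
    expect_identical(nrow(ev), 0L)
  }
})

test_that("raising the threshold never increases the event count", {
  fs <- 25000
  set.seed(105)
  x <- rnorm(fs * 5, 0, 0.01)
  centers <- seq(10000, 120000, by = 2500)
  amps <- seq(0.05, 0.3, length.out = length(centers))
  sd_n <- 0.2e-3 * fs / 2.3548
  for (i in seq_along(centers)) {
    idx <- (centers[i] - 30):(centers[i] + 30)
    x[idx] <- x[idx] + amps[i] * exp(-0.5 * ((idx - centers[i]) / sd_n)^2)
  }
  bl <- estimate_baseline(x)
  counts <- vapply(c(4, 6, 8, 10, 14, 20),
                   function(ns) nrow(detect_events(x, bl, fs, n_sigma = ns)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("amplitudes are scale-equivariant, dwells invariant", {
  fs <- 25000
  set.seed(106)
  x <- rnorm(fs * 5, 2, 0.01)
  sd_n <- 0.2e-3 * fs / 2.3548
  for (c0 in c(30000, 70000, 110000)) {
    idx <- (c0 - 30):(c0 + 30)
    x[idx] <- x[idx] + 0.25 * exp(-0.5 * ((idx - c0) / sd_n)^2)
  }
  ev1 <- detect_events(x, estimate_baseline(x), fs)
  cs <- 3.7
  ev2 <- detect_events(cs * x, estimate_baseline(cs * x), fs)
  expect_identical(nrow(ev2), nrow(ev1))
  expect_equal(ev2$amp_nA, cs * ev1$amp_nA, tolerance = 1e-8)
  expect_equal(ev2$dwell_ms, ev1$dwell_ms, tolerance = 1e-8)
})

test_that("nearby threshold crossings are merged into one event", {
  fs <- 1e5
  set.seed(107)
  x <- rnorm(fs, 0, 0.01)
  # two lobes 0.05 ms apart (< merge_gap 0.1 ms) from one molecule
  for (c0 in c(50000, 50005)) {
    idx <- (c0 - 25):(c0 + 25)
    x[idx] <- x[idx] + 0.2 * exp(-0.5 * ((idx - c0) / 4)^2)
  }
  bl <- estimate_baseline(x)
  expect_identical(nrow(detect_events(x, bl, fs)), 1L)
  # with a tiny merge gap they separate (two crossings only if the dip
  # actually crosses the threshold, so use a deep valley variant)
  x2 <- rnorm(fs, 0, 0.01)
  for (c0 in c(50000, 50040)) {
    idx <- (c0 - 12):(c0 + 12)
    x2[idx] <- x2[idx] + 0.2 * exp(-0.5 * ((idx - c0) / 3)^2)
  }
  bl2 <- estimate_baseline(x2)
  expect_identical(nrow(detect_events(x2, bl2, fs, merge_gap_ms = 0.01)), 2L)
  expect_identical(nrow(detect_events(x2, bl2, fs, merge_gap_ms = 1)), 1L)
})

test_that("detection recovers per-species amplitude means within 5%", {
  cfg <- quick_config(seed = 31L, n_loops = 25L, sampling_rate = 1e5,
                      capture_rate = 2, initial_fractions = c(0.5, 0.5))
  sim <- generate_experiment(cfg)
  ev <- detect_experiment(sim$trace)
  gtw <- gt_in_windows(sim$ground_truth$events)
  m <- match_to_ground_truth(ev, gtw)
  det_amp <- ev$amp_nA[m$matched_det]
  det_t <- ev$peak_s[m$matched_det]
  sp <- gtw$species[vapply(det_t, function(t) which.min(abs(gtw$time_s - t)), 0L)]
  for (s in unique(sp)) {
    injected <- mean(gtw$amp_nA[gtw$species == s])
    recovered <- mean(det_amp[sp == s])
    expect_lt(abs(recovered - injected) / injected, 0.05)
  }
})

test_that("event tables round-trip through TSV", {
  cfg <- quick_config(seed = 17L, n_loops = 8L)
  ev <- detect_experiment(generate_experiment(cfg)$trace)
  expect_gt(nrow(ev), 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back, ev, tolerance = 1e-12)
  expect_identical(nrow(back), nrow(ev))
  write_events(ev[0, ], path)
  expect_identical(nrow(read_events(path)), 0L)
})
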