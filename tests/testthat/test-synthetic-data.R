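# the ground-truthed experiment generator

test_that("identical configs give bit-identical traces and ground truth", {
  cfg <- quick_config(seed = 42L, n_loops = 3L)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$trace$current, b$trace$current)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
})

test_that("zero capture rate yields a pure-baseline trace", {
  cfg <- quick_config(seed = 3L, n_loops = 4L, capture_rate = 0)
  sim <- generate_experiment(cfg)
  expect_identical(nrow(sim$ground_truth$events), 0L)
  # nothing but Gaussian noise: no sample anywhere near a pulse amplitude
  expect_lt(max(abs(sim$trace$current - cfg$baseline_mean)),
            6 * cfg$baseline_sigma)
})

test_that("event count matches the Poisson expectation of the config", {
  # 10-minute run: 64 sweeps x 6 s capture at 2 events/s -> mean 768
  cfg <- quick_config(seed = 11L, n_loops = 64L, capture_rate = 2)
  sim <- generate_experiment(cfg)
  mu <- 2 * 6 * 64
  expect_lt(abs(nrow(sim$ground_truth$events) - mu), 4 * sqrt(mu))
})

test_that("trace length and event placement respect the waveform", {
  cfg <- quick_config(seed = 5L, n_loops = 6L)
  sim <- generate_experiment(cfg)
  wf <- cfg$waveform
  expect_identical(length(sim$trace$current),
                   as.integer(round(waveform_period(wf) * cfg$sampling_rate)) *
                     wf$n_loops)
  # no injected event (centre) inside a rest phase
  phase <- sim$ground_truth$events$time_s %% waveform_period(wf)
  expect_true(all(phase >= wf$rest_duration))
  # and the trace is quiet during every rest phase (no pulse leakage)
  rest_n <- round(wf$rest_duration * cfg$sampling_rate)
  period_n <- round(waveform_period(wf) * cfg$sampling_rate)
  for (s in seq_len(wf$n_loops) - 1L) {
    rest <- sim$trace$current[(s * period_n + 1):(s * period_n + rest_n)]
    expect_lt(max(abs(rest - cfg$baseline_mean)), 6 * cfg$baseline_sigma)
  }
})

test_that("frozen mixture with burst kinetics gives the doubled-product share", {
  # burst_fraction 0.5 with k = 0 freezes f at 0.5 for all t, so the
  # reactant share among events must sit at f/(f+2(1-f)) = 1/3
  kin <- kinetics_spec("single_turnover_burst", k = 0, enzyme_units = 1,
                       burst_fraction = 0.5)
  cfg <- quick_config(seed = 8L, n_loops = 30L, capture_rate = 5,
                      kinetics = kin)
  sim <- generate_experiment(cfg)
  ev <- sim$ground_truth$events
  share <- mean(ev$species == "dsDNA_3kbp")
  expect_lt(abs(share - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / nrow(ev)))
})

test_that("injected amplitudes follow the species model (KS check)", {
  cfg <- quick_config(seed = 21L, n_loops = 40L, capture_rate = 9)
  sim <- generate_experiment(cfg)
  amps <- sim$ground_truth$events$amp_nA
  expect_gt(length(amps), 2000)
  ks <- suppressWarnings(stats::ks.test(amps, "pnorm", 0.25, 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("close events are flagged as collisions", {
  cfg <- quick_config(seed = 2L, n_loops = 40L, capture_rate = 12,
                      collision_warn_frac = 1)
  sim <- generate_experiment(cfg)
  ev <- sim$ground_truth$events
  gaps <- diff(ev$time_s)
  same_sweep <- diff(floor(ev$time_s / 9.5)) == 0
  tight <- which(same_sweep & gaps < 2e-3)
  expect_gt(length(tight), 0)
  expect_true(all(ev$collision[tight]))
  expect_true(all(ev$collision[tight + 1L]))
  # and an over-driven pore warns
  expect_warning(
    generate_experiment(quick_config(seed = 2L, n_loops = 3L,
                                     capture_rate = 120)),
    "collide")
})

test_that("ground truth round-trips through TSV", {
  cfg <- quick_config(seed = 9L, n_loops = 10L, capture_rate = 4)
  sim <- generate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$ground_truth, path)
  back <- read_ground_truth(path)
  expect_equal(back, sim$ground_truth$events, tolerance = 1e-12)
  expect_identical(nrow(back), nrow(sim$ground_truth$events))
  # empty ground truth stays a valid header-only table
  empty <- generate_experiment(quick_config(seed = 1L, n_loops = 2L,
                                            capture_rate = 0))$ground_truth
  write_ground_truth(empty, path)
  expect_identical(nrow(read_ground_truth(path)), 0L)
})

test_that("per-minute true fractions follow the kinetic law", {
  kin <- kinetics_spec("first_order_multi_turnover", k = 0.02,
                       enzyme_units = 10)
  cfg <- quick_config(seed = 4L, n_loops = 32L, kinetics = kin)
  gt <- generate_experiment(cfg)$ground_truth
  expect_equal(gt$uncleaved$uncleaved,
               uncleaved_fraction(kin, gt$uncleaved$minute - 0.5))
})
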