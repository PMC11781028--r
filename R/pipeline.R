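#' Read a pipeline configuration file
#'
#' YAML mirroring [simulation_config()] plus an `analysis` block with the
#' detection/quantification/kinetics thresholds. All keys are optional and
#' default to the assay's standard values (10 sigma threshold, 0.1 ms merge
#' gap, +-10% boundaries, minutes 1-15 window, slope thresholds -0.1/-1).
#' See `inst/extdata/demo_config.yaml` for a complete, commented example.
#'
#' @param path YAML file path.
#' @return List with elements `seed`, `simulation` (a [simulation_config()])
#'   and `analysis` (named list of thresholds).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .fail("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  sim <- cfg$simulation %||% list()
  wf_in <- sim$waveform %||% list()
  wf <- waveform_spec(
    capture_voltage = wf_in$capture_mV %||% -700,
    capture_duration = wf_in$capture_s %||% 6,
    rest_voltage = wf_in$rest_mV %||% 100,
    rest_duration = wf_in$rest_s %||% 3.5,
    n_loops = wf_in$n_loops %||% 190)
  kin_in <- sim$kinetics %||% list()
  kin <- kinetics_spec(
    model = kin_in$model %||% "none",
    k = kin_in$k_per_unit_min %||% 0.02,
    enzyme_units = kin_in$enzyme_units %||% 5,
    burst_fraction = kin_in$burst_fraction %||% 0,
    start_offset = kin_in$start_offset_min %||% 1)
  if (!is.null(sim$species)) {
    species <- lapply(sim$species, function(s) {
      species_model(s$name, s$length_kbp, s$amp_mean_nA, s$amp_sd_nA,
                    s$dwell_mean_ms, s$dwell_sd_ms,
                    capture_weight = s$capture_weight %||% 1)
    })
    fractions <- vapply(sim$species, function(s) s$fraction %||% 0, 0)
  } else {
    species <- default_species_models()
    fractions <- c(1, 0)
  }
  sc <- simulation_config(
    sampling_rate = sim$sampling_rate_hz %||% 1e5,
    baseline_mean = sim$baseline_mean_nA %||% 5,
    baseline_sigma = sim$baseline_sigma_nA %||% 0.01,
    capture_rate = sim$capture_rate_per_s %||% 2,
    species = species,
    initial_fractions = fractions,
    waveform = wf,
    kinetics = kin,
    seed = cfg$seed %||% 1L,
    pulse_shape = sim$pulse_shape %||% "gaussian")
  ana_in <- cfg$analysis %||% list()
  analysis <- list(
    n_sigma = ana_in$n_sigma %||% 10,
    merge_gap_ms = ana_in$merge_gap_ms %||% 0.1,
    boundary_fraction = ana_in$boundary_fraction %||% 0.1,
    min_events_per_minute = ana_in$min_events_per_minute %||% 10,
    kde_bw = ana_in$kde_bw_nA,
    prominence_frac = ana_in$prominence_frac %||% 0.1,
    window_min = unlist(ana_in$window_min %||% c(1, 15)),
    slope_inactive_above = ana_in$slope_inactive_above %||% -0.1,
    slope_active_below = ana_in$slope_active_below %||% -1,
    lowpass_khz = ana_in$lowpass_khz)
  list(seed = cfg$seed %||% 1L, simulation = sc, analysis = analysis)
}

#' Run the full simulate-detect-quantify-fit pipeline
#'
#' Executes the stages simulate -> segment/detect -> quantify -> fit ->
#' classify from a single configuration, writing stage outputs (TSV tables,
#' a JSON kinetic summary) and a run manifest with config snapshot, seed,
#' package version and per-file MD5 checksums. Re-running with an identical
#' config reproduces identical outputs.
#'
#' @param config Path to a YAML config file, or the list from
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @param write_trace Also write the full trace TSV (large), default FALSE.
#' @return The manifest list, invisibly. Stage failures propagate with the
#'   stage name prefixed.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, write_trace = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config$simulation, "simulation_config"))
  if (!is.null(seed)) config$simulation$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ana <- config$analysis
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .fail(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- stage("simulate", generate_experiment(config$simulation))
  paths <- list(ground_truth = file.path(out_dir, "ground_truth.tsv"),
                events = file.path(out_dir, "events.tsv"),
                probability = file.path(out_dir, "probability.tsv"),
                kinetics = file.path(out_dir, "kinetic_fit.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_ground_truth(sim$ground_truth, paths$ground_truth)
  if (write_trace) {
    paths$trace <- file.path(out_dir, "trace.tsv")
    write_trace(sim$trace, paths$trace)
  }

  events <- stage("detect", detect_experiment(
    sim$trace, n_sigma = ana$n_sigma, merge_gap_ms = ana$merge_gap_ms,
    lowpass_khz = ana$lowpass_khz))
  write_events(events, paths$events)

  wf <- config$simulation$waveform
  n_minutes <- max(1L, floor(wf$n_loops * waveform_period(wf) / 60))
  series <- stage("quantify", probability_series(
    events, n_minutes = n_minutes, fraction = ana$boundary_fraction,
    min_events = ana$min_events_per_minute, bw = ana$kde_bw,
    prominence_frac = ana$prominence_frac))
  write_probability_series(series, paths$probability)

  fit <- stage("kinetics", fit_initial_velocity(series, window = ana$window_min))
  cls <- classify_condition(fit, inactive_above = ana$slope_inactive_above,
                            active_below = ana$slope_active_below)
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept,
         stderr_slope = fit$stderr_slope, r_squared = fit$r_squared,
         rate = fit$rate, window = fit$window, n_points = fit$n_points,
         classification = cls),
    paths$kinetics, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = config$simulation$seed,
    package = "porekinetics",
    version = as.character(packageVersion("porekinetics")),
    config = .config_snapshot(config),
    classification = cls,
    files = lapply(paths[names(paths) != "manifest"], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate one digestion experiment and analyse it end to end
#'
#' Convenience wrapper chaining [generate_experiment()],
#' [detect_experiment()], [probability_series()] and
#' [fit_initial_velocity()] for a single seeded run — the unit of work when
#' measuring rates across enzyme concentrations or replicates.
#'
#' @param seed Integer seed for the generator.
#' @param kinetics A [kinetics_spec()].
#' @param minutes Experiment duration (min); the waveform loop count is
#'   chosen to cover it.
#' @param sampling_rate Sampling rate (Hz), default 100000.
#' @param capture_rate Capture-phase event rate (events/s), default 2.
#' @param initial_fractions Initial molar fractions (reactant, product).
#' @param window Fit window in minutes, default `c(1, 15)`.
#' @param bw,prominence_frac,boundaries Passed to [probability_series()].
#' @param n_sigma Detection threshold (sigmas), default 10.
#' @return List: `ground_truth`, `events`, `series`, `fit`.
#' @export
simulate_and_analyze <- function(seed, kinetics, minutes = 15,
                                 sampling_rate = 1e5, capture_rate = 2,
                                 initial_fractions = c(1, 0),
                                 window = c(1, 15), bw = NULL,
                                 prominence_frac = 0.1, boundaries = NULL,
                                 n_sigma = 10) {
  wf <- waveform_spec(n_loops = ceiling(minutes * 60 / 9.5))
  cfg <- simulation_config(sampling_rate = sampling_rate,
                           capture_rate = capture_rate,
                           initial_fractions = initial_fractions,
                           waveform = wf, kinetics = kinetics, seed = seed)
  sim <- generate_experiment(cfg)
  events <- detect_experiment(sim$trace, n_sigma = n_sigma)
  series <- probability_series(events, n_minutes = minutes, bw = bw,
                               prominence_frac = prominence_frac,
                               boundaries = boundaries)
  list(ground_truth = sim$ground_truth, events = events, series = series,
       fit = fit_initial_velocity(series, window = window))
}

#' Match detected events to ground-truth records
#'
#' Greedy nearest-neighbour matching of detected peak times against
#' injected event times within `tol_s`, for computing detection recall and
#' precision on synthetic experiments.
#'
#' @param detected Event data.frame from [detect_experiment()].
#' @param gt_events Ground-truth events data.frame (or `ground_truth`).
#' @param tol_s Matching tolerance (s), default 1 ms.
#' @return List: `n_matched`, `recall`, `precision`, `matched_gt` (logical
#'   per ground-truth row), `matched_det` (logical per detected row).
#' @export
match_to_ground_truth <- function(detected, gt_events, tol_s = 1e-3) {
  if (inherits(gt_events, "ground_truth")) gt_events <- gt_events$events
  gt_t <- gt_events$time_s
  det_t <- detected$peak_s
  matched_gt <- logical(length(gt_t))
  matched_det <- logical(length(det_t))
  if (length(gt_t) && length(det_t)) {
    for (i in order(det_t)) {
      j <- which(!matched_gt & abs(gt_t - det_t[i]) <= tol_s)
      if (length(j)) {
        j <- j[which.min(abs(gt_t[j] - det_t[i]))]
        matched_gt[j] <- TRUE
        matched_det[i] <- TRUE
      }
    }
  }
  list(n_matched = sum(matched_det),
       recall = if (length(gt_t)) mean(matched_gt) else NA_real_,
       precision = if (length(det_t)) mean(matched_det) else NA_real_,
       matched_gt = matched_gt, matched_det = matched_det)
}

# plain-list snapshot of a config for the manifest
.config_snapshot <- function(config) {
  sc <- config$simulation
  list(
    sampling_rate_hz = sc$sampling_rate,
    baseline_mean_nA = sc$baseline_mean,
    baseline_sigma_nA = sc$baseline_sigma,
    capture_rate_per_s = sc$capture_rate,
    pulse_shape = sc$pulse_shape,
    species = lapply(sc$species, unclass),
    initial_fractions = sc$initial_fractions,
    waveform = unclass(sc$waveform),
    kinetics = unclass(sc$kinetics),
    analysis = config$analysis)
}
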