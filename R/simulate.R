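#' Configuration of a synthetic nanopore experiment
#'
#' Bundles everything the generator needs: sampling, baseline noise, the
#' Poisson capture rate during capture phases, the species mixture with its
#' initial molar fractions, the voltage waveform and the digestion kinetics.
#'
#' @param sampling_rate Sampling rate (Hz), default 100000 (10 us).
#' @param baseline_mean Open-pore current level (nA), default 5.
#' @param baseline_sigma White-noise SD of the baseline (nA), default 0.01.
#' @param capture_rate Poisson event rate during capture phases (events/s).
#' @param species List of [species_model()]s; default reactant + product pair.
#' @param initial_fractions Initial molar fractions of `species` (sum to 1).
#' @param waveform A [waveform_spec()].
#' @param kinetics A [kinetics_spec()]. When the model is not `"none"`,
#'   exactly two species are required: the reactant first, the product second.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param pulse_shape `"gaussian"` (FWHM = dwell) or `"rectangular"`.
#' @param collision_limit_ms Events in the same sweep closer than this are
#'   flagged as collisions in the ground truth (merged in the trace), default 2.
#' @param collision_warn_frac Warn when the flagged fraction exceeds this.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 1e5,
                              baseline_mean = 5,
                              baseline_sigma = 0.01,
                              capture_rate = 2,
                              species = default_species_models(),
                              initial_fractions = c(1, 0),
                              waveform = waveform_spec(),
                              kinetics = kinetics_spec("none"),
                              seed = 1L,
                              pulse_shape = c("gaussian", "rectangular"),
                              collision_limit_ms = 2,
                              collision_warn_frac = 0.1) {
  pulse_shape <- match.arg(pulse_shape)
  .check_num(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  .check_num(baseline_sigma, "baseline_sigma", lower = 0, strict_lower = TRUE)
  .check_num(capture_rate, "capture_rate", lower = 0)
  stopifnot(inherits(waveform, "waveform_spec"),
            inherits(kinetics, "kinetics_spec"),
            is.list(species), length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "species_model")))
  if (length(initial_fractions) != length(species)) {
    .fail("'initial_fractions' must have one entry per species")
  }
  if (any(initial_fractions < 0) ||
      abs(sum(initial_fractions) - 1) > 1e-8) {
    .fail("'initial_fractions' must be non-negative and sum to 1")
  }
  if (kinetics$model != "none" && length(species) != 2L) {
    .fail("digestion kinetics require exactly two species (reactant, product)")
  }
  structure(list(sampling_rate = sampling_rate,
                 baseline_mean = baseline_mean,
                 baseline_sigma = baseline_sigma,
                 capture_rate = capture_rate,
                 species = species,
                 initial_fractions = initial_fractions,
                 waveform = waveform,
                 kinetics = kinetics,
                 seed = as.integer(seed),
                 pulse_shape = pulse_shape,
                 collision_limit_ms = collision_limit_ms,
                 collision_warn_frac = collision_warn_frac),
            class = "simulation_config")
}

# positive-truncated normal draws (vectorised rejection; means are many SDs
# above zero for realistic species so redraws are rare)
.rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a ground-truthed synthetic experiment
#'
#' Builds a full-length current trace (Gaussian baseline noise around
#' `baseline_mean`) and injects conductive pulses — positive deflections, as
#' the polymer-electrolyte setup increases conductance during translocation —
#' at Poisson arrival times restricted to capture phases. Each event's
#' species is drawn from the time-evolving molar mixture (one cleaved parent
#' contributes two product fragments, see [reactant_molar_share()]); its
#' amplitude and dwell come from the species model.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `trace` (a [nanopore_trace()]) and
#'   `ground_truth`, itself a list of class `ground_truth` with `events`
#'   (data.frame: `time_s`, `species`, `amp_nA`, `dwell_ms`, `collision`)
#'   and `uncleaved` (data.frame: `minute`, `uncleaved` — the kinetic law
#'   evaluated at each minute's midpoint).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  wf <- config$waveform
  fs <- config$sampling_rate
  period_s <- waveform_period(wf)
  period_n <- round(period_s * fs)
  rest_n <- round(wf$rest_duration * fs)
  n_total <- period_n * wf$n_loops
  current <- rnorm(n_total, config$baseline_mean, config$baseline_sigma)

  counts <- rpois(wf$n_loops, config$capture_rate * wf$capture_duration)
  n_ev <- sum(counts)
  if (n_ev > 0) {
    sweep0 <- rep(seq_len(wf$n_loops) - 1L, counts)
    t_ev <- sweep0 * period_s + wf$rest_duration +
      runif(n_ev) * wf$capture_duration
    ord <- order(t_ev)
    t_ev <- t_ev[ord]; sweep0 <- sweep0[ord]

    sp_idx <- .draw_species(config, t_ev / 60)
    amp <- .rtruncnorm_pos(
      n_ev,
      vapply(config$species, `[[`, 0, "amp_mean")[sp_idx],
      vapply(config$species, `[[`, 0, "amp_sd")[sp_idx])
    dwell <- .rtruncnorm_pos(
      n_ev,
      vapply(config$species, `[[`, 0, "dwell_mean")[sp_idx],
      vapply(config$species, `[[`, 0, "dwell_sd")[sp_idx])

    # pulse support must stay inside the capture phase (no event overlaps a
    # rest phase); clamp centres so the +-4 sigma footprint fits
    fwhm_to_sd <- 1 / (2 * sqrt(2 * log(2)))
    sd_n <- dwell / 1000 * fs * fwhm_to_sd
    half_n <- if (config$pulse_shape == "gaussian") {
      ceiling(4 * sd_n)
    } else {
      ceiling(dwell / 1000 * fs / 2)
    }
    i0 <- round(t_ev * fs)
    cap_lo <- sweep0 * period_n + rest_n          # 0-based capture start
    cap_hi <- (sweep0 + 1) * period_n             # 0-based capture end (excl)
    i0 <- pmin(pmax(i0, cap_lo + half_n), cap_hi - 1 - half_n)
    t_ev <- i0 / fs

    for (e in seq_len(n_ev)) {
      idx0 <- (i0[e] - half_n[e]):(i0[e] + half_n[e])  # 0-based
      pulse <- if (config$pulse_shape == "gaussian") {
        amp[e] * exp(-0.5 * ((idx0 - i0[e]) / sd_n[e])^2)
      } else {
        rep(amp[e], length(idx0))
      }
      current[idx0 + 1L] <- current[idx0 + 1L] + pulse
    }

    collision <- logical(n_ev)
    gap_s <- config$collision_limit_ms / 1000
    same_sweep <- diff(sweep0) == 0
    close_pair <- which(same_sweep & diff(t_ev) < gap_s)
    collision[close_pair] <- TRUE
    collision[close_pair + 1L] <- TRUE
    if (mean(collision) > config$collision_warn_frac) {
      warning(sprintf(
        "%.1f%% of injected events collide within %.1f ms; capture_rate may be too high",
        100 * mean(collision), config$collision_limit_ms))
    }
    events <- data.frame(
      time_s = t_ev,
      species = vapply(config$species, `[[`, "", "name")[sp_idx],
      amp_nA = amp, dwell_ms = dwell, collision = collision,
      stringsAsFactors = FALSE)
  } else {
    events <- data.frame(time_s = numeric(), species = character(),
                         amp_nA = numeric(), dwell_ms = numeric(),
                         collision = logical(), stringsAsFactors = FALSE)
  }

  minutes <- seq_len(max(1L, ceiling(n_total / fs / 60)))
  gt <- structure(
    list(events = events,
         uncleaved = data.frame(
           minute = minutes,
           uncleaved = uncleaved_fraction(config$kinetics, minutes - 0.5)),
         seed = config$seed),
    class = "ground_truth")

  list(trace = nanopore_trace(current, fs, waveform = wf),
       ground_truth = gt)
}

# species index per event from the time-evolving molar mixture
.draw_species <- function(config, t_min) {
  n <- length(t_min)
  w_cap <- vapply(config$species, `[[`, 0, "capture_weight")
  if (config$kinetics$model == "none") {
    p <- config$initial_fractions * w_cap
    sample.int(length(config$species), n, replace = TRUE, prob = p)
  } else {
    f0 <- config$initial_fractions[1]
    u <- uncleaved_fraction(config$kinetics, t_min)
    w_r <- f0 * u * w_cap[1]
    w_p <- (2 * f0 * (1 - u) + (1 - f0)) * w_cap[2]
    p_r <- ifelse(w_r + w_p > 0, w_r / (w_r + w_p), 0)
    ifelse(runif(n) < p_r, 1L, 2L)
  }
}

#' Write / read ground-truth event records
#'
#' Tab-separated with header `time_s species amp_nA dwell_ms collision`;
#' round-trips losslessly (to numerical write precision).
#'
#' @param gt A `ground_truth` object (or its `events` data.frame).
#' @param path Output file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the events data.frame.
#' @export
write_ground_truth <- function(gt, path) {
  events <- if (inherits(gt, "ground_truth")) gt$events else gt
  stopifnot(is.data.frame(events),
            identical(names(events),
                      c("time_s", "species", "amp_nA", "dwell_ms", "collision")))
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) .fail("ground-truth file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = "species")))
  expected <- c("time_s", "species", "amp_nA", "dwell_ms", "collision")
  if (!identical(names(df), expected)) {
    .fail("unexpected ground-truth columns: ", paste(names(df), collapse = ", "))
  }
  df$collision <- as.logical(df$collision)
  df
}
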