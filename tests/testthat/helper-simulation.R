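# shared fixtures, all generated in code

# small, fast experiment config (25 kHz keeps pulse FWHM at ~4 samples,
# plenty for amplitude work; detection-fidelity tests use 100 kHz)
quick_config <- function(seed = 1L, n_loops = 20L, sampling_rate = 25000,
                         capture_rate = 2, kinetics = kinetics_spec("none"),
                         initial_fractions = c(1, 0), ...) {
  simulation_config(sampling_rate = sampling_rate,
                    capture_rate = capture_rate,
                    initial_fractions = initial_fractions,
                    waveform = waveform_spec(n_loops = n_loops),
                    kinetics = kinetics, seed = seed, ...)
}

# event table drawn straight from the species amplitude models (no trace,
# no detection) for population/kinetics tests
synth_events <- function(n_per_min, minutes, reactant_share,
                         amp_r = c(0.25, 0.02), amp_p = c(0.15, 0.015),
                         seed = 1L) {
  set.seed(seed)
  if (length(reactant_share) == 1L) {
    reactant_share <- rep(reactant_share, minutes)
  }
  out <- lapply(seq_len(minutes), function(m) {
    is_r <- runif(n_per_min) < reactant_share[m]
    amp <- ifelse(is_r,
                  rnorm(n_per_min, amp_r[1], amp_r[2]),
                  rnorm(n_per_min, amp_p[1], amp_p[2]))
    data.frame(onset_s = sort(runif(n_per_min, (m - 1) * 60, m * 60)),
               amp_nA = pmax(amp, 1e-6))
  })
  do.call(rbind, out)
}

# independent oracle for the boundary-bounded AUC: mean per-event Gaussian
# kernel-CDF mass between the boundaries, in percent
kernel_mass_pct <- function(amplitudes, bw, lower, upper) {
  100 * mean(pnorm(upper, amplitudes, bw) - pnorm(lower, amplitudes, bw))
}

# ground-truth events whose centres fall inside the 4-9 s analysis windows
gt_in_windows <- function(gt_events, period = 9.5, window = c(4, 9),
                          edge_s = 0.01) {
  phase <- gt_events$time_s %% period
  gt_events[phase >= window[1] + edge_s & phase < window[2] - edge_s, ,
            drop = FALSE]
}
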