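# Demonstration configuration: a short no-digestion control.
# Units are encoded in the key names.
seed: 1

simulation:
  sampling_rate_hz: 20000        # 100000 in the laboratory setup
  baseline_mean_nA: 5
  baseline_sigma_nA: 0.01
  capture_rate_per_s: 3          # Poisson rate during capture phases
  pulse_shape: gaussian
  waveform:
    rest_mV: 100
    rest_s: 3.5
    capture_mV: -700
    capture_s: 6
    n_loops: 64                  # ~10 min of recording
  kinetics:
    model: none                  # no-digestion control
    k_per_unit_min: 0.02
    enzyme_units: 0
    start_offset_min: 1
  species:
    - name: dsDNA_3kbp
      length_kbp: 3
      amp_mean_nA: 0.25
      amp_sd_nA: 0.02
      dwell_mean_ms: 0.20
      dwell_sd_ms: 0.04
      fraction: 1
    - name: dsDNA_1.5kbp
      length_kbp: 1.5
      amp_mean_nA: 0.15
      amp_sd_nA: 0.015
      dwell_mean_ms: 0.15
      dwell_sd_ms: 0.03
      fraction: 0

analysis:
  n_sigma: 10                    # detection threshold in baseline sigmas
  merge_gap_ms: 0.1
  boundary_fraction: 0.1         # +-10% of the minute-1 reference peak
  min_events_per_minute: 10
  window_min: [1, 10]            # fit window (10 min demo recording)
  slope_inactive_above: -0.1
  slope_active_below: -1
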