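#' Describe one translocating DNA species
#'
#' A species is a population of molecules producing conductive pulses whose
#' peak amplitudes and dwell times are (truncated-)normally distributed.
#' Defaults for the assay's two species are supplied by
#' [default_species_models()]: the 3 kbp reactant centred near 0.25 nA /
#' 0.20 ms and the 1.5 kbp product near 0.15 nA / 0.15 ms.
#'
#' @param name Species label.
#' @param length_kbp Double-stranded DNA length in kilobase pairs.
#' @param amp_mean,amp_sd Mean and SD of the pulse peak amplitude (nA).
#'   Draws are truncated at zero.
#' @param dwell_mean,dwell_sd Mean and SD of the pulse dwell (FWHM, ms).
#'   Draws are truncated at zero.
#' @param capture_weight Relative capture propensity (dimensionless). The
#'   assay model assumes length-independent capture, so the default is 1.
#' @return An object of class `species_model`.
#' @export
species_model <- function(name, length_kbp, amp_mean, amp_sd,
                          dwell_mean, dwell_sd, capture_weight = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_num(length_kbp, "length_kbp", lower = 0, strict_lower = TRUE)
  .check_num(amp_mean, "amp_mean", lower = 0, strict_lower = TRUE)
  .check_num(amp_sd, "amp_sd", lower = 0)
  .check_num(dwell_mean, "dwell_mean", lower = 0, strict_lower = TRUE)
  .check_num(dwell_sd, "dwell_sd", lower = 0)
  .check_num(capture_weight, "capture_weight", lower = 0)
  structure(list(name = name, length_kbp = length_kbp,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 dwell_mean = dwell_mean, dwell_sd = dwell_sd,
                 capture_weight = capture_weight),
            class = "species_model")
}

#' Default reactant/product species pair
#'
#' Population centres follow the reported event populations (reactant
#' approximately 0.25 nA and 0.2 ms; product approximately 0.15 nA and
#' 0.15 ms); spreads are set to a realistic ~8-10% amplitude CV so the two
#' populations are distinct but adjacent, as in the observed scatter.
#'
#' @return Named list with elements `reactant` and `product`.
#' @export
default_species_models <- function() {
  list(
    reactant = species_model("dsDNA_3kbp", 3,
                             amp_mean = 0.25, amp_sd = 0.02,
                             dwell_mean = 0.20, dwell_sd = 0.04),
    product  = species_model("dsDNA_1.5kbp", 1.5,
                             amp_mean = 0.15, amp_sd = 0.015,
                             dwell_mean = 0.15, dwell_sd = 0.03)
  )
}

#' Alternating capture/rest voltage waveform
#'
#' One waveform period ("sweep") is `rest_duration` seconds at the rest
#' voltage (DNA pushed away from the pore) followed by `capture_duration`
#' seconds at the capture voltage (translocations occur). The default is the
#' assay's 3.5 s at +100 mV then 6 s at -700 mV, looped.
#'
#' @param capture_voltage Capture-phase voltage (mV), default -700.
#' @param capture_duration Capture-phase length (s), default 6.
#' @param rest_voltage Rest-phase voltage (mV), default +100.
#' @param rest_duration Rest-phase length (s), default 3.5.
#' @param n_loops Number of waveform periods, default 190 (~30 min).
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(capture_voltage = -700, capture_duration = 6,
                          rest_voltage = 100, rest_duration = 3.5,
                          n_loops = 190L) {
  .check_num(capture_duration, "capture_duration", lower = 0, strict_lower = TRUE)
  .check_num(rest_duration, "rest_duration", lower = 0, strict_lower = TRUE)
  .check_num(n_loops, "n_loops", lower = 1)
  structure(list(capture_voltage = capture_voltage,
                 capture_duration = capture_duration,
                 rest_voltage = rest_voltage,
                 rest_duration = rest_duration,
                 n_loops = as.integer(n_loops)),
            class = "waveform_spec")
}

#' Period of one waveform sweep in seconds
#' @param waveform A [waveform_spec()].
#' @return Sweep period (s).
#' @export
waveform_period <- function(waveform) {
  waveform$rest_duration + waveform$capture_duration
}

#' Digestion kinetics for the synthetic generator
#'
#' The generator supports three kinetic laws for the uncleaved reactant
#' fraction f(t) (t in minutes of recording; `start_offset` adds the
#' mixing-to-measurement delay, 1 min by default):
#'
#' * `"none"`: f(t) = 1 (no digestion control).
#' * `"first_order_multi_turnover"`: f(t) = exp(-k * enzyme_units *
#'   (t + start_offset)) - a multi-turnover restriction enzyme whose initial
#'   rate is proportional to the amount of enzyme.
#' * `"single_turnover_burst"`: f(t) = (1 - burst_fraction) *
#'   exp(-k * enzyme_units * (t + start_offset)) - a Cas9-like enzyme that
#'   cleaves a `burst_fraction` of the substrate before the first recorded
#'   minute and then works through the remainder slowly.
#'
#' @param model One of `"none"`, `"first_order_multi_turnover"`,
#'   `"single_turnover_burst"`.
#' @param k Rate constant per enzyme unit (1/min), `k >= 0`.
#' @param enzyme_units Amount of enzyme (units).
#' @param burst_fraction Fraction cleaved in the initial burst, in \[0, 1\]
#'   (single-turnover model only).
#' @param start_offset Delay between mixing and the start of recording (min).
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(model = c("none", "first_order_multi_turnover",
                                    "single_turnover_burst"),
                          k = 0.02, enzyme_units = 5, burst_fraction = 0,
                          start_offset = 1) {
  model <- match.arg(model)
  .check_num(k, "k", lower = 0)
  .check_num(enzyme_units, "enzyme_units", lower = 0)
  .check_num(burst_fraction, "burst_fraction", lower = 0, upper = 1)
  .check_num(start_offset, "start_offset", lower = 0)
  structure(list(model = model, k = k, enzyme_units = enzyme_units,
                 burst_fraction = burst_fraction, start_offset = start_offset),
            class = "kinetics_spec")
}

#' Uncleaved reactant fraction at time t
#'
#' Evaluates the kinetic law of a [kinetics_spec()] at recording time `t`
#' (minutes). The result is clipped to \[0, 1\] and is non-increasing in t.
#'
#' @param kinetics A [kinetics_spec()].
#' @param t Recording time(s) in minutes, `t >= 0`. Vectorised.
#' @return Uncleaved fraction(s) in \[0, 1\].
#' @export
#' @examples
#' uncleaved_fraction(kinetics_spec("none"), 30)                      # 1
#' uncleaved_fraction(kinetics_spec("first_order_multi_turnover",
#'                                  k = 0.1, enzyme_units = 1,
#'                                  start_offset = 0), 10)            # exp(-1)
uncleaved_fraction <- function(kinetics, t) {
  stopifnot(inherits(kinetics, "kinetics_spec"))
  if (!is.numeric(t) || anyNA(t)) .fail("'t' must be numeric and non-missing")
  if (any(t < 0)) .fail("'t' must be >= 0 (minutes since start of recording)")
  f <- switch(kinetics$model,
    none = rep(1, length(t)),
    first_order_multi_turnover =
      exp(-kinetics$k * kinetics$enzyme_units * (t + kinetics$start_offset)),
    single_turnover_burst =
      (1 - kinetics$burst_fraction) *
        exp(-kinetics$k * kinetics$enzyme_units * (t + kinetics$start_offset))
  )
  pmin(pmax(f, 0), 1)
}

#' Molar share of the reactant among capturable molecules
#'
#' Each cleaved parent molecule yields two product fragments, doubling the
#' product molarity. With uncleaved fraction `f` of an initial reactant
#' molar fraction `f0` (remainder pre-existing product), the share of
#' reactant among all molecules is
#' `f0 f / (f0 f + 2 f0 (1 - f) + (1 - f0))`.
#' At `f0 = 1` this reduces to `f / (f + 2 (1 - f))`.
#'
#' @param f Uncleaved fraction(s) in \[0, 1\].
#' @param f0 Initial molar fraction of the reactant, default 1.
#' @return Molar reactant share(s) in \[0, 1\].
#' @export
reactant_molar_share <- function(f, f0 = 1) {
  .check_num(f0, "f0", lower = 0, upper = 1)
  if (any(f < 0 | f > 1)) .fail("'f' must lie in [0, 1]")
  denom <- f0 * f + 2 * f0 * (1 - f) + (1 - f0)
  ifelse(denom > 0, f0 * f / denom, 0)
}
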