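# porekinetics

Real-time, single-molecule enzyme kinetics from solid-state nanopore
recordings.

A glass nanopore in a polymer-electrolyte bath reports each translocating
dsDNA molecule as a *conductive pulse* — a transient increase of ionic
current above baseline. When an endonuclease cleaves a 3 kbp substrate into
two 1.5 kbp fragments, the pulse population shifts from the larger
reactant's amplitude (~0.25 nA) to the smaller product's (~0.15 nA), so the
progress of the digestion can be read off the event stream minute by minute
while the reaction happens inside the pore. `porekinetics` implements the
complete analysis for such assays — for multi-turnover restriction enzymes
(SwaI-like) and single-turnover Cas9 ribonucleoproteins alike — together
with a ground-truthed synthetic-data generator, so the whole pipeline is
testable without any laboratory traces.

The pipeline, stage by stage:

* **Sweep segmentation.** Recordings alternate 3.5 s at +100 mV (rest) with
  6 s at −700 mV (capture), sampled at 100 kHz; seconds 4–9 of each 9.5 s
  period are analysed.
* **Event detection.** Per-window robust baseline (median, σ = 1.4826·MAD);
  contiguous excursions beyond **10 σ** become events; peak amplitude (nA)
  and dwell (FWHM, ms) are extracted per event.
* **Population quantification.** Per-minute Gaussian-kernel density
  estimates (PDFs) of peak amplitude on a shared grid; fixed boundaries at
  **±10%** of the minute-1 reactant peak; the probability of detecting the
  reactant is the AUC between the boundaries, per minute:

  P(t) = 100 · ∫_{0.9·A₁}^{1.1·A₁} f̂ₜ(a) da, with ∫ f̂ₜ = 1.

* **Kinetics.** Initial velocity = OLS slope m of P(t) over minutes 1–15;
  reaction rate = −m; rate vs enzyme units with replicate SEM; conditions
  classified inactive (m > −0.1), weakly active, or active (m < −1).
* **Replicate statistics.** Two-tailed unpaired Student t-test (minute 1 vs
  minute 30), Levene homoscedasticity gate, significance codes
  ns / * / ** / ****.

## Worked example

Simulate a 15-minute digestion (5 enzyme units, k = 0.02 min⁻¹ per unit),
detect events, quantify the reactant population and fit the initial
velocity:

```r
library(porekinetics)

kin <- kinetics_spec("first_order_multi_turnover", k = 0.02, enzyme_units = 5)
res <- simulate_and_analyze(seed = 1, kin, minutes = 15,
                            sampling_rate = 25000,
                            bw = 0.01, prominence_frac = 0.25)

head(res$series[, 1:3], 5)
#>   minute n_events probability_pct
#> 1      1       52        62.77590
#> 2      2       77        48.88213
#> 3      3       56        38.14877
#> 4      4       62        29.10160
#> 5      5       62        28.79347

res$fit
#> <kinetic_fit> slope m = -3.514 %/min (SE 0.380), rate = 3.514, R2 = 0.868,
#>               minutes 1-15 (n = 15)

classify_condition(res$fit)
#> [1] "active"
```

The probability of detecting the 3 kbp reactant starts near 63% and falls
as cleavage converts it into 1.5 kbp fragments; the fitted slope of
−3.5 percentage points per minute is this condition's reaction rate, and it
is steep enough (m < −1) to classify the enzyme as active. The boundaries
used were 0.221–0.270 nA, i.e. ±10% around the 0.245 nA reference peak
found in the minute-1 PDF.

Replicate probabilities at two time points are compared as in the
condition-screening figures:

```r
compare_timepoints(c(69.4, 73.1, 65.6), c(19.3, 22.4, 16.9))
#>  mean_a  sem_a mean_b  sem_b     t        p levene_p code
#>   69.37   2.17  19.53   1.59 18.54 4.98e-05     0.71 ****
```

A complete run (simulate → detect → quantify → fit → classify, with a
manifest and per-stage checksums) is driven by a YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "porekinetics"),
             out_dir = "demo_out")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/porekinetics.R run --config <yaml> --out-dir <dir>`
(subcommands: `simulate`, `detect`, `quantify`, `kinetics`, `compare`,
`run`).

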