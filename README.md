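# dynlogic

Dynamic control of gene expression during a bioprocess needs sensors
that report the reactor state and circuits that integrate them.
`dynlogic` models that stack for *E. coli* batch growth: three metabolic
sensors — glucose, dissolved oxygen (DO) and acetate — feed
combinatorial logic circuits whose output promoters switch genes on and
off at programmable times during growth. The package is written for
synthetic biologists and modelers who want to simulate, fit and design
these components without a wet lab: every input the pipeline needs can
be generated synthetically.

## What it implements

* **Sensor models** (`hill_sensor`, `fit_hill`): Hill transfer functions
  $y = y_{\min} + (y_{\max}-y_{\min})\,s^n/(EC_{50}^n + s^n)$ (and the
  depletion-activating form for the low-oxygen sensor), RPU calibration
  from fluorescence, and bounded Levenberg–Marquardt dose-response
  fitting with log-scale residuals.
* **Logic gates and circuits** (`circuit`, `circuit_steady_state`,
  `digitize`, `enumerate_circuits`): NOT/NOR repressor gates
  ($y = y_{\min} + (y_{\max}-y_{\min})K^n/(K^n+x^n)$), AND gates
  ($\propto x_1x_2^2/(K + x_1x_2^2)$) and ANDN gates
  ($y_{\min} + (x_1-y_{\min})K/(K+x_2)$) wired into acyclic netlists;
  truth-table digitization at the sensors' RPU corners and deduplicated
  enumeration of all layered 3-input circuits.
* **Circuit dynamics** (`simulate_circuit`): per-gate ODEs
  $dy/dt = \alpha P(x(t)) - \gamma(y - y_{\min})$ driven by linearly
  interpolated sensor time courses, fixed-step Euler (dt = 0.025 h, 27-h
  horizon) with an rk4 cross-check, initialized at steady state.
* **Promoter-library design** (`build_library`): combinatorial insertion
  of CRP/FNR/FruR operators into σ⁷⁰ promoter backbones (single-position
  scans and paired insertions with variable spacing), screened for ≥6 bp
  direct repeats, BsaI sites and spurious σ⁷⁰ promoters, finalized as
  190-bp synthesis oligos with amplification tails.
* **Knockdown kinetics** (`steady_state_fold`, `simulate_knockdown`,
  `estimate_fold`): a linear two-stage expression model with CRISPRi
  (transcription block), sRNA (mRNA destabilization) and targeted
  proteolysis acting separately or together, plus median-ratio fold
  estimation from cytometry-like populations with bootstrap intervals.
* **Synthetic data** (`simulate_batch`, `generate_dose_response`,
  `generate_population`): a calibrated Monod batch-fermentation
  generator (glucose exhausted ≈ 15 h, DO below the oxygen sensor's
  half-max ≈ 8 h, acetate past 15 mM ≈ 14 h), noisy dose-response data
  and lognormal populations, all seeded.

A thin command-line surface over these functions lives in
`inst/cli/dynlogic.R` (subcommands `simulate`, `design-library`, `fit`,
`generate`, `truth-table`, `knockdown`).

## Worked example

Recover a sensor's parameters from synthetic noisy data, then run the
full batch-to-circuit pipeline with the `(glucose AND acetate) AND NOT
low-oxygen` demonstration circuit:

```r
library(dynlogic)

sensors <- default_sensors()
dr <- generate_dose_response(sensors$acetate,
                             reference_dose_grid("acetate"),
                             noise_cv = 0.05, n_rep = 3, seed = 7)
fit <- fit_hill(dr, mode = "activating", fix_n = 1)
fit$estimates
#>       y_min       y_max        ec50      hill_n
#> 0.004407059 1.033651805 14.503779293 1.000000000

pl <- run_batch_pipeline()   # batch -> sensor wires -> pulse_circuit()
out <- pl$trajectories$g_out
```

The fitted `ec50` of 14.5 mM recovers the acetate sensor's 13.8 mM
half-maximum within 5 %, and `y_max/y_min` ≈ 235 recovers its 250-fold
dynamic range. The pipeline's output promoter activity prints as a
temporal pulse:

```
circuit output: 0.0011 RPU at 0.5 h, peak 0.0032 RPU at 5.4 h, 0.0018 RPU at 27 h
glucose exhausted at 15.3 h; DO crosses 36 umol/l at 7.8 h; acetate passes 15 mM at 13.8 h
```

i.e. the circuit turns on once the batch is underway (glucose high,
oxygen still present) and turns off again as the culture depletes
oxygen — the rise-then-fall behavior that makes combinatorial sensor
integration useful for scheduling.

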