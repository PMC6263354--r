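---
title: "Models and methods in dynlogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dynlogic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlogic)
```

`dynlogic` models how combinatorial genetic logic circuits integrate
three *E. coli* metabolic sensors — glucose, dissolved oxygen (DO) and
acetate — to schedule gene expression during batch growth, together with
the surrounding toolchain: promoter-library design for building such
sensors, knockdown kinetics for acting on the circuit's output, and a
synthetic-data generator that stands in for wet-lab measurements. This
vignette describes the models, their assumptions, the tunable parameters,
and the design decisions taken where the problem left the design open.

## Sensor transfer functions

Each sensor is a phenomenological Hill function with four parameters:
basal output $y_{\min}$, maximal output $y_{\max}$, half-maximum stimulus
$EC_{50}$ and slope $n$:

$$y(s) = y_{\min} + (y_{\max} - y_{\min})\,
  \frac{s^n}{EC_{50}^n + s^n}\qquad\text{(activating)},$$

$$y(s) = y_{\min} + (y_{\max} - y_{\min})\,
  \frac{EC_{50}^n}{EC_{50}^n + s^n}\qquad\text{(depletion-activating)}.$$

The glucose and acetate sensors are activating; the low-oxygen sensor is
depletion-activating on DO concentration (its output rises as oxygen is
consumed). This deliberately ignores the underlying CRP/cAMP and FNR
iron–sulfur mechanisms, the acetate sensor's pH sensitivity, and the
population bimodality of the acetate response at intermediate doses —
the package models population-median behavior only.

The reference sensors ship with the reported half-maximum points
(0.1 % glucose, 36 µmol/l DO, 13.8 mM acetate) and fold changes (18, 25,
250). The slope is not reported for any sensor, so all three default to
$n = 1$; the slope is always a fittable parameter. Output scale is
arbitrary and normalized to $y_{\max} = 1$ with $y_{\min} = 1/\text{fold}$
unless an RPU calibration is applied. Fluorescence converts to relative
promoter units (RPU) by multiplying background-subtracted values by a
single global factor ($10^{-3}$ by default, overridable per call); the
calibration also records each sensor promoter's measured RPU extremes
(glucose 0.006–0.237, low oxygen 0.020–1.346, acetate 0.002–0.700),
which serve as the digital "low"/"high" wire levels.

### Fitting

`fit_hill()` estimates all four parameters by bounded
Levenberg–Marquardt. Three numerical choices matter:

* **Log-scale residuals** (default). Measurement noise on promoter
  output is multiplicative with roughly constant CV, and outputs span
  orders of magnitude; least squares on $\log y$ is the maximum-likelihood
  criterion under that noise model, and absolute residuals would leave
  the off state — hence the dynamic range — essentially unconstrained.
* **Multi-start**. The floor of a depletion-activating sensor is only
  approached asymptotically, and a single optimizer run can stall on the
  $y_{\min} > 0$ bound; the fit restarts from a small grid of
  $y_{\min}$ and $EC_{50}$ initializations and keeps the best optimum.
* **Optional fixed slope.** `fix_n = 1` holds the slope at the generating
  model's value. In the package's parameter-recovery exercises the data
  are generated from the unit-slope reference sensors, so fixing the
  slope uses that structural knowledge and roughly halves the sampling
  error of $EC_{50}$ and the dynamic range; co-estimating the slope
  remains the default for data of unknown shape.

Fits that fail to converge, or whose curve explains less than half the
(log-scale) response variance, are flagged `poor_fit` — for example when
monotone-decreasing data are fitted in activating mode.

### Measurement designs

`reference_dose_grid()` fixes the 12-level dose series used for
synthetic characterization: a zero dose plus a log-spaced ladder for the
activating sensors (0–1.6 % glucose, 0–100 mM acetate), and a
high-DO-weighted design for the oxygen sensor (0–210 µmol/l). The DO
axis ends at air saturation (210 µmol/l), which is only $5.8\times$ the
sensor's $EC_{50}$: the oxygen sensor's off state is never observed
directly, so its dynamic range is weakly identified no matter how the
doses are placed (a Fisher-information analysis puts the relative
standard deviation of the recovered fold near 20 % at 3 replicates and
5 % CV). The recovery pipeline therefore replicates the synthetic
experiment over 11 seeded datasets and reports the median recovered
value; the oxygen dynamic range remains the least certain quantity the
package recovers, and occasional excursions beyond a 15 % band are
expected behavior, not a defect.

## Gate response functions and circuits

Three gate families are modeled in RPU space:

* **Repressor (NOT/NOR)**:
  $y = y_{\min} + (y_{\max}-y_{\min})\,K^n/(K^n + x^n)$, where $x$ is the
  input promoter activity (for NOR, the *sum* of both inputs). Published
  per-repressor parameter sets are not bundled; the package ships a
  neutral default ($y_{\min}$ 0.01, $y_{\max}$ 1.0, $K$ 0.1, $n$ 2) and
  reads user parameter sets from netlist files, with no claim of
  matching any specific characterized repressor.
* **AND** (activator/chaperone):
  $y = y_{\min} + (y_{\max}-y_{\min})\,x_1 x_2^2/(K + x_1 x_2^2)$ with
  defaults $y_{\min}$ 0.001, $y_{\max}$ 0.3 RPU, $K = 10^{-5}$ RPU³. The
  squared second input is kept exactly as published, not generalized.
* **ANDN** (AND NOT): $y = y_{\min} + (x_1 - y_{\min})\,K/(K + x_2)$ with
  defaults $y_{\min}$ 0.001, $K$ 0.0025 RPU. When $x_1 < y_{\min}$ the
  formula would undershoot; the response is clamped at $y_{\min}$. Where
  a genetic implementation reuses the same input promoter in two places,
  both occurrences take the same wire value.

Circuits are acyclic netlists over named sensor wires; gates are stored
in topological order, so steady-state propagation
(`circuit_steady_state()`) is independent of the order gates were
declared in.

### Digitization

`digitize()` evaluates the circuit at every input corner (each sensor at
its low or high RPU level) and thresholds each output at the geometric
mean of that output's own corner extremes — a scale-free rule,
symmetric in log space. An output whose corner extremes differ by less
than a factor of 10 carries no logic transition (exact equality never
occurs in the analog model, and genuine transitions span orders of
magnitude); such outputs are flagged constant and assigned against the
global geometric mean of the input levels.

A consequence of the published AND parameters worth knowing: with
$K = 10^{-5}$ RPU³ and the sensors' measured RPU ranges, the AND gate is
already on at the (glucose low, acetate high) corner
($x_1 x_2^2 \approx 3\times 10^{-3} \gg K$), so its digitized table is
OR-like rather than A∧B. Ideal conjunctive behavior appears only under
near-ideal parameters (vanishing basal output, large fold,
$K$ placed inside the input swing), which is the regime the
logic-equivalence checks use (`ideal_gate_setup()`).

### Enumeration

`enumerate_circuits()` builds all layered circuits of bounded depth
(≤ 3; the combinatorial guard aborts with a count estimate when the
candidate set explodes) over the three sensor inputs, with symmetric
gates taking unordered distinct input pairs and ANDN ordered ones. Each
circuit's ideal Boolean table is computed by direct logical evaluation,
and one representative per distinct table is kept — at most
$2^{2^3} = 256$. Logic synthesis (truth table → netlist) is deliberately
not implemented; enumeration plus classification replaces it.

## Circuit dynamics

Each gate's output relaxes toward its steady-state response with
first-order kinetics,

$$\frac{dy}{dt} = \alpha\,P(x(t)) - \gamma\,(y - y_{\min}),$$

where $P$ is the $x$-dependent production part of the gate's
steady-state response and $\alpha, \gamma$ (both 1 h⁻¹ by default) are
the on/off rate constants. The published formulation writes this for
repressor gates; the package applies the same
$\alpha$-production/$\gamma$-relaxation structure to the AND and ANDN
response surfaces, an extension consistent with the framework. With
$\alpha = \gamma$ and constant inputs the fixed point is exactly the
steady-state response.

Sensor inputs are piecewise-linear interpolations of sampled time
courses; beyond the sampled range the terminal value is held constant
(no trends are invented). Integration is fixed-step explicit Euler at
$dt = 0.025$ h over a 27-h horizon by default, mirroring the reference
discrete solution; a classical Runge–Kutta (rk4) integrator is provided
for verification, and the test suite checks first-order convergence and
Euler/rk4 agreement within 1 % on the fixture circuits, confirming the
step size is adequate. Initial gate states solve the ODEs at steady
state by topological substitution
($y = y_{\min} + (\alpha/\gamma)P$).

The published initial sensor activities (1.294, 0.006, 0.028 RPU) are
stored verbatim as the `sim_config()` default even though 1.294 exceeds
the glucose sensor's maximum of 0.237 RPU and is closest to the
low-oxygen maximum — the original sensor-to-input assignment at $t = 0$
is ambiguous, and the package documents rather than resolves it; the
mapping is user-overridable. The end-to-end batch pipeline
(`run_batch_pipeline()`) instead initializes gates from the *inoculum*
state — a glucose-free, aerobic, acetate-free preculture, i.e. all
wires at their RPU floor — which is what produces the characteristic
rise-then-fall output pulse when the culture is shifted into glucose
media.

Negative transients cannot occur under default parameters; as a guard
for user parameter files, outputs are clamped at 0 with a warning.

## Promoter-library design

The designer reproduces the combinatorial construction of
operator-embedded constitutive promoters: four σ⁷⁰ cores (−35 to +1;
hexamers, 17-bp spacer, discriminator, +1) each combined with three
seeded random spacer pairs gives 12 backbones of 150 bp; single
operators (CRP, FNR, FruR consensus sequences) are then scanned across
every position in replace mode (preserving the 150-bp length; insert
mode is available), and ordered pairs of distinct operators are placed
at three named sites — the +1 site, the 17-bp spacer between −35 and
−10, or immediately upstream of the −35 — at inter-operator gaps of
0–12 bp (a nominal 6-bp gap varied by offsets of ±6; the published range
gives the ±6 but not the nominal gap, which is the package's choice).

Every candidate is screened for: exact direct repeats of length ≥ 6
within the oligo (the most common synthesis-QC reading of a ">5 bp
repeat" screen; inverted and cross-library repeats are not checked);
BsaI recognition sites on either strand (GGTCTC/GAGACC), which would
collide with Golden-Gate assembly; and spurious σ⁷⁰ promoters — a
≤ 1-mismatch match to TTGACA followed 15–19 bp later by a ≤ 1-mismatch
match to TATAAT — anywhere except the intended core, whose hexamer pair
is whitelisted by coordinates. The stringency of the near-consensus
screen (one mismatch per hexamer, 15–19 bp spacing) is a package choice;
the screen itself is named but not specified in the original
description. Backbones are pre-filtered with the same screens (spacers
are redrawn up to 100 times), which is what makes the repeat screen
feasible at all: a fresh random 150-mer contains a duplicated 6-mer with
probability ≈ 0.92, but once the backbone is repeat-free only
operator–backbone junctions can create new repeats. Two consequences
follow: same-operator dual insertions always fail (the operator itself
repeats), so only distinct pairs are enumerated; and the default build
is a few thousand members rather than the reference's 11,964 — the same
order of magnitude, with the exact count depending on the seeded
spacers.

The four named backbone cores are bundled as *synthetic* stand-ins
(`promoter_cores_synthetic.tsv`): the registry sequence of the one core
that is widely known contains GCTAGC twice and would itself fail the
repeat screen, so repeat-free synthetic cores with the canonical
architecture are shipped instead. Finalized oligos are flanked by two
20-bp amplification tails (defaults taken from the annealing ends of the
published amplification primers) and the tail junctions are re-checked
for BsaI sites; a junction collision rejects the oligo.

Coordinates are 0-based and half-open throughout; designs are generated
on the sense strand, and the BsaI screen checks both strands.

## Knockdown kinetics

A linear two-stage expression model,

$$\frac{dm}{dt} = k_m - d_m m,\qquad
  \frac{dp}{dt} = k_p m - d_p p,$$

carries three repression mechanisms: CRISPRi blocks a fraction of
transcription ($k_m \to (1-b)k_m$), an sRNA adds mRNA decay
($d_m \to d_m + \delta_m$), and a targeted protease adds protein decay
($d_p \to d_p + \delta_p$). Linear (non-saturating) kinetics are a
deliberate choice — no enzyme-saturation data are available — and make
the steady-state fold a product of independent mechanism factors,

$$\text{fold} = \frac{1}{1-b}\cdot\frac{d_m+\delta_m}{d_m}\cdot
  \frac{d_p+\delta_p}{d_p},$$

giving a clean calibration path from a reported fold back to a rate
(`calibrate_knockdown()`). Defaults place $d_p = 1$ h⁻¹ (dilution at a
1 h⁻¹ growth rate, consistent with the gate rate constants) and
$d_m = 6$ h⁻¹ (a ~7-min mRNA half-life). The model reproduces the
kinetic ordering of the mechanisms: proteolysis removes the existing
protein pool and reaches half-repression faster than transcription
blocking whenever $\delta_p > d_m$, and adding proteolysis to CRISPRi
never slows the response. One documented divergence: the linear model
predicts multiplicative folds for combined CRISPRi + protease, whereas
the reported measurements could not detect greater potency than sgRNA
alone; the property is kept as a flagged model prediction rather than
silently reconciled. Growth-phase slowdown of dilution can be emulated
by lowering `d_p`; a fully time-varying $d_p(t)$ is not modeled.

Fold estimation from population samples uses the ratio of medians with
a seeded 1,000-resample bootstrap interval, mirroring how gated
cytometry histograms are summarized.

## The synthetic batch generator

`simulate_batch()` emulates the stimulus trajectories of a 1.6 %-glucose
batch culture with four phenomenological components: Monod growth
($\mu_{\max}$ 0.31 h⁻¹, $K_s$ 0.02 %), yield-coupled glucose consumption
($Y_{xs}$ 3 OD per %), quasi-static dissolved oxygen relaxing (at
10 h⁻¹) toward saturation minus a biomass-proportional demand, and
overflow acetate produced proportionally to biomass (1.4 mM OD⁻¹ h⁻¹)
while glucose remains. The oxygen demand includes a maintenance term
(0.05 h⁻¹) so that DO stays depressed after glucose exhaustion, as
measured DO does in stationary-phase cultures — without it the
low-oxygen wire would switch off late in the run and the end-to-end
pulse would not fall. DO is clipped at the 20 µmol/l measurement floor
and calibrated to 210 µmol/l saturation. Acetate production stops once
glucose falls below a trace threshold ($10^{-4}$ %), since Monod
consumption reaches zero only asymptotically.

The defaults were calibrated once so the generator reproduces the three
published timeline landmarks — glucose exhausted near 15 h, DO crossing
the oxygen sensor's half-maximum near 8 h, acetate crossing 15 mM near
14 h — and are pinned in code so these contracts are stable. The
generator targets only those crossing times, not the full measured curve
shapes (which are not tabulated anywhere recoverable); it also omits
acetate re-consumption, pH dynamics and nitrogen limitation. Passing
tests therefore demonstrate correct behavior under this idealized
single-substrate batch, not fidelity to any particular measured
fermentation.

Synthetic dose-response data apply multiplicative lognormal noise of a
stated CV to the sensor model; synthetic cytometry populations are
lognormal with a requested median and CV. All generators take explicit
seeds, restore the global RNG state, and are byte-reproducible.

## Problem sizes

The shipped tests and the acceptance script run at the sizes the methods
are defined at: 27-h simulations at $dt = 0.025$ h (1,081 steps),
dose-response recovery at 12 doses × 3 replicates × 11 replicated
datasets, depth-2 circuit enumeration (633 candidate circuits), the full
default promoter library (~7,600 candidates before filtering), and
10⁴-cell synthetic populations.

## Known limitations

* Sensor models are population-median phenomenology; no single-cell
  distributions, no bimodality, no pH or growth-rate coupling.
* Repressor gate parameters are a neutral default, not a characterized
  gate library; quantitative circuit predictions require user-supplied
  parameter files.
* The oxygen sensor's dynamic range is weakly identified from any
  physically realizable DO dose series (see above).
* The dynamic model has a single global $\alpha$ and $\gamma$; per-gate
  rates, delays, stochasticity and growth feedback are out of scope.
* The library designer checks synthesis-QC constraints, not promoter
  strength; no thermodynamic model is included.
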