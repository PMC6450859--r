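---
title: "Clamp tracer kinetics: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clamp tracer kinetics: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the turnover model
and its assumptions, the parameters that matter and why their defaults are
what they are, what the simulator does and does not emulate, the numerical
decisions, and the known limitations. Everything quantitative stated here
is computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted that the code does not check.

## 1. The measurement problem

A two-stage hyperinsulinaemic–euglycaemic clamp probes insulin action at
three tissues in one session. Insulin at 10 mU·m⁻²·min⁻¹ (stage 1,
0–120 min) half-suppresses hepatic glucose output and adipose lipolysis —
the sensitive range for liver and fat — while 40 mU·m⁻²·min⁻¹ (stage 2,
120–240 min) drives skeletal-muscle glucose uptake. Plasma glucose is held
at 5 mmol/l by a variable 20% dextrose infusion adjusted every 5 min. A
primed, continuous [6,6-²H₂]-glucose infusion and a primed [²H₅]-glycerol
infusion label the two pools; glycerol tracks lipolysis because, unlike
NEFA, glycerol is not appreciably re-esterified. The dextrose is spiked
with tracer (8 mg/g at low dose, 10 mg/g at high dose) so the plasma
tracer-to-tracee ratio (TTR) stays nearly constant — the "hot infusate"
technique that keeps the non-steady-state model error small.

## 2. Turnover model

The package implements the single-pool Steele equation for stable
isotopes:

$$R_a(t) = \frac{F(t) - V\,C(t)\,\dot Z(t)}{Z(t)}, \qquad
  R_d(t) = R_a(t) - V\,\dot C(t), \qquad
  \mathrm{EGP}(t) = R_a(t) - \mathrm{GIR}(t)$$

with $F$ the total tracer delivery (pump plus labelled infusate), $C$ the
tracee concentration, $Z$ the TTR, and $V$ the effective distribution
volume. Assumptions: a single well-mixed pool of fixed volume; tracer and
tracee kinetically identical; all sources and sinks exchange with that
pool. `v_frac` defaults to 0.22 (V = 220 ml/kg). No separate "pool
fraction" multiplier is applied: the 22% figure is treated as the
definition of the effective volume, and `v_frac` is the single knob.

**Basal rates** use the plateau reduction $R_a = F/\bar Z$ on the
window-mean TTR over −30..0 min, not the non-steady formula: the basal
period is an isotopic plateau by design (120 min of equilibration after
the prime), and a derivative estimated from four flat points would add
variance with no information. At basal steady state $R_d = R_a$.

**Clamp windows.** Rates are evaluated at the scheduled sample times
inside each analysis window (low-dose 90, 100, 110, 120 min; high-dose
210, 220, 230, 240 min) from the smoothed curves, then averaged —
computed-then-averaged, not averaged-then-computed. At the 120-min point,
which abuts the stage-2 insulin step, left-hand derivatives and the
pre-switch pump rate are used so the sample is analysed as part of the
stage it physiologically belongs to.

**Exogenous glucose terms.** The bedside pump record is a step function
(a new rate every 5 min). The smoothed tracer curves low-pass this
staircase, so subtracting the *instantaneous* recorded rate from a
smoothed $R_a$ re-injects pump jitter into EGP. Both the infusate tracer
term in $F$ and the EGP subtraction therefore use the exact window
integral of the step record (`gir_window_mean()`), which is unbiased for
the window mean and dramatically less noisy. The tracee GIR is used
unadjusted for its ≤1% tracer content (a second-order correction the
analysis ignores, as the enrichment is ≤10 mg/g).

**Negative EGP** near-complete suppression can emerge from measurement
error. It is reported as computed and flagged `NEGATIVE_EGP`, never
floored: flooring would bias group means upward exactly where suppression
is strongest.

**Glycerol** uses the same Steele form with no exogenous tracee term. The
glycerol tracer stops just before stage 2, so only the basal and low-dose
windows are legal; requesting the high-dose window is a protocol error by
construction.

## 3. Smoothing: the optimal-segments stand-in

Non-steady-state calculations need $C$, $Z$ and their slopes. Tracer
studies classically smooth each channel with an "optimal segments"
routine; the original algorithm is not fully specified in the secondary
literature, so this package implements an explicit, reproducible
formulation of the same idea and documents it as such:

* continuous piecewise polynomials (degree 2 by default, degree 1
  available) in a truncated-power basis, so the fitted value is continuous
  while the first derivative may jump at a breakpoint (the right-hand
  slope is reported there by default, the left-hand slope on request);
* breakpoints restricted to observed sample times, every candidate set
  enumerated exhaustively (≤ `max_segments` segments; default 4 for a
  generic 16-point series);
* selection by penalised weighted SSE. The penalty is AICc — the
  small-sample information criterion — which at n = 16 penalises extra
  segments more strongly than BIC. During development BIC systematically
  overfitted the TTR channel and inflated the variance of window
  derivatives; AICc removed that failure mode without affecting
  noise-free behaviour (exact fits are selected through an RSS floor that
  makes all exact candidates compare by parameter count, so the fewest
  exact segments always win);
* deterministic tie-breaking: fewer segments first, then the first
  breakpoint set in lexicographic enumeration order.

`required_spans` lets the caller force at least one breakpoint into given
intervals. `subject_kinetics()` uses this to require a breakpoint within
each insulin stage: the dose steps at 0 and 120 min are protocol-known
regime changes, and without the constraint the selector occasionally
spanned the stage-2 TTR rise with a single quadratic, corrupting the
low-dose window derivative. The kinetics driver also raises its default to
`max_segments = 5`, because a full two-stage series genuinely traverses
five regimes (basal plateau, stage-1 transition, stage-1 plateau, stage-2
transition, stage-2 plateau); the glycerol channels, which end at 120 min,
use one fewer.

Weights default to uniform; when a measurement-variance model is known,
1/variance weights can be supplied. Evaluation outside the fitted range is
an error, never an extrapolation.

## 4. Derived indices

* **M** (mg·kg⁻¹·min⁻¹): mean GIR over 210–240 min (exact step-function
  integral) minus the glucose-pool change correction
  $(C_{240}-C_{210})\,v_\mathrm{space}/\Delta t$ converted to mass units.
  The correction volume defaults to the tracer distribution volume
  (0.22 l/kg) for internal consistency; the classical 0.19 l/kg glucose
  space is available via `v_space_l_kg`. Endpoint samples (not a
  regression slope) define the concentration change — with four points in
  a 30-min window the difference is immaterial and endpoints are the
  transparent choice.
* **M/I**: M divided by mean insulin over the same window
  (per pmol·l⁻¹).
* **Percentage indices**: `pct_change(basal, clamp)` =
  100·(clamp − basal)/basal, negative for suppression. Cohort summaries
  are means of per-subject percentages, never percentages of group means —
  the two differ (for group means 8.82 → 5.76 the percentage of means is
  −34.7% while the mean per-subject suppression in the motivating design
  is several points different), and per-subject percentages are what the
  tissue-specific sensitivity figures report.
* **AUCs**: trapezium rule over the clamp period (0–240 min by default);
  missing interior samples simply widen the spanning trapezoid.

## 5. Group statistics

The routing mirrors standard clamp-study practice: Shapiro–Wilk at
α = 0.05 per group on the raw scale (both groups must pass) → Student's
pooled-variance *t* with mean difference and 95% CI; otherwise log₁₀
transform and re-test → pooled *t* on logs, back-transformed to a
geometric-mean ratio; otherwise Mann–Whitney (exact for small untied
samples). Student's *t*, not Welch, because the pooled-variance test is
what this literature names and reports. Contrasts are ordered first group
minus (or over) second group. Covariate adjustment is a least-squares
group coefficient on complete cases; missing body-composition covariates
reduce n rather than being imputed. No multiple-testing adjustment is
applied anywhere, matching field practice for these small physiological
panels; p-values should be read accordingly. The type-I error of the full
route-then-test pipeline is checked by simulation (2000 null cohorts at
n = 18/15) in the acceptance suite.

`group_from_summary()` rebuilds a sample with exact n/mean/SD from
published summary tables, which lets the same raw-data routines re-derive
printed contrasts and CIs; the shipped
`inst/extdata/reference_cohort_summary.csv` carries the reference study's
group summaries. The recomputation flags one inconsistency: the
visceral-fat row's printed upper CI bound (+0.62) is incompatible with its
printed p = 0.01 and with the recomputed interval (−3.30, −0.62); the
sign is almost certainly a typographical slip, and the package flags
rather than silently corrects it.

## 6. The simulator: what it emulates, and what it does not

`simulate_subject()` integrates tracee and tracer mass balances

$$V\dot C = \mathrm{EGP}(I) + \mathrm{GIR} - R_d(I,C), \qquad
  V\,\widehat{\frac{d(CZ)}{dt}} = F_\mathrm{pump} + e_\mathrm{inf}\,
  \mathrm{GIR} - R_d\,Z$$

(and the glycerol pair without exogenous tracee) with classical RK4 in
5-min blocks (substep 0.5 min). Design choices:

* **Insulin is prescribed, not modelled**: first-order approach (τ = 8
  min) to stage plateaus. The estimator never uses insulin kinetics, only
  concentrations, so infusion pharmacokinetics would add parameters
  without testing anything. Default plateaus (≈100 pmol/l low,
  ≈155 pmol/l high, basal at the published geometric means) are set so
  that M/I magnitudes match the published scale.
* **Dose–responses are Hill curves** normalised to pass through the basal
  operating point exactly. Defaults are calibrated once to the published
  cohort magnitudes: ≈36% EGP suppression at the low dose and ≈80% at the
  high dose, ≈200% R_d stimulation at the high dose, ≈37% lipolysis
  suppression at the low dose. Disposal scales linearly with glucose
  (mass action) so the clamp has a stable operating point.
* **The controller is a velocity-form PI** acting on 5-min glucose
  readings (noisy readings when measurement noise is on), gains
  k_p = 15, k_i = 10 µmol·kg⁻¹·min⁻¹ per mmol/l. In noise-free default
  runs the mean |C − 5| over 90–240 min is ≈0.05 mmol/l (the tested bound
  is 0.2). Runs leaving 3–9 mmol/l are flagged unstable.
* **Tracer pools start on their basal isotopic plateau** (Z = F/Ra)
  rather than simulating the priming bolus wash-in. The single-pool model
  with V = 22% BW has a turnover time of ≈150 min, so a literal
  2.0 mg/kg prime would not plateau by −30 min inside this model; the
  protocol's prime exists precisely to *reach* plateau, and basal
  isotopic steady state is the condition the generator is required to
  emulate. The prime quantities remain in `clamp_protocol()` as protocol
  metadata.
* **Conservation is auditable by construction**: cumulative in/out fluxes
  are integrated with the same RK4 stages as the pools, so
  in − out − Δpool closes to floating-point precision (~10⁻¹⁵ relative;
  the tested bound is 10⁻⁶). This verifies the integrator's bookkeeping;
  the *accuracy* of the dynamics is tested separately through
  steady-state limits and parameter recovery.
* **Noise** is multiplicative Gaussian per channel: CV 2% glucose, 1.5%
  TTR, 5% insulin, 7% NEFA and glycerol — typical assay performance.
* **Cohorts** draw anthropometry, body composition and physiology from
  group-level distributions matching the published two-group summaries
  (e.g. VAT 3.72 ± 1.07 vs 5.68 ± 2.43 kg; basal EGP 8.82 ± 1.49 vs
  9.25 ± 1.66 µmol·kg⁻¹·min⁻¹; basal lipolysis geometric means
  1.51 vs 1.82), truncated at zero with rejection resampling. Sensitivity
  deviates for muscle, liver and adipose dose–responses are correlated
  (muscle–adipose r = 0.25/0.78 per group as the default scenario,
  muscle–liver 0.6) — adopted as a scenario, not a validated
  physiological claim. The resulting per-subject spread of the
  percentage indices (suppression SD ≈ 20 points) matches the published
  per-subject SDs. The R_d drive uses median 14 in cohort draws versus
  16 for the canonical single subject: lognormal spread and
  insulin-plateau heterogeneity inflate the cohort mean, and 14 centres
  the simulated group means on the published magnitudes.

What the simulator does **not** emulate: meal dynamics,
counter-regulation, NEFA compartmental kinetics, two-compartment glucose
kinetics, time-varying distribution volume, assay drift or batch effects,
or the pre-clamp sliding-scale insulin normalisation (runs start at the
subject's basal glycaemia). Passing recovery tests therefore show that the
estimator inverts the physics it assumes under realistic measurement
noise — not that real plasma data are this well behaved.

## 7. Numerical choices

* RK4 substep 0.5 min inside 5-min controller blocks; stage boundaries
  and sample times fall on block edges, so no event interpolation is
  needed.
* Smoothing selection: AICc; RSS floor 10⁻²⁰·Σwy² for exact-fit
  comparison; scores compared with a 10⁻¹² margin so enumeration order
  breaks exact ties.
* Each segment must contain at least degree + 1 points.
* Derivative convention at interior breakpoints: right-hand by default,
  left-hand at analysis-window ends that abut a stage change.
* `evaluate_curve()` clamps times within 10⁻⁸·range tolerance of the
  boundary and errors beyond it.
* Geometric-mean CIs are t-intervals on log₁₀ values, back-transformed.

## 8. Test problem sizes

The suite exercises: 200 simulated subjects (100 per group, default
noise) for parameter recovery — measured EGP bias ≈3%, RMSE ≈14%;
R_d ≈1%/4.4%; glycerol Ra ≈0.7%/1.2%; basal Ra ≈0.1%/0.8% — with bounds
bias < 5% and RMSE < 15%; noise-free suppression/stimulation recovery
within 3 percentage points (measured < 0.5); 2000 null cohorts for
type-I calibration; 150 Monte-Carlo replicates for smoothing coverage;
500-replicate routing checks. `scripts/acceptance.R` re-runs a 33-subject
study end-to-end plus the calibration loop in a few minutes.

## 9. Known limitations

* **Single-pool Steele.** No two-compartment or circulatory model; rapid
  transients (first ~20 min of a stage) are outside the analysis windows
  precisely because the single-pool approximation is poor there.
* **Enrichment-mismatch bias.** The hot-infusate enrichments (8/10 mg/g)
  are matched to mid-range suppression. Subjects far from that design
  point (EGP suppressed ≫ 50%) show real TTR drift whose curvature the
  quadratic segments only partially capture; recovery studies show a
  small negative EGP bias concentrated in deeply suppressed subjects.
  This is a property of the method, shared with the original analysis.
* **EGP precision.** At 1.5% TTR noise the low-dose EGP window RMSE is
  ≈14% — close to the information limit of derivative estimation from 16
  samples with this curve family. Studies needing tighter EGP should
  sample more densely around the low-dose window.
* **The smoothing objective is a stand-in** for the cited optimal-segments
  method, whose exact objective is not reproduced in the accessible
  literature; the formulation here is explicit and fully reproducible,
  but not guaranteed identical to historical software.
* **Percentage indices are undefined** when the basal denominator is
  missing (flagged, not imputed), mirroring the reduced n in the
  motivating study's figures.
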