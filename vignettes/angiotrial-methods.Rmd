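---
title: "Methods: VEGF-coupled tumour growth, virtual trials and kinetic threshold biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VEGF-coupled tumour growth, virtual trials and kinetic threshold biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`angiotrial` simulates anti-VEGF therapy in tumour-bearing mice with two
coupled layers.

**Molecular layer.** A three-compartment (normal tissue, blood, tumour)
mass-action network of VEGF ligand-receptor kinetics: human isoforms
VEGF~121~ and VEGF~165~ secreted by tumour cells, mouse isoforms
VEGF~120~ and VEGF~164~ secreted by endothelial cells and muscle fibres,
surface receptors VEGFR1 and VEGFR2 and the neuropilin co-receptors
NRP1/NRP2 on separate luminal and abluminal endothelial pools at each
blood-tissue interface, soluble VEGFR1 as a decoy, and
alpha-2-macroglobulin as a plasma sink. VEGF isoforms, sVEGFR1 and the
drug move between compartments by transendothelial macromolecular
permeability and lymphatic flow and are removed by plasma clearance.
Bevacizumab is a humanized anti-human-VEGF antibody: in the model it
binds the human isoforms only, and is delivered as 1-minute intravenous
infusions into the blood compartment. The *angiogenic signal*
$Ang(t)$ is the summed concentration of VEGF-bound VEGFR1/VEGFR2
complexes (with or without neuropilin) on the tumour abluminal
endothelium; soluble-receptor sequestration complexes and complexes in
other compartments never count.

**Growth layer.** Tumour volume follows a switching growth law
modulated by the signal:

$$\frac{dV}{dt} \;=\; \max\!\Big(\frac{Ang(t)}{Ang_0},\,0\Big)\;
\frac{k_0 V}{\big[1 + (k_0 V / k_1)^{\psi}\big]^{1/\psi}},$$

exponential at rate $k_0$ below the switch volume $k_1/k_0$, saturating
to linear growth at rate $k_1$ above it, with sharpness $\psi$ (held at
20; sensitivity analyses of this model family show $\psi$ does not
materially influence the volume, and the limit $\psi\to\infty$ is the
piecewise law $\min(k_0V, k_1)$). The modulation is linear in
$Ang/Ang_0$ and clamped at zero, so anti-VEGF treatment *limits* growth
but never shrinks the tumour. The coupling $m(\cdot)$ is a separate
function (`modulation()`) so an alternative form can be substituted
without touching the network engine.

## Units

Internally the simulator works in days, cm^3^ and mol/cm^3^. The
user-facing growth kinetics are expressed per second ($k_0$ in s^-1^,
$k_1$ in cm^3^ s^-1^): with that convention realistic mouse kinetics
($k_0 \sim 10^{-6}\text{--}10^{-5}$, $k_1 \sim 10^{-7}\text{--}10^{-6}$)
fall inside the published two-decade fitting bounds
($10^{-8}$ to $10^{-2}$ for both rates, $10^{-16}$ to $10^{-14}$
mol/cm^3^ for $Ang_0$), and threshold values on $k_1$ have the
magnitude ($\sim 10^{-6}$) reported for this model family. The
$k_0/k_1$ ratio (cm^-3^) is invariant to the time unit, so all ratio
threshold arithmetic is unaffected by this choice.

## The packaged parameterization is synthetic

The rate constants, compartment volumes, receptor densities and
secretion rates in `default_network_config()` are a clearly-labelled
synthetic stand-in with literature-plausible magnitudes (picomolar
free VEGF, 30-300 pM VEGFR affinities, nanomolar neuropilin binding, an
antibody with 17 pM affinity for its ligand, slow antibody clearance of
0.08/day, fast free-VEGF clearance of 20/day). They are chosen so that

* the equilibrated basal signal is $\approx 5.6\times10^{-15}$
  mol/cm^3^ (interior to the $Ang_0$ bounds), and
* roughly 45% of the basal signal comes from the (drug-targetable)
  human isoforms, so sustained bevacizumab exposure drives
  $Ang/Ang_0$ to $\approx$ 0.6: treated tumours keep growing but
  measurably slower, which is the regime in which survival curves,
  hazard ratios and threshold sweeps are all informative.

Every analysis function takes the configuration (or a full
`vegf_model`) as an argument, so fitted constants can be supplied
without code changes.

Two structural simplifications are deliberate. Tumour receptor pools
are modelled at constant density (new endothelial surface arrives with
the growing tumour), and soluble concentrations are treated as
intensive, without an explicit growth-dilution term; consistently,
tumour secretion and tumour exchange conductances scale linearly with
total tumour volume, making per-volume source and exchange rates
volume-independent. The net effect is a basal signal that is
approximately stationary in untreated animals, which is what anchors
$Ang_0$. Mole-conservation checks are therefore asserted on
fixed-volume configurations. The tumour interstitial fluid volume is a
pluggable coupling to total volume; the packaged form is the constant
fraction 0.5.

## Numerical implementation

The network is compiled to flat index arrays and integrated with
`deSolve::lsoda` calling a C right-hand side, so stiff integration --
including the numerically generated Jacobian -- stays at C level
(~10 ms per 100-day mouse). Tolerances: relative $10^{-7}$, absolute
$10^{-21}$ for concentrations and $10^{-9}$ for volume. Dosing uses
exact event handling: the trigger crossing is located by `lsodar` root
finding, and each 1-minute infusion window is integrated as its own
segment so the adaptive stepper cannot step over it; the delivered
amount equals dose x body mass / molar mass exactly. Simulations are
started from a pre-equilibrated state (volume frozen at
$V_0 = 0.004$ cm^3^ until species pools settle), so
$Ang(0) = Ang_0$ and the control modulation starts at 1. The switch
denominator is evaluated in an overflow-safe form for large
$(k_0V/k_1)^\psi$.

## Trial design

Populations draw $k_0$ and $k_1$ i.i.d. uniform within per-case ranges
(400 mice per case in the headline design), with $Ang_0$ fixed at the
median of its per-case estimates and $\psi$ constant. Mice whose
control tumour does not reach 0.1 cm^3^ within 10 days of engraftment
are excluded before treatment assignment (and are not replaced; the
effective n is reported). Protocols are trigger-started: A (10 mg/kg,
trigger 0.1 cm^3^), Z (10 mg/kg, at engraftment), V11a (10 mg/kg,
0.5 cm^3^) and V11a-D (20 mg/kg, 0.5 cm^3^), all twice weekly for 12
weeks by default. "Biweekly" is read as twice per week; for protocol A
the sources conflict between weekly and twice-weekly dosing, so the
frequency is a parameter (default twice weekly) rather than a resolved
fact. Paired arms share the mouse, the initial volume and an identical
absolute horizon (12 weeks past the latest trigger among retained
mice), so they differ only in dosing events, and the relative tumour
volume RTV(t) = mean treated / mean control is defined on every shared
day. The dispersion reported alongside the endpoint RTV is the
standard deviation of the per-mouse treated/control ratio -- the
ratio-of-means and its per-mouse dispersion are distinct quantities and
both are labelled explicitly.

## Survival machinery

A mouse is "sacrificed" (event) at the first sampled day its tumour
reaches 2 cm^3^ and censored at the end of its simulation otherwise;
event-time resolution is deliberately the daily grid (medians are then
integers or half-integers). Kaplan-Meier estimation, the Mantel-Cox
log-rank test and the Mantel-Haenszel hazard ratio are implemented in
the package: the threshold sweep evaluates the log-rank test once per
candidate per case (tens of thousands of calls), so the risk-table
accumulation is vectorised with exact integer accounting; the test
suite cross-checks all three against the survival package
(`survfit`, `survdiff`, `coxph`) and against brute-force hand
computations. The MH hazard ratio is the Mantel-Haenszel common
odds-ratio estimator over the 2x2 tables at distinct event times,
which is consistent for the common hazard ratio under proportional
hazards, with a 95% CI from the Robins-Breslow-Greenland variance of
the log estimate; this form inverts exactly under group relabelling.
Exactly-0.5 median survival plateaus return the midpoint of the
plateau interval. When the estimate never falls below 50% the median
is undefined (`NA`), not an error.

## Threshold discovery

Every observed value of the selected kinetic parameter ($k_0$, $k_1$,
or the $k_0/k_1$ ratio) is tested as a split point on the treated arm
(the swept arm is an argument): mice strictly above vs strictly below
the candidate are compared by log-rank at $\alpha = 0.05$, requiring at
least 10 mice per side (log-rank validity; candidates failing this are
marked skipped). A valid range is a contiguous run of significant
candidates with a consistent direction of benefit; the widest run is
the case's primary interval; the common range across cases is the
interval intersection, and the working threshold is its midpoint --
consistent with published interval medians that equal the midpoint of
the printed endpoints (for the ratio interval [9.757, 17.982] the
midpoint is 13.8695; the two published renderings of that median,
13.689 and 13.8693, differ, and the midpoint matches the latter to
1.4e-5 relative, suggesting the former is typographical). No
multiplicity correction is applied across candidates, exactly as in
the published procedure; the null-population property test (no wide
stable interval when survival is independent of the parameter) guards
the interpretation.

## Fitting

`fit_control()` estimates $(k_0, k_1, Ang_0)$ from control volume
series by box-constrained least squares on log~10~ parameters
(Levenberg-Marquardt via `minpack.lm`), with the published two-decade
bounds as defaults. Because the likelihood surface has an
$Ang_0$-scaling ridge and boundary local minima, the multistart is
screened: the objective is evaluated once at every log-uniform start
(50 by default) and the refinement runs only from the best few (8 by
default); ties in SSR break on the lowest start index.
`validate_and_select()` re-simulates the treatment schedule per fit,
scores combined control+treatment error on the objective scale, and
keeps the 12 best sets, whose ranges seed validation populations. For
datasets reported only relative to a reference day, the `"normalized"`
objective fits day-normalized series (and the interstitial-volume
coupling of the supplied model applies).

## What the synthetic generators emulate -- and what they do not

`gen_growth_dataset()` samples the full mechanistic model at hidden
kinetics and applies multiplicative log-normal noise (volume errors
scale with size), at a twice-weekly day 3-24 schedule chosen to span
the exponential phase, the switch and the linear phase -- the two rates
are jointly identifiable only if the design covers the curvature around
the switch volume. `gen_case_ranges()` builds per-case sampling ranges
whose attainable ratio span straddles the common threshold interval.
`gen_survival_cohort()` and `gen_planted_threshold_population()`
produce exponential event times with known hazard structure as oracles
for the survival and sweep machinery. These generators emulate the
*shape* of xenograft training data (MDA-MB-231-like magnitudes and
noise), not any particular published dataset: passing recovery tests
demonstrates the estimators and the sweep work under the stated noise
model, not that the packaged constants reproduce a specific animal
study.

## Problem sizes used by the shipped analyses and tests

The analysis scripts sample 400 mice per case and simulate paired
trials for 60 of them per case; the test suite uses populations of
2-50 mice for mechanistic checks, 100 seeded populations of 400 for
planted-threshold recovery, 20 noisy datasets (40 starts, 10
refinements) for fitting recovery, and 20 seeded 500-per-arm cohorts
for hazard-ratio calibration. These sizes were chosen so the full
suite completes in a few minutes while leaving every statistical check
comfortably powered.

## Known limitations

* The packaged kinetic constants are order-of-magnitude stand-ins;
  quantitative reproduction of any specific study requires supplying
  its fitted constants via the configuration.
* Vascularity dynamics and vascular normalization are not modelled;
  the vascular fraction of the tumour is implicitly constant.
* Cytotoxic (cell-killing) drug action, correlated $(k_0, k_1)$
  sampling and inter-mouse variability in the molecular constants are
  out of scope.
* The sweep's per-candidate tests are not multiplicity-corrected;
  interpret single significant candidates accordingly.
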