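---
title: "Mechanistic model and virtual-trial methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic model and virtual-trial methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(elraqsp)
library(dplyr)
```

## The scientific problem

Bispecific T-cell engagers against BCMA bridge CD3 on T cells and membrane
BCMA on myeloma plasma cells. Efficacy is driven by the *trimer* (drug
simultaneously bound to both receptors); single-arm *dimers* are inactive
and, in excess, block trimer assembly, which produces the bell-shaped
concentration-response typical of ternary complexes. Shed soluble BCMA
(sBCMA) circulates at concentrations far above the membrane pool, binds the
BCMA arm, and acts as a drug sink; it is also a marker of disease burden.
This package implements a mechanistic model of these processes together
with the virtual-population machinery needed to ask regimen questions: dose
escalation under sBCMA stratification, binding-ratio curve shapes, and
dose-frequency de-escalation after response.

## Model structure

The model has three compartments: central (circulation), bone marrow (site
of action) and a peripheral distribution compartment (free drug only).
All molecular species are carried in nM within their compartment volume;
cells are absolute counts, converted to receptor concentrations exactly
once, at state assembly (`make_patient()`), via Avogadro's number and the
compartment volume. States per compartment:

* subcutaneous depot, free drug (central, peripheral, bone marrow);
* free and drug-bound sBCMA in central and bone marrow;
* membrane BCMA as free receptor, drug dimer, and functional trimer;
* CD3 on T cells (free, drug dimer) in bone marrow and circulation, plus a
  nonfunctional CD3-drug-sBCMA complex;
* serum M-protein (g/dL) and free light chain (mg/L);
* IL-6 and a releasable IL-6 pool;
* cumulative eliminated drug (mass-balance bookkeeping).

Tumor cells and T-cell counts are *derived* states: the tumor is
represented by its total membrane-BCMA pool and divided by the per-cell
receptor density, so the conservation identities (free + dimer + trimer =
receptors/cell x cells) hold exactly rather than to solver tolerance.
Growth adds free receptors at the logistic rate `g (1 - N/N_max)`; killing
removes all receptor species proportionally; the CD3-drug portion of a
killed trimer is returned to the dimer pool (the T cell survives).

Killing is driven by the *effective binding ratio* -- trimers divided by
all membrane BCMA receptors -- through a Hill function with maximum
`k_max`, coefficient `n_kill` and half-maximum `alpha_kill`, attenuated by
acquired resistance `1/(1 + alpha_resis * t)` with the clock starting at
the first dose and not resetting on dose holidays. Paraproteins are
produced proportionally to tumor burden and eliminated first order, so a
response in M-protein lags tumor kill by roughly the immunoglobulin
half-life. Trimer formation releases IL-6 from a depletable pool
(attenuation on repeated dosing) and IL-6 slows T-cell egress from the
marrow (`k_out/(1 + I/I50)`).

The right-hand side is written once in C (deSolve's compiled-model
convention) and mirrored by an R reference implementation
(`derivatives()`); the test suite asserts their equality at random states.
Dose events are discrete depot additions with the integrator stopped and
restarted at event times. Default tolerances are `rtol = 1e-6`,
`atol = 1e-9`; the output grid is daily plus event times. Solver-tolerance
negatives are floored at zero; materially negative states raise an
integration-quality error.

## Parameter choices that matter

| parameter | default | why |
|---|---|---|
| `kon_B`, `koff_B` | 1 /nM/day, 5 /day | tight BCMA arm (Kd 5 nM), assay-scale |
| `kon_C`, `koff_C` | 1 /nM/day, 60 /day | deliberately weaker CD3 arm (Kd 60 nM) |
| `chi` | 0.8 | avidity efficiency of the trimer-closing step |
| `CL`, `Vc` | 1 L/day, 8 L | average central exposure ~70 nM at 76 mg QW |
| `k_cl_S` | 1.5 /day | physiological sBCMA turnover (half-life ~11 h) |
| `k_elim_M`, `k_elim_F` | 0.05, 0.4 /day | immunoglobulin vs light-chain clearance |
| `N_max` | 3e12 cells | tumor carrying capacity |

Two consequences are central to the package's behaviour. First, the
ternary-complex optimum sits near `sqrt(Kd_B * Kd_C)` (about 17 nM), well
*below* the average exposure of the weekly clinical dose, so responders on
continued weekly dosing sit on the descending limb of their bell curve --
this is what makes frequency de-escalation after response non-inferior.
Second, the sBCMA pool turns over quickly: sustaining an observed baseline
of hundreds of ng/mL against a 1.5/day clearance requires a production flux
comparable to the weekly dose itself, so high-sBCMA patients genuinely lose
drug to the sink, not merely to a static buffer.

### Steady-state back-solving

Four rates are back-solved per patient so that the pre-treatment state is a
steady state of the equations: paraprotein production (`k_M`, `k_F`) from
the baseline marker levels, T-cell marrow entry (`k_in`) from the baseline
compartment counts, and the shedding rate `k_shed` from the observed
baseline sBCMA against the fixed clearance. Shedding heterogeneity is
varied through `k_shed_mult`, which scales shedding and clearance jointly
and therefore preserves the baseline steady state. We chose this over
sampling an absolute shedding rate and back-solving the clearance: in that
parameterisation the steady-state drug drain is set by the (sampled)
shedding flux alone and becomes independent of baseline sBCMA, so the
sink's stratum effect -- the phenomenon of interest -- cannot emerge.

### Assay floors

Assessment-track values are floored at an assay lower limit of
quantification (0.02 g/dL for M-protein, 1 mg/L for FLC). Without a floor,
the 25%-from-nadir progression rule fires on numerical noise around
paraprotein levels of 1e-8 g/dL, which no laboratory could measure;
with it, progression requires regrowth into the quantifiable range.

## The synthetic cohort

No patient-level trial data are public, so `sample_baselines()` and
`parameter_priors()` define the study conditions. Baselines are log-normal:
M-protein (median 1.5 g/dL), FLC (150 mg/L), tumor burden (8e10 cells),
T cells (2.5e9 circulating, 3e9 marrow). The sBCMA distribution is anchored
so that exactly 70% of patients fall below the 100 ng/mL stratum cutoff,
and sBCMA is coupled to tumor burden by a Gaussian copula at rank
correlation 0.5 (sBCMA as a disease-burden marker). Nine parameters vary
uniformly between documented bounds (receptor densities, kill-function
shape, resistance, growth, shedding multiplier, maximal kill, marrow
T-cell multiplier); all other constants are fixed. The growth prior
deliberately overshoots the doubling-time plausibility bounds of
[60, 600] days on both sides so that the filter does real work (roughly
70-80% of candidates survive).

Cohort-level calibration targets (`default_targets()`) promote the printed
cohort summaries to generator constants: the headline two-step-priming
76 mg QW cohort carries stratum response rates of 0.77 (low sBCMA) and
0.37 (high), a median trajectory reaching below -90% by day 100, and a
best-response decile profile spanning +25% to -100%; the two smaller
lower-dose cohorts carry strictly lower, neutral-default rates and are
weighted by cohort size.

What the generator does *not* emulate: assay noise on the biomarkers,
total-vs-free analyte distinctions, dropout for toxicity, correlation
between the varied mechanistic parameters, or real inter-study
heterogeneity. Passing calibration here shows that the workflow recovers
known cohort statistics from a heterogeneous mechanistic pool -- not that
the model is calibrated to real patients.

## Virtual-population workflow

```{r workflow, eval = FALSE}
candidates <- sample_trial_patients(10000, seed = 1)
pool <- plausibility_filter(candidates, bounds = c(60, 600),
                            targets = default_targets())
vpops <- calibrate_vpops(pool, default_targets(), k = 10, size = 120)
```

`plausibility_filter()` first screens untreated tumor and M-protein
doubling times (computed from the drug-free limit of the model, in which
the tumor follows the logistic closed form exactly), then simulates every
survivor once under every target regimen -- with the cycle-7 PR switch rule
and progression dropout applied -- and caches assessment-time percent
changes (last observation carried forward after dropout), best response and
responder flags. Genetic-algorithm selection is then pure arithmetic on the
cache: tournament selection (size 3), union-based crossover with
cardinality repair (rate 0.8), two random member swaps per child, elitism
of 2, population 50, 100 generations. These hyperparameters are package
defaults; the objective is the trial-size-weighted sum over cohorts of
three unit-scale metrics (stratified response-rate squared error, median
trajectory MSE, decile-profile MSE, all on the fraction scale), with a
fixed penalty of 25 for an empty stratum or an undersized decile group.

## Regimens and response scoring

Presets cover the clinical schedules: weight-based weekly escalation
levels (fixed-dose equivalents at 76 kg, printed clinical doses where one
exists), one-step priming (44 mg day 1, 76 mg day 8), two-step priming
(12 mg day 1, 32 mg day 4, 76 mg day 8), flat weekly 16-152 mg and 76 mg
every two weeks. Assessments fall every 28 days under fractionated
(priming) regimens and every 21 days otherwise. A biochemical responder
shows a 50% or deeper decline from baseline in the integrated paraprotein
(M-protein if at least 0.5 g/dL at baseline, otherwise measurable FLC,
otherwise excluded) at two consecutive assessments; 90% or deeper is VGPR;
progression is an inclusive 25% rise from the running nadir (baseline
included). Percent change is always from the pre-dose baseline. The
frequency switch is evaluated from the end-of-cycle-6 assessment (day 168)
and takes effect from cycle 7 (day 169); we read eligibility this way
because with 28-day assessments there is no assessment on day 169 itself,
and the clinical rule switches *at* cycle 7 for patients confirmed by then.
Eligibility keeps being re-checked at every later assessment until the
switch fires once. Best overall response is the best single-assessment
change (not best confirmed).

## Numerical and design notes

* Dose events at a chunk boundary belong to the following chunk (half-open
  windows), so chunked adaptive simulation administers each dose exactly
  once and scenario branches share their pre-switch trajectory exactly.
* The ternary-equilibrium oracle solves the algebraic binding equilibrium
  by damped fixed-point iteration to residuals below 1e-12 of the largest
  total; it exists to validate the ODE limit and the bell-shape property,
  never to stand in for the dynamics.
* Curve-shape classification uses a 2% relative tolerance to absorb solver
  noise; ties collapse toward monotone labels, and a multi-peak sequence is
  labelled bell with a quality flag.
* Empty strata in the objective draw a penalty constant rather than an
  exception so the GA can traverse them.
* `switch_study()` compares scenarios from the identical saved state at the
  individual switch assessment; trimer:tumor-cell ratios are averaged over
  whole 28-day cycles (cycles 18 and 36) to avoid dose-phase artifacts.

## Problem sizes

The shipped tests and the acceptance script run the workflow at desk
scale: pools of 500-1100 sampled candidates (800-odd plausible patients),
single 120-member virtual populations, and three-year switch studies on
one VPop's persistent responders. The full-scale defaults (10,000
candidates, 10 VPops) run the identical code path and are exercised for
structure rather than re-simulated wholesale.

## Known limitations

* Progression fractions among persistent responders are smaller than
  clinical experience (single-digit percent over three years at default
  priors); the de-escalation comparisons are therefore directional.
  Calibrating relapse kinetics would require the proprietary patient-level
  data.
* The "decreasing" dose/binding-ratio class is rare under default priors:
  in this parameterisation the per-patient optimum shifts mainly through
  the sBCMA sink, which also depresses exposure, so patients rarely sit
  entirely past their peak at the lowest dose. The classifier supports the
  label and is tested synthetically.
* T cells neither expand nor exhaust; trimer-engaged cells do not migrate.
* IL-6 magnitudes are configuration-level choices (tens of pg/mL first-dose
  peaks with attenuation), not calibrated to assay data.
* The peripheral compartment carries free drug only.

## A worked single patient

```{r patient}
pat <- make_patient()
sim <- simulate_patient(pat, preset_regimen("two_step_priming_76QW"), 196)
round(effective_binding_ratio(sim, c(0, 84)), 5)
ad <- simulate_adaptive(pat, preset_regimen("two_step_priming_76QW",
                                            switch_rule("PR")), 280)
ad$response[, c("responder", "bor_pct", "persistent")]
ad$switch_log
```

```{r plot}
autoplot(sim)
```
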