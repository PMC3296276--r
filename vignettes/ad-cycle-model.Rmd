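---
title: "Modelling the GSK3beta/p53/ROS cycle linking amyloid-beta and tau"
author: "adcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the GSK3beta/p53/ROS cycle linking amyloid-beta and tau}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcycle)
```

## The model

Alzheimer pathology couples two very different aggregates: extracellular
amyloid-beta (Abeta) plaques and intracellular tangles of
hyperphosphorylated tau.  `adcycle` implements a stochastic mass-action
network in which the two are linked indirectly, through a
positive-feedback cycle:

* soluble Abeta monomers raise reactive oxygen species (ROS);
* ROS produces DNA lesions (`damDNA`);
* lesions drive phosphorylation of p53, which both stabilises it
  (phospho-p53 cannot be captured by Mdm2 for ubiquitination and
  proteasomal degradation) and activates it;
* phospho-p53 binds GSK3beta; the `GSK3b_p53` complex is the
  activity-carrying species;
* active complexes drive further Abeta production *and* tau
  phosphorylation, closing the cycle on the Abeta side and feeding the
  tau side.

Aggregation itself is deliberately simple: monomers pair into
oligomers, oligomers pair into plaques; phospho-tau pairs irreversibly
into tangles.  Because the cycle has multiple points of entry (basal
ROS, constitutive Abeta production, spontaneous DNA damage), plaques
and tangles can arise together, separately, or not at all in any given
cell, which is exactly the heterogeneity the ensemble experiments
probe.

Every reaction is elementary mass action.  The simulator is an exact
Gillespie direct-method SSA: waiting times are exponential in the total
propensity, the next reaction is chosen proportionally to its
propensity, and homo-oligomerisation uses the combinatoric
$k\,n(n-1)/2$ convention.  Timed events (the intervention mechanism)
interrupt the waiting time: if the sampled firing time falls at or past
the next event, no reaction fires, the clock jumps to the event, the
parameter changes instantaneously, and the waiting time is redrawn --
justified by the memorylessness of the exponential.

```{r model}
m <- build_default_network()
m
head(parameter_values(m))
```

## Cooperative tau phosphorylation

One structural choice deserves its own section.  Tau phosphorylation is
catalysed by *pairs* of active kinase complexes:

```
tau + 2 GSK3b_p53  ->  tau_P + 2 GSK3b_p53        (complexes catalytic)
```

so its propensity is $k \cdot C(C-1)/2 \cdot [\mathrm{tau}]$, zero
whenever fewer than two complexes exist.  Biologically this encodes the
primed, multi-site character of pathological tau hyperphosphorylation:
producing the tangle-competent epitope requires more than one active
kinase engagement, so a lone, transiently formed complex in an
unstressed cell does nothing.

The choice is also what makes the model's threshold behaviour work.  In
a healthy (or clearance-protected) cell the complex count is almost
always 0 or 1, so the basal phospho-tau flux is *exactly* zero rather
than merely small; after ignition of the feedback cycle the complex
count reaches the hundreds and the flux is enormous.  A linear
(single-modifier) encoding cannot do this: with tangle formation
quadratic in phospho-tau, the ratio of ignited to basal tangle hazard
is bounded by the squared ratio of complex counts, and no rate
constants make the baseline ensemble form tangles in most cells while
one hundred clearance-protected cells form none.  The pair requirement
removes that bound.

## Parameters, units, calibration

Time is measured in days (every reported timing in the study design is
in days) and the horizon is 12 days.  Copy numbers are arbitrary
molecule counts; the only externally meaningful scale is the apoptosis
threshold (mean 600 copies of total p53, below).

The source study does not print its rate constants (they live in a
deposited SBML file), so the defaults here are calibrated -- once --
to the *reported ensemble behaviours*, not to any numerical table:

* **Unstressed steady state.**  p53 synthesis (300/day) balances
  Mdm2 capture, ubiquitination and proteasomal degradation so the
  total p53 pool sits near 68 with about 10 free copies; ROS, lesions,
  monomers and phospho-species all fluctuate near zero.
* **Stochastic ignition.**  Basal ROS bursts produce lesions at a
  fraction per day; each lesion converts a few p53 copies to the
  phospho form, which may capture GSK3beta and seed the cycle.  The
  seed either fizzles (dephosphorylation wins) or ignites the
  feedback, making ignition an essentially one-shot stochastic event.
  At the defaults most cells ignite within the first few days while a
  small percentage never do within 12 days, reproducing the reported
  mix of affected and escaping cells.
* **Disease course.**  After ignition, complexes accumulate (capped by
  the GSK3beta pool of 300), tau converts and tangles nucleate first
  (median first tangle about day 3.3); monomers, oligomers and then
  plaques follow (median first plaque about day 5.4) -- tangles precede
  plaques, as reported.  Total p53 crosses the 600-copy apoptosis
  threshold in over 90% of runs.
* **Interventions.**  A 100-fold boost of soluble-monomer clearance at
  day 0 breaks the cycle's entry point: across hundreds of verification
  runs no plaque or tangle ever forms and p53 stays low, so no cell
  dies.  Boosting at day 2 leaves a residue (a few tangles, slightly
  elevated ROS); from day 6 onward the tangle burden is essentially
  that of untreated cells (within 25%) although plaques are still cut
  by more than 80%, because tau phosphorylation has already been
  driven by the pre-intervention Abeta load.
* **Blockades.**  Zeroing Abeta-mediated ROS production reproduces the
  day-0 clearance condition (all stress observables near zero, p53
  basal).  Zeroing GSK3beta/p53 binding keeps complexes -- and hence
  tangles -- at exactly zero and plaques near zero, while total p53
  still rises through the damage-phosphorylation route.
* **Elevated drive.**  The aggregation constants are set high enough
  that a cell with elevated Abeta production forms its first aggregate
  within two to three days (median about 2.5 d over 100 runs).  The
  elevated condition multiplies the constitutive production constant
  `k_ab_basal` by 30 (`elevated_network("abeta_production")`), the
  kind of drive a familial APP-processing mutation represents; the
  tau-phosphorylation variant uses fold 10.  Both folds are declared
  calibration constants of the condition, chosen once.

Two numerical consequences of the calibration are worth knowing.
First, ignited trajectories keep growing after the death threshold is
crossed -- cell death is a post-hoc annotation, not a reaction -- so
end-of-run means of p53, monomers and ROS in uncontrolled ensembles
are large; they should be read as "runaway", not as physiology.
Second, the p53/Mdm2 module is deliberately minimal (no
p53-induced Mdm2 transcription, hence no damped oscillations); the
study's claims do not depend on that feature.

## The five experiments

```{r experiments, eval = FALSE}
sweep <- run_clearance_sweep(days = c(0, 2, 4, 6, 8, NA),
                             n_runs = 100, base_seed = 1)
ros   <- run_ros_block(n_runs = 100, base_seed = 1)
bind  <- run_binding_block(n_runs = 100, base_seed = 1)
viab  <- viability_analysis(lapply(sweep, `[[`, "trajectories"),
                            threshold_model(mean = 600, variance = 50),
                            seed = 1)
```

`run_clearance_sweep()` applies the 100-fold clearance boost at each
requested day (day 0 as a direct parameter edit, later days as timed
events) plus a no-intervention control.  The blockade experiments zero
their parameter from time 0 and layer a day-8 clearance boost on top.
Each condition derives its seed stream from the base seed and the
condition *label*, so conditions are reproducible independently and
their results do not depend on execution order.

The viability analysis is purely post hoc: each run draws an apoptosis
threshold from Normal(600, variance 50) -- the variance is a variance,
so the spread is about 7 copies; both are configurable -- and dies at
the first recorded time its total p53 pool strictly exceeds it.
Thresholds come from their own seeded stream, so re-analysis with new
thresholds needs no re-simulation.

## Numerical choices and edge cases

* **Recording.**  Trajectories are sampled piecewise-constant on a
  0.05-day grid (241 points over 12 days); the value at grid time $t$
  is the state after the last transition at or before $t$.  First
  passage to the first plaque/tangle is recorded at exact event times;
  the p53 threshold crossing is detected on the grid, which at this
  resolution is indistinguishable from the exact time.
* **Ties.**  An event scheduled exactly at a grid point is applied
  before the grid samples; an event at the horizon still fires.
* **Seeds.**  Run $i$ of an ensemble uses `base_seed + i - 1`; the
  same (model, seed, grid) triple is bit-reproducible, which the test
  suite checks against an independent pure-R implementation of the
  same stepper consuming the same RNG stream.
* **Degenerate models.**  A network with no reactions is valid and
  yields a constant trajectory; zero-valued rate constants are legal
  (they *are* the blockades); propensities clamp at zero so no count
  can go negative.
* **Problem sizes.**  The shipped tests run the full 100-run ensembles
  for the headline claims and 2000-run ensembles of two tiny linear
  networks for the exact-moment checks against closed-form
  chemical-master-equation solutions; those sizes keep the whole suite
  within a few minutes on one core.

## What the synthetic ensembles do and do not show

The generator *is* the study: its defaults encode the study
conditions (ensemble size 100, 12-day horizon, intervention days,
fold changes, threshold distribution), and every reported behaviour is
an emergent property of those conditions.  Passing tests show the
mechanism is coherent -- a multi-entry positive-feedback cycle
reproduces the qualitative epidemiology of plaques, tangles and death
under all five experimental manipulations.  They do not show the
model is quantitatively right about real neurons: rate constants are
calibrated to reported behaviours rather than measured kinetics, copy
numbers are arbitrary, space and transport are ignored, apoptosis has
no mechanistic back-reaction on the network, and the aggregation
kinetics are deliberately accelerated so that a 12-day in-silico
window can stand in for decades of disease.

## Known limitations

* The SBML interface covers exactly the constructs this model family
  uses (mass-action kinetic laws, time-triggered parameter events);
  species role tags -- and with them the `total_p53` observable -- are
  not representable in plain SBML and are lost on import.
* Ensemble means average full trajectories, including cells already
  past their death threshold (matching the study's presentation); a
  survivor-only average would look different after day ~8.
* The dispersion reported for a single-run "ensemble" is zero by
  convention.
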