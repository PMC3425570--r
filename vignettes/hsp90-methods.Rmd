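---
title: "Methods: the HSP90 heat-shock network model and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HSP90 heat-shock network model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the shipped parameter set and how it was calibrated, the
numerical machinery, what the synthetic-data generator does and does not
emulate, and the known limitations. Nothing stated here is an empirical
claim beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## 1. The model

The network has three modules and exactly 27 dynamical species, all
governed by elementary mass-action kinetics (at most bimolecular;
degradation always first order with untracked products). Concentration
units are nominal nM, time is in seconds; absolute scales are arbitrary in
the same way densitometry scales are, which is why all data comparisons use
percent-of-max normalization.

**Module 1 — activation and trimerization.** Inactive HSF1 monomer is
synthesized at a constant rate and degrades first order. Stress — a single
dimensionless strength `k_stress`, the bifurcation parameter — multiplies
two activation rates: direct activation `HSF1 -> HSF1S` and the
dissociation of the chaperone-bound pool `C90 -> HSF1S + HSP90c`. Both
stress entries are needed: the direct path makes the response operative
when the feedback pair is silenced, and the complex-dissociation path makes
the C90 pool a stress-released reservoir. Active monomer deactivates back
(`k_deact`), dimerizes slowly, trimerizes quickly, and the trimer binds the
heat-shock element: `HSF1_3S + HSE <-> HH`. The four active free forms
degrade first order.

**Module 2 — the phosphorylation–dephosphorylation (PdP) ladder.** The
promoter-bound complex climbs `HH -> HHp -> HHpp -> HHppp -> HHpppp`, each
step through an explicit Michaelis complex with the kinase MK3.
Dephosphorylation is asymmetric: PP5 binds the tetra-phosphorylated top
(`PP5:HHpppp`), and its catalytic release generates the activated form
PP5S, which strips the remaining phosphates (the `HHppp` step and the two
lowest steps as direct second-order catalysis); PP5S deactivates back to
PP5; free PP5 also strips `HHp` and `HHpp` directly and docks on
unphosphorylated HH with high affinity (`PP5:HH`). Two structural choices
close the module: the spent complex is displaced after transcription
(promoter clearance `HHpppp -> HSE + HSF1_3S`), and free activated trimers
are decoy substrates that sequester the kinase (`HSF1_3S + MK3 <->
MK3:HSF1_3S`) — biologically, HSF1 is itself an MK3 substrate whether or
not it is promoter-bound.

**Module 3 — chaperone production and the conformational cycle.**
`HHpppp` drives transcription of `mRNA90` (zeroth order in the product),
mRNA decays and is translated into open HSP90; the conformational cycle
`open -> open:ATP -> I1 -> I2 -> closed` runs with ATP held as a fixed
input lumped into the pseudo-first-order loading rate, plus an ATPase
reset `closed -> open`. Closed HSP90 degrades, binds free inactive HSF1
(the feedback pair `k_fb_f`/`k_fb_b`, forming C90), and C90 itself slowly
degrades (`kd_c90`) — the storage-death term that matters below.

Three pools are exactly conserved (promoter element, kinase, phosphatase);
the HSF1 pool is open (synthesis and degradation). `conserved_moieties()`
recovers the three invariants as non-negative integer left-null vectors of
the stoichiometric matrix, and all steady-state machinery works on the
moiety-reduced (24-dimensional) system, because the full Jacobian is
singular along the conserved directions.

## 2. The shipped parameter set

`hsp90_parameters()` carries 62 named constants. Fifty-three are flagged
`estimated` — the package's own calibration — and nine (`kh_*`, the
conformational cycle) are flagged `literature`, set to nominal
seconds-to-minutes rates for an ATP-driven two-intermediate closing cycle.
Four entries are concentrations: the initial inactive-HSF1 pool
(289 nM) and the conserved totals of HSE (1320 nM), MK3 (92 nM) and PP5
(39.1 nM). Both rate constants of the mono-phosphorylation step are 0.08
(binding in 1/(nM s), catalysis in 1/s); the catalytic constant `k_k1_c`
is the dial used for the isola sweep.

The calibration targets were dynamical structures, not time-course fits:
the parameter set is chosen so that the model sits in the mushroom regime
with its characteristic responses to the two canonical perturbations. The
mechanisms, in the package's own terms:

- **S-shaped window (switch-on, `k_stress` about 0.47–0.49).** At low
  stress the ladder is held off: free PP5 strips the lower phospho-forms
  faster than the kinase can forward them. Rising stress raises the trimer
  supply, hence the HH occupancy; HH docks PP5 away from its stripping
  duty, mass leaks to the top of the ladder, and the top then traps the
  remaining phosphatase in the saturated `PP5:HHpppp` complex — a
  positive feedback that ignites the switch. The ON state also sustains
  itself through promoter clearance: spent complexes return trimers that
  re-bind, so ladder occupancy supports its own supply. Both branches of
  the hysteresis survive silencing of the HSP90–HSF1 feedback pair, which
  is why the knockout keeps an S-shaped diagram.
- **Z-shaped window (collapse, about 2.48–2.82).** With the feedback
  intact, closed HSP90 captures inactive monomers into C90. At moderate
  stress C90 is a slow reservoir in which a fixed fraction of captured
  monomers dies (`kd_c90`); at high stress the release rate
  `k_rel * k_stress` clears the reservoir faster than it dies, so the
  surviving active pool — and with it the free-trimer load — grows with
  stress along the upper branch. When the trimer load reaches the
  decoy-sequestration regime, MK3 is titrated away from the ladder, the
  hyper-phosphorylated top collapses, production stops, and the collapse
  self-amplifies because clearance and unbinding liberate the
  ladder-bound trimers. The knockout has no reservoir channel, its trimer
  load saturates far below the decoy regime, and the Z-window disappears —
  the collapse is a property of the feedback loop, not an assumption.
- **Isola transition.** Lowering the mono-phosphorylation catalytic rate
  `k_k1_c` from 0.08 delays ignition (S-folds move right) and advances the
  collapse (Z-folds move left): the inner limit-point gap shrinks
  monotonically (about 1.98, 1.28, 0.70, 0.25 at 0.08, 0.045, 0.03,
  0.025). Between 0.025 and 0.022 the cap pinches off the lower branch:
  the main branch becomes a fold-free monostable curve and the former cap
  survives as a closed loop of steady states over `k_stress` roughly in
  [0.74, 1.38] — an isola, reachable only by perturbation. By 0.020 the
  loop has died. `secondary_parameter_scan()` tracks the detaching loop by
  re-seeding each sweep value with stable states remembered from the
  previous one; a fresh random multistart would usually miss the isola's
  small basin.

Two tensions in the calibration are worth recording. First, the S-window
sits near 0.49, below the three stress strengths (0.41, 0.99, 1.21) used
for the synthetic fitting study, so the two higher conditions both lie on
the rising upper branch; pushing the S-fold between the two upper values
while keeping the Z-pair inside [0, 3] was not achievable in this
architecture, because lowering the direct-activation rate shifts both
structures right together. Second, a Hopf pair flags a narrow oscillatory
sliver on the upper branch near the collapse; the package detects and
reports Hopf points but deliberately does not continue periodic orbits.

## 3. Numerical machinery

**Stiff integration.** `deSolve::lsoda` with the analytic Jacobian,
absolute tolerance 1e-9 nM and relative 1e-7. The model mixes sub-second
complex kinetics with multi-hour transcription and week-scale slow modes
(promoter-site redistribution at low trimer), so non-stiff methods are
excluded. Reported trajectories change by well under 0.1% when the
tolerances are halved (tested).

**Steady states.** Newton on the moiety-reduced system with a trust-region
cap and a *non-monotone* line search: full Newton steps are allowed to
raise the residual a bounded number of times, because near roots with tiny
positive concentrations the first full step routinely overshoots before
the quadratic phase. When Newton stalls — typically along the week-scale
slow modes, where direct integration is also hopeless — a pseudo-transient
continuation (implicit-Euler steps with switched-evolution step growth)
takes over. Stability is classified from the reduced Jacobian with a
±1e-9 margin around zero (marginal in between) to avoid misclassification
at folds.

**Continuation.** Pseudo-arclength with secant predictor and Newton
corrector on the augmented system; corrector tolerance 1e-9; adaptive
scaled arclength step within [1e-8, 0.1]. States are scaled by their
starting magnitude floored at 20 nM for the full model — concentrations
grow from near zero to above 1000 nM along the branch, and without the
floor the arclength budget is consumed by state growth rather than
parameter progress. Limit points are located by the sign change of the
parameter component of the branch tangent and refined by bisection (to
about 1e-8 in the parameter); Hopf points by the sign change of the
largest complex-pair real part, refined the same way. Loop closure (isola
detection) is declared when the branch returns within a relative 1e-4 of
its start after meaningful travel; a branch that never touches either end
of the scanned range is also treated as closed, because winding loops can
exhaust the point budget before the closure test triggers. Branch points
with any component below a small negative slack are flagged non-physical
and excluded from classification.

**Independent oracle.** `brute_force_steady_states()` integrates to the
attractor from random initial conditions drawn on the conserved-moiety
manifold (log-uniform free pools, random splits of each conserved total),
then polishes with the Newton/pseudo-transient solver and clusters distinct
stable endpoints at relative radius 1e-3. Integration comes first because
raw Newton from distant random states happily converges to spurious
negative roots. On the cubic normal form the folds agree with the closed
form to 1e-10 and state counts match everywhere; on the full model the
counts match the continuation on a 25–50-point grid (the acceptance script
reports the measured agreement).

**Classification.** Rule-based on the deduplicated limit points inside the
scanned range: none and monotone gives `monostable` (or
`ultrasensitive_monostable` above a normalized slope of 10); two on one
branch give `s_` or `z_hysteresis` by comparing the stable levels outside
the window; four with two disjoint windows give `mushroom`; an odd count
gives `irreversible`; a closed branch plus another branch gives
`isola_plus_branch`. Hopf presence is a flag alongside, never a topology
label.

## 4. Estimation

The objective is plain least squares on percent-of-max series: both data
and model prediction are normalized to 100 at their own series maximum
(per experiment, mirroring arbitrary-scale blot densitometry), and each
experiment is simulated at its own stress value. Weights default to 1 with
a hook. A failed simulation returns a 1e12 penalty instead of an error so
optimizers can step over bad regions.

`fit_global()` is a scatter-search-style metaheuristic on the log10 scale:
a log-uniform initial population (optionally joined by the current values
as a warm start), an elite reference set, pairwise recombination with
over-relaxation and jitter, Nelder-Mead polish of the incumbent, and
random restarts of the worst half on stagnation. Default bounds span a
configurable log-range around the current values (the model is guaranteed
simulable there); the population size defaults to `10*sqrt(n_free)`. All
randomness is seeded. With a cold start and a degenerate parameter subset,
different seeds reach similar costs through different parameter vectors —
the identifiability degeneracy the correlation analysis quantifies.

`fit_single_parameter()` is a 1-D golden-section/parabolic search on the
log scale, used for the stress-strength recovery experiments.

## 5. Sensitivity and identifiability

Raw sensitivities are central finite differences with relative step 1e-4
(the default), or forward sensitivity equations on the augmented system;
the two paths agree to about 1e-3 relative on the decay toy and on
full-model subsets, and the toy also matches the closed form
`dy/dk = -t y`. Relative indices `SI = (dy/dp) p / y` are aggregated over
the sampling grid by root-mean-square (configurable to mean-absolute or
end-point); times where the output magnitude is below 1e-12 nM are
excluded from relative scaling. The sampling grid defaults to the
synthetic experiments' time points, and the shipped analysis evaluates
each measured output at its own experimental stress value.

The identifiability matrix is the Pearson correlation between parameter
columns of the raw array stacked over outputs and times; zero-variance
columns are flagged NA rather than propagated as NaN. At the shipped set
the matrix contains hundreds of near-±1 pairs, many spanning the
activation module and the PdP module — compensating parameter changes the
four time courses cannot distinguish.

One finding the package reports as measured: for the phosphorylated
complex output the top-ranked constants include the kinase and phosphatase
rates, but for the free-trimer output the ranking is dominated by the
upstream activation cycle (activation, deactivation, supply and decay) —
in this calibration trimer occupancy is controlled before the ladder, not
inside it.

## 6. The synthetic-data generator

`generate_study()` emulates the *statistical shape* of sparse
immunoblot-style time courses: four experiments — trimer occupancy at
three increasing stress strengths (defaults 0.4136, 0.9859, 1.2066) and
the mono-phosphorylated complex at a fourth (0.9557) — sampled on an
irregular grid that is dense over the first 600 s and sparse out to
14400 s, normalized to percent of maximum, with additive Gaussian noise in
percent units (default sd 5; multiplicative available behind an option)
clamped below at zero. Normalization precedes noise, so values above 100
are permitted. The injected noise is recorded per point, which makes the
bookkeeping identity exact: the cost at the generating truth equals the
summed squared injected noise.

What the generator does *not* emulate: the shipped kinetics approach their
steady states much more slowly than the 4-hour sampling window (the slow
modes run to 1e5–1e6 s), so all four series are still rising at the last
sample and the low-stress series do not show a peak-and-attenuation shape;
the series differ mainly in absolute scale and early curvature. Two
consequences follow and are visible in the tests. Noiseless recovery of
the stress strength is essentially exact (the shape retains enough
information at machine precision). Under 5% noise, recovery of the two
higher stress values is biased low by 10–20%, because above `k_stress`
of about 0.9 the *normalized* shape saturates in the stress strength —
the conditions differ mostly by scale, which percent-of-max normalization
removes. Passing the noiseless tests therefore says the estimator and
generator are consistent; it does not say the stress strength is well
identified from normalized data at high stress, and the noisy tests
document exactly where it is not.

## 7. Problem sizes used by the tests

The unit suite runs the full 27-state model throughout; continuation uses
up to 5000 points per diagram at a maximum scaled step of 0.1; the oracle
cross-validation uses 25–50 grid points with 5–8 random starts each;
recovery experiments use 10 sampling times and 10 noise seeds per
condition; scatter-search tests use budgets of about 200–260 evaluations
on 2–6 free parameters. These sizes were chosen so the whole suite
exercises every code path at full model dimension while remaining a
routine desktop run.

## 8. Known limitations

- Hopf points are detected and reported, but periodic orbits are not
  continued; the oscillatory sliver near the collapse fold is flagged, not
  characterised.
- The S-shaped window is narrow (about 0.023 wide in `k_stress`) and sits
  below the synthetic study's stress values; see the calibration notes
  above.
- The isola search is seed-assisted; a purely random multistart can miss
  the isola's small basin, which is why the sweep carries states between
  neighbouring secondary values.
- No SBML import/export, no stochastic simulation, no compartments, and no
  two-parameter continuation; the parameter file interface is the flat
  key=value format plus XPPAUT-tolerant import and `.ode` export.
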