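---
title: "A reduced-order model of complement activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of complement activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(complementr)
```

## Scope and modeling philosophy

`complementr` implements a deliberately small kinetic description of the
lectin and alternative complement pathways: 18 ordinary differential
equations and 28 free parameters. The compactness is bought with three
simplifications, each of which is a modeling assumption the user should be
aware of:

1. **Lumped initiation.** Classical-pathway C1 activation is not modeled;
   lectin and classical inputs are merged at the level of C4/C2 cleavage.
   Alternative-pathway tickover is a single first-order C3 → C3a + C3b step;
   the C3w/C3wBb intermediates are absorbed into the AP C3 convertase
   assembly step, and factors B and D are assumed to be in excess (so AP
   convertase assembly is first order in C3b).
2. **Rule-based control.** Regulation enters as multiplicative control terms
   `v ∈ [0, 1]` built from Hill transfer functions combined by a `min`/`max`
   integration rule, not as explicit binding balances. Factor H and C4BP act
   only through inhibitory control factors, so their own balances are
   constant. The zymosan trigger is an activating Hill gate on the two
   lectin-initiation reactions, which closes completely at zero dose.
3. **Truncation at C5.** The terminal pathway (C6–C9, MAC assembly and its
   regulators) is out of scope; the model stops at C5a/C5b.

Cleavage and convertase activity use saturation kinetics
`kmax · ε · x^η/(K^η + x^η)`; protein–protein binding uses irreversible mass
action. Irreversibility is an approximation chosen for identifiability: with
sparse C3a/C5a time courses, forward/reverse pairs are not separable.

## The time-scale factor τ

Species balances are assembled as `dx/dt = τ · S (r ∘ v)`. The factor
`τ = z/z*` (reference dose `z*` = 1 mg/ml) applies to the two
initiator-scaled species, C5a and C5b, and captures unmodeled dose-dependent
effects: at sub-reference doses C5a production slows, producing the
dose-dependent C5a lag, and at the reference dose `τ = 1` leaves the
balances untouched. Two aspects deserve emphasis:

* The balance form is multiplicative on the derivative (`dx/dt = τ·Σσr`
  rather than `(1/τ)·dx/dt = Σσr` read as division); the algebra admits
  either reading, and the multiplicative one is what produces a *slower*
  C5a response at low dose, matching the observed behavior.
* At `z = 0` the scaling is not applied (`τ = 1`): the correction models
  initiator-driven effects, and the alternative pathway must still produce
  C5a without any initiator — the no-zymosan condition is one of the two
  training objectives. A literal `τ = 0` would disconnect C5a from the
  model everywhere the lectin gate is shut.

Only C5a and C5b are initiator-scaled; the rule is declared per species in
the model definition (`tau = "initiator"`) and can be moved to other species
in user-supplied model files.

## Network reconstruction and the 28-parameter budget

No reaction table is printed for the original network, so the shipped
reaction list is reconstructed from the pathway structure under the
constraint of exactly 18 states and 28 free parameters: two gated lectin
cleavages (C4, C2), CP convertase assembly (C4b + C2a; the biochemically
standard pairing), CP/AP C3 convertase activity under C4BP / factor H
control, tickover, AP convertase assembly, two C5 convertase assemblies
(convertase + C3b), two C5 cleavages, and first-order C3a/C5a clearance.
Everything is user-editable through the YAML model format
(`read_model()`/`write_model()`), so a discrepancy with any other encoding of
the network can be patched without code changes.

The parameter budget lands on 28 as follows: the six saturation reactions
contribute `kmax` and `K` each, and the four convertase-activity reactions
additionally a free Hill order `η ∈ [1, 4]`; the three binding reactions and
four first-order steps contribute one rate constant each; the zymosan gate
contributes its gain, and each of C4BP and factor H a gain and an order.
Two shape choices are deliberately fixed rather than free: the lectin
cleavage saturation orders (η = 1 — no evidence for cooperativity upstream)
and the zymosan gate's Hill order (2 — the gate is a structural switch whose
steepness is not identifiable from a two-dose training design). Parameters
are declared in network order; the declaration index is the parameter index
used in reports (e.g. index 12 = tickover rate, 13 = AP C3 convertase
assembly).

## Units, initial conditions and nominal values

Concentrations are nM and time is hours. Initial conditions are
physiological serum levels converted by molecular weight (C3 1.2 mg/ml ≈
6500 nM, C4 0.4 ≈ 1950 nM, C2 0.025 ≈ 245 nM, C5 0.075 ≈ 395 nM, factor H
0.5 ≈ 3200 nM, C4BP 0.25 ≈ 440 nM); all fragments and complexes start at
zero, and a model file may specify `initial_mg_ml` + `mw_kda` to let the
loader convert. Nominal kinetic constants are the package's own choices,
fixed once so that the qualitative behaviors of the system hold
simultaneously: C3a roughly three orders of magnitude above C5a, C3a
reaching ≥ 90% of its plateau by 8 h at 1 mg/ml zymosan, dose-monotone C5a,
and C5a robustness to C3 knockdown when both pathways are active. They are
not asserted as measured rate constants; bounds default to ±2 decades
around nominal.

## Estimation machinery

**Objective.** For every (condition, species) series the objective adds a
shape term — squared differences between min–max scaled measurements and the
min–max scaled simulation interpolated linearly to the measurement times —
and a scale term `((M′ − max y)/M′)²` comparing the largest measured
concentration with the largest simulated value. Min–max scaling makes the
shape term invariant to measurement units; only the scale term sees
amplitude. Two objectives are used: `O1` (C3a + C5a residual without
initiator) and `O2` (at 1 mg/ml). Note that the scale term compares against
the trajectory-wide simulated maximum, so a "perfect" fit retains a tiny
positive residual whenever the simulated peak falls between sampling times.

**Search space.** Both optimizers work in log10 parameter space, since rate
constants span decades; bounds are the declared parameter bounds clipped to
±2 decades around nominal.

**Warm start.** A two-phase heuristic: independent particle swarms (3
swarms × 8 particles, standard constriction parameters) for 40% of the
evaluation budget or until 25 stagnant sweeps, then dynamically dimensioned
search — perturbing a randomly chosen subset of dimensions whose inclusion
probability decays as `1 − log(m)/log(M)`, with Gaussian steps of 0.2 × the
bound range, reflected at the bounds. The default start is the centre of the
log-bound box, which coincides with the nominal parameter set. The phase
switch point is a pragmatic approximation, not a reproduction of any
published trigger.

**Pareto ensemble.** A simulated-annealing walk accepts any candidate that
is non-dominated with respect to the current archive, and dominated
candidates with Metropolis probability `exp(−ΔO/T)` on the summed-objective
increase. The temperature starts at the spread of the summed objective over
a few probe perturbations and cools geometrically (×0.9 every 10
iterations — the schedule is a design choice; none is prescribed). The
archive keeps all accepted points with refreshed layered non-dominated
ranks; the returned ensemble is trimmed to a configurable target size
(default 100; full-scale studies would use thousands — scaling down is
explicit, not hidden).

**Model comparison.** `AIC = 2·N_p + N_m·ln(RSS/‖M‖)`. The data-scale
normalisation `‖M‖` is not uniquely defined in the field; the default is the
sum of squared measurements (making the log argument a relative residual),
with `N_m · max(M)²` available by flag. Fitted ensembles are compared
against log-uniform random-parameter controls drawn within the same bounds.

## Global analysis

**Sobol sensitivity.** Saltelli sampling produces exactly `N(2d+2)` rows
(A, B, and the `AB_i`/`BA_i` cross matrices, Latin-hypercube base samples,
uniform in log10 of the bounds by default); total-order indices use the
Jansen estimator averaged over the A/AB and B/BA forms, with bootstrap
confidence intervals over base samples. The analysed output is the training
residual of a chosen condition set. The full study scale is N = 400 at
d = 28 (23,200 evaluations); the shipped tests and the acceptance script run
the model-level analysis at N = 4–16 and verify the estimator itself against
the Ishigami closed form at N = 1024, where estimates land within 0.05 of
truth. Failed integrations inside a sensitivity sweep are pinned at the
worst observed residual rather than dropped, keeping the Saltelli layout
intact.

**Pairwise displacement.** Every ordered parameter pair is increased by 10%
(the diagonal therefore compounds to a (1.1)² single-parameter change), the
model re-simulated at 1 mg/ml initiator, and the euclidean distance between
the perturbed and nominal trajectories (full concatenated state trajectory
by default — stricter and dimensionally stable; terminal state available via
`use = "final"`) averaged over ensemble members and log10-transformed with a
1e-12 floor. Rows are clustered into three groups (Ward linkage, euclidean
metric) labelled high/medium/low by cluster-mean displacement. Note that a
structurally inert parameter shows its null only on the diagonal — off-
diagonal cells move through the partner parameter.

**Robustness.** Knockdowns multiply the initial condition of C3, C5, or both
by 1 − fraction (50/90/99%), with and without initiator; the coefficient is
`log10(AUC_perturbed/AUC_nominal)` of C3a or C5a over the simulation window,
averaged over an ensemble subset (default: Pareto rank < 5). The structural
identity that C5 knockdown cannot move C3a (C5 has no edge into any
C3a-producing or consuming reaction) holds to integrator tolerance
(≈ 1e-11) and is asserted in the tests.

## Numerical choices

* Integrator: `deSolve::ode(method = "lsoda")`, rtol 1e-6, atol 1e-9 —
  stiff-capable with automatic switching; convertase feedback makes the
  system stiff at high initiator dose. States are clamped at zero inside the
  rate evaluation (irreversible mass action can undershoot numerically) and
  on output.
* Output grid: 200 even points by default; AUCs are trapezoidal on this
  grid, with window endpoints interpolated linearly. Halving the grid moves
  smooth-trajectory AUCs by well under 0.1%.
* Simulation-to-measurement alignment: linear interpolation at measurement
  times.
* Degenerate inputs: constant measurement series cannot be min-max scaled
  (error); a flat simulated series scales to zeros; zero nominal AUC makes a
  robustness coefficient undefined (error); a zero-variance sensitivity
  response raises rather than returning NaNs; ensemble members that fail to
  integrate are skipped and counted, never NaN-filled.

## The synthetic data generator

`generate_measurements()` emulates an immunoassay time-course experiment:
a zymosan titration (0, 0.001, 0.01, 0.1, 1 mg/ml), 8 samples per condition
over 8 hours, C3a and C5a measured, multiplicative log-normal noise with
σ = 0.05 (an immunoassay-like CV; the true assay error model of any given
dataset is unknown). Doses 0 and 1 mg/ml are tagged for training, the
intermediate doses for validation — two training and three validation
conditions per species. What it does **not** emulate: real inter-donor
variability, non-constant assay CVs, detection limits/censoring, matrix
effects, or any systematic model discrepancy — the generator samples the
model itself, so passing recovery tests demonstrates that the estimation
machinery works, not that the model is true. Pipelines accept externally
supplied tables in the same CSV schema.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run everything at desk scale, a
deliberate package choice: warm start budget 150 evaluations + 150
annealing proposals with a 60-member archive; Sobol at N = 16 (928 model
evaluations) for the model-level analysis and N = 1024 for the
estimator-vs-closed-form check; robustness on the nominal parameter set or
the near-front ensemble subset. The structure of every computation is
identical at full scale — only `N`, `budget`, `iterations` and
`ensemble_size` change.

## Known limitations

* The reconstructed reaction list and the nominal parameterisation are this
  package's own; they reproduce qualitative behaviors, not any specific
  laboratory dataset.
* Reversible binding, factor B/D balances, C3w intermediates,
  surface-vs-fluid compartments, MAC assembly and C2-bypass initiation are
  all out of scope by design.
* The optimizers are simplified, behavior-equivalent forms of their
  published namesakes (multi-swarm + DDS hybrid; Pareto simulated
  annealing); they are not bit-for-bit reimplementations.
* With an excellent warm start the Pareto front can collapse to few
  members; increase `iterations`/`step` to trace a broader trade-off
  surface.
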