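# complementr

Reduced-order kinetic modeling and perturbation analysis of human complement
activation.

The complement cascade is a proteolytic amplification network at the core of
innate immunity: initiation through the lectin pathway (triggered here by a
zymosan dose) or the alternative pathway (seeded by spontaneous C3 "tickover"
hydrolysis) assembles C3 convertases, which cleave C3 into the anaphylatoxin
C3a and the opsonin C3b; C3b recruitment converts C3 convertases into C5
convertases, which release C5a and C5b. Fluid-phase regulators (factor H,
C4BP) restrain the convertases. `complementr` is for modelers who need a
compact, estimable description of this cascade — for example as a component of
a larger pharmacokinetic model — rather than a 100-state mechanistic one.

## The model

The shipped network has **18 state variables and 28 free kinetic
parameters**. Species balances follow

```
dx_i/dt = tau_i * sum_j sigma_ij * r_j(x, eps, k) * v_j
```

where `sigma_ij` is the stoichiometric matrix, `r_j` a saturation
(`kmax * eps * x^eta / (K^eta + x^eta)`), irreversible mass-action
(`kmax * prod x_s^(-sigma_sj)`) or first-order kinetic term, and
`v_j ∈ [0, 1]` a rule-based control term: Hill transfer functions of the
controlling factors combined by a `min`/`max` integration rule (`v_j = 1`
for unregulated reactions). The time-scale factor `tau_i = z / z*`
(`z*` = 1 mg/ml) applies to C5a and C5b when an initiator dose `z > 0` is
given, reproducing the dose-dependent C5a lag. Concentrations are in nM,
time in hours.

Around the model, the package provides:

- **simulation** — stiff ODE integration (`deSolve`), ensemble confidence
  bands, trapezoidal AUCs;
- **estimation** — min-max measurement scaling, a two-term shape+scale
  objective, a hybrid particle-swarm / dynamically-dimensioned-search warm
  start, a multiobjective simulated-annealing Pareto ensemble, AIC scoring
  against log-uniform random-parameter controls;
- **global analysis** — Saltelli sampling with Jansen total-order Sobol
  indices, pairwise 10% perturbation displacement clustering, and log10-AUC
  robustness coefficients for C3/C5 knockdowns;
- **synthetic data** — immunoassay-style C3a/C5a time courses over a zymosan
  titration (train on 0 and 1 mg/ml, validate on intermediate doses).

## Worked example

```r
library(complementr)

model <- default_complement_model()
model
#> <complement_model>
#>   species:     18
#>   reactions:   13
#>   parameters:  28
#>   initiator:  zymosan (mg/ml)

traj <- simulate_model(model, dose = 1)   # 1 mg/ml zymosan, 8 h
tail(traj[, c("time", "C3a", "C5a")], 3)
#>    time   C3a   C5a
#> 1  7.92 4920.  22.0
#> 2  7.96 4906.  22.8
#> 3  8    4892.  23.5
```

C3a accumulates to thousands of nM while C5a stays near 20 nM — the two
markers are separated by over two orders of magnitude at the reference dose
(more than three without initiator). Knockdown robustness coefficients
(`alpha` = log10 of the AUC ratio perturbed/nominal; 0 = no effect):

```r
rt <- robustness_study(model, levels = 90, doses = 1)
rt[rt$marker == "C5a", ]
#>   marker target level dose  alpha n_members
#> 1    C5a     C3    90    1 -1.220         1
#> 2    C5a  C3+C5    90    1 -2.093         1
#> 3    C5a     C5    90    1 -0.876         1
```

A 90% knockdown of C3 and C5 together suppresses C5a exposure by two orders
of magnitude — far more than either single intervention, the model's central
pharmacological prediction. Fitting and sensitivity follow the same
data-frame-in, tibble-out style:

```r
measurements <- generate_measurements(model, synthetic_protocol(sigma = 0.05))
train <- train_validate_split(measurements)$train
fit <- fit_complement(train, model, budget = 150, iterations = 150, seed = 1)
glance(fit)                      # front size, best objectives, AIC
autoplot(simulate_ensemble(model, fit, dose = 1))
sobol_sensitivity(model, train, conditions = "zymosan_1", N = 16,
                  ensemble = fit)
```

A thin command-line wrapper with `simulate`, `generate-data`, `fit`,
`sensitivity` and `robustness` subcommands ships in `inst/cli/complementr`.

## Documentation

The methods vignette (`vignettes/complement-model.Rmd`) describes the
network reconstruction, parameterisation, estimation machinery and the
analysis design in detail, including what the synthetic data generator does
and does not emulate.
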