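# recirc

Whole-organism kinetics of lymphocyte recirculation in the rat.

Naive thoracic-duct lymphocytes (TDLs) travel continuously between blood,
lung and liver vasculature, spleen, lymph nodes and Peyer's patches. How
fast they enter each tissue and how long they stay there determines how
quickly the immune system surveys the body, yet classic adoptive-transfer
and cannulation experiments were long interpreted only qualitatively.
`recirc` is for quantitative immunologists and modellers who want to turn
such time courses into rates: it implements a linear compartment model of
TDL traffic, fits it to data, and derives the predictions that make the
model useful.

The model: blood feeds each organ at entry rate $s_i$ (per minute) and
organs return cells at exit rates $m_i$, with three structural features —
Peyer's-patch efflux drains into the mesenteric nodes rather than blood;
lymph-node transit passes through $k$ serial sub-compartments, making
node residence times gamma-distributed with mean $k/m$; and a removal rate
$\mu$ drains the blood, a fraction $\varphi$ of it accumulating in the
liver as dying cells. A cannulation switch harvests thoracic-duct outflow
(all mesenteric plus a fraction $f \approx 0.5$ of subcutaneous-node
efflux) while node transit slows as $e^{-\nu t}$.

What the package provides:

* `simulate_trajectory()` — stiff-safe forward simulation (compiled
  right-hand side, conservation to 1e-6);
* `steady_state()`, `mean_residence_time()`,
  `residence_time_distribution()` — closed-form arithmetic;
* `fit_migration()`, `joint_fit()`, `compare_models()`, `bootstrap_ci()` —
  least-squares and generalized-likelihood estimation with multi-start
  Levenberg–Marquardt, F-test/AIC comparison and residual-bootstrap CIs;
* `predict_cannulation()`, `scenario_table()`, `fit_stimulated_node()`,
  `simulate_entry_blockade()`, `expected_vascular_passes()` — the derived
  predictions (duct output, perturbation steady states, stimulated-node
  decomposition, blockade bias, pass counts);
* `generate_migration_dataset()` and friends — synthetic datasets with the
  error structure the analysis assumes;
* broom-style `tidy()`/`glance()`, `autoplot()` methods, CSV readers and
  writers, and a thin command-line interface (`inst/cli/recirc.R`).

## A worked example

```r
library(recirc)

p <- reference_params()          # published rat TDL rate estimates
mean_residence_time(p) / 60      # hours
#>       blood        lung       liver      spleen        scln         mln          pp
#> 0.007114298 0.007680492 0.014619883 2.380952381 9.803921569 9.803921569 9.803921569
```

Cells spend ~26 seconds in the blood and under a minute in lung or liver
vasculature per pass, but ~2.4 h in the spleen and ~9.8 h in lymph nodes:
the lymphoid organs are slow sinks fed by a very fast vascular loop.

```r
steady_state(p)
#> # A tibble: 7 x 2
#>   organ  percent
#>   <chr>    <dbl>
#> 1 blood    2.63
#> 2 lung     2.22
#> 3 liver    0.947
#> 4 spleen  21.1
#> 5 scln    40.3
#> 6 mln     24.6
#> 7 pp       8.21
```

At steady state only ~2.6% of labelled cells are in the blood; two thirds
sit in lymph nodes. Perturbations reshape this sharply — a 20-fold longer
lung residence (inflammation) parks 31% of cells in the lung:

```r
steady_state(apply_scenario(p, scenario_lung_inflammation()))
#> ...
#> 2 lung    31.2
```

Fitting synthetic data regenerated from the model recovers the rates:

```r
d <- generate_migration_dataset(p, noise = noise_spec(seed = 1))
fit <- fit_migration(d, k = 2)
tidy(fit)        # estimates on the natural scale
glance(fit)      # SSR, AIC, convergence
autoplot(fit)    # data and fitted curves, log time axis
```

And the cannulation prediction that motivates the exit-decline parameter:
with no decline the model collects ~80% of transferred cells in 45 h of
thoracic-duct cannulation — far more than observed in such experiments,
which is why node egress must slow during cannulation:

```r
pc <- predict_cannulation(p, f = 0.5, nu = 0)
tail(pc, 1)
#>    time duct_rate cumulative
#> 1  2700     0.966       79.8
```

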