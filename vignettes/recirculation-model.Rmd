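---
title: "Modelling whole-organism lymphocyte recirculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-organism lymphocyte recirculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recirc)
```

## The model

Naive lymphocytes collected from the thoracic duct (TDLs) recirculate
continuously between the blood and the major lymphoid and nonlymphoid
tissues. `recirc` implements a linear compartment model of this traffic in
the rat. Blood is the hub: cells leave it into the lung, liver, spleen,
subcutaneous lymph nodes (SCLN, the pooled skin-draining nodes), mesenteric
lymph nodes (MLN) and Peyer's patches (PP) at organ-specific entry rates
$s_i$ (per minute), and return at exit rates $m_i$. Two deviations from pure
hub-and-spoke topology encode known physiology:

* **PP drain into MLN**, not into blood: the efflux of the Peyer's-patch
  chain feeds the first mesenteric sub-compartment.
* **Two lymphatic ducts**: SCLN efflux reaches the blood via the thoracic
  (left lymphatic) duct with probability $f$ (default 0.5) and via the right
  lymphatic duct otherwise; MLN efflux travels entirely through the thoracic
  duct.

Lymph-node transit shows a reproducible delay that a single exponential
cannot produce, so each LN/PP compartment is a serial chain of $k$
sub-compartments with a common per-stage rate $m$. Transit times through the
chain are then gamma-distributed with shape $k$ and mean $k/m$. The
sub-compartments are a mathematical device for non-exponential residence
times, not anatomical claims. $k = 2$ is the default (it describes the
migration time courses best); $k$ from 1 to 3 is supported.

Two further pools close the mass balance. A removal rate $\mu$ takes cells
out of the blood (death plus migration to unsampled organs); a fraction
$\varphi$ of that flux is deposited in the liver as dying/dead cells, which
matters because the measured liver signal is live transit plus accumulated
dead cells. The state also tracks a cumulative `removed` pool and, during
cannulation, the cumulative label collected from the duct, so every
trajectory satisfies a conservation identity (total = 100%) that the test
suite checks to $10^{-6}$.

**Cannulation mode** (the switch $\xi$): when the thoracic duct is
cannulated, MLN efflux and the fraction $f$ of SCLN efflux are harvested
instead of returning to the blood, and all LN/PP chain rates decline as
$e^{-\nu t}$ — cannulation drains the nodes, and reduced cellularity slows
egress. $\nu$ applies uniformly to every LN/PP chain transition (the model
has one LN/PP rate scale); lung, liver and spleen rates are unaffected.

## Reference parameters and two calibrated values

`reference_params()` carries the published point estimates for rat TDLs:
entry rates 1.83 (lung), 0.41 (liver), 0.056 (spleen), 0.026 (SCLN), 0.0106
(MLN), 0.0053 (PP) per minute; exit rates 2.17, 1.14, 0.007 per minute and a
shared LN/PP per-stage rate 0.0034 per minute. These imply a blood residence
of ~26 s, under a minute in lung and liver vasculature, ~2.4 h in the
spleen and ~9.9 h in LNs/PPs at $k = 2$:

```{r residence}
mean_residence_time(reference_params()) / 60 # hours
```

Two parameters are not published as numbers and are calibrated here once:

* `removal = 0.0048` per minute — chosen so that simulated whole-body
  recovery of label at 24 h equals the reported 90%. Without removal the
  model would retain all label indefinitely, and long-horizon predictions
  (notably cumulative duct output) would be biased high.
* `dying_fraction = 0.5` — the share of removed cells parked in the liver
  is not identifiable from published summaries (it only redistributes loss
  between an invisible pool and the liver plateau). It must be well above
  zero for the model to produce the liver accumulation it exists to
  explain; one half is adopted as the neutral convention.

Both choices are deliberate conventions of this package, documented here
and revisited nowhere else.

## Steady states and perturbation scenarios

With removal off, the flow network has a closed-form steady state: each
single-compartment organ holds $s_i/m_i$ relative to blood, each chain
stage holds its throughput over its rate (so chains scale with $k$, and the
MLN throughput includes the PP flux). `steady_state()` normalizes the seven
organ totals to 100%. `scenario()` objects apply multiplicative rate
modifiers before the computation; the presets mirror classic perturbations
— lung inflammation (lung exit ÷ 20), anti-CD62L antibody (LN/PP entry
÷ 20), FTY720 (LN/PP exit ÷ 5):

```{r scenarios}
scenario_table(reference_params()) |>
  tidyr::pivot_wider(names_from = scenario, values_from = percent)
```

Every scenario prediction is verified in the tests against brute-force
integration to $t = 10^7$ minutes (agreement < 0.1 percentage points).

## Fitting

`fit_migration()` estimates the 12 free parameters (6 entry rates, 3
single-organ exit rates, the shared LN/PP rate, $\mu$, $\varphi$) from a
long-format (organ, time, percent) table by nonlinear least squares on the
raw percent scale. Rates are optimized as logarithms and fractions as
logits, which enforces positivity and boundedness without constraints.
Optimization is Levenberg–Marquardt with multi-start (5 jittered starts by
default) around a data-driven initial point (early-time uptake fractions
for entry rates, quasi-equilibrium organ/blood ratios for exit rates).

Numerical choices that matter:

* the ODE is integrated with a stiff-capable solver at `rtol 1e-9`,
  `atol 1e-12` for user-facing simulation (rates span three orders of
  magnitude) and `1e-8`/`1e-10` inside fit loops;
* finite-difference steps for the LM Jacobian are widened (`epsfcn`) so
  they sit well above the solver's error floor — with default steps the
  Jacobian is integration noise and the optimizer stalls;
* degenerate inputs fail loudly: negative times, non-finite parameters,
  zero exit rates with positive inflow, missing organs (named in the
  error), duplicate records.

`joint_fit()` adds the cannulation dataset under a generalized likelihood
with dataset-specific normal error variances. Profiling the variances at
$\hat\sigma_i^2 = \mathrm{SSR}_i/n_i$ reduces the objective to
$n_1\log \mathrm{SSR}_1 + n_2\log \mathrm{SSR}_2$, minimized by
Nelder–Mead with a BFGS polish, seeded by a migration-only fit. The exit
decline $\nu$ is the extra free parameter; $f$ is fixed at 0.5 by default
because entry/exit rates and $f$ are strongly confounded in duct-output
data (it can be freed).

`compare_models()` provides the F-test for nested least-squares fits
(shared versus organ-specific LN/PP exit rates are treated as nested — the
shared model is the equality constraint) and a least-squares AIC,
$n\log(\mathrm{SSR}/n) + 2p$ with the additive constant dropped, valid only
within one dataset.

`bootstrap_ci()` resamples residuals within each dataset, inflated by
$\sqrt{n/(n-p)}$ to undo the variance deflation of least-squares residuals,
refits from the point estimate, and reports percentile intervals. 1000
replicates is the production default; the packaged studies use fewer (see
below).

## Virtual experiments

* `predict_cannulation()` — duct output rate (percent of transferred cells
  per hour) and cumulative collection from a bolus. With the reference set,
  $k = 2$, $f = 0.5$ and no exit decline, ~80% of transferred cells are
  collected within 45 h; with the fitted decline the peak flattens and
  shifts late.
* `fit_stimulated_node()` — decomposes stimulated versus resting popliteal
  node accumulation into per-node entry and exit rates. The node is an
  auxiliary chain driven by the global blood curve (it holds too little
  label to feed back). Inside the fit loop the chain is evaluated by
  closed-form convolution of the blood trajectory (variation of constants
  plus trapezoid quadrature on a dense grid) rather than by re-integrating
  the ODE; the generator keeps the ODE route, so round-trip tests
  cross-validate the two implementations. An exponential-in-time modifier
  of node rates is deliberately *not* provided: time-varying entry/exit
  trends fitted to such data tend to be biologically unreadable, and the
  constant-rate decomposition is the quantity of interest here.
* `simulate_entry_blockade()` — pre-equilibrates the system, scales LN/PP
  entry by $1-\mathrm{efficacy}$, and fits a single exponential to the
  SCLN decay, reproducing the design of antibody-blockade experiments. The
  skin-draining pool is the default observable because it receives no
  inter-node inflow; with partial blockade the content decays to a nonzero
  equilibrium and the fitted "apparent egress rate" underestimates the
  true exit rate — a caution for blockade-based residence estimates. With
  $k = 2$ the decay is a two-exponential that still fits a single
  exponential with $R^2 > 0.98$ over 48 h, so an exponential-looking
  decline is not evidence of exponential residence times.
* `expected_vascular_passes()` — treating each blood exit as a Bernoulli
  trial, the expected number of lung/liver passes before a cell first
  enters a secondary lymphoid organ is $(1-p)/p$ with
  $p = (s_{spleen}+s_{scln}+s_{mln}+s_{pp})/\sum_i s_i$. Removal is
  excluded from the denominator by default (the pass count concerns
  organ-bound traffic); the reference rates give $p \approx 0.042$ and
  about 23 passes.

## The synthetic-data generator

`generate_migration_dataset()`, `generate_cannulation_dataset()` and
`generate_stimulated_node_dataset()` emulate the three experimental
designs: organ harvests at 1, 2, 5, 10, 30 minutes and 1, 2.5, 6, 9, 12,
15, 18, 24 hours; duct collection at 90-minute intervals over 45 h; and
paired node time courses. The error model is additive i.i.d. normal noise
with dataset-specific SDs, matching the assumption of the generalized
likelihood. Negative noisy percents are clamped to zero (percent data
cannot be negative) and the clamp count is attached as an attribute.

Noise defaults are conventions: per-time-point SDs were never published.
The migration default (0.5 percent units) is calibrated so that a
synthetic dataset determines the entry rates with the precision of the
published intervals — the published series are means over at least five
animals, and larger noise would make the lung entry rate (which sits on a
flat likelihood ridge against the fast blood–lung exchange) far less
determined than the published CI implies. The cannulation default (0.2
percent/h) resembles the scatter of the digitized duct-output series.

What passing tests on synthetic data do **not** show: the generator draws
from the model itself, with homoscedastic noise and no per-animal
structure, digitization error, or model misspecification. Recovery and
coverage results therefore certify the inference machinery, not the
biological correctness of the model on real measurements.

## Statistical calibration studies (problem sizes)

The packaged studies are sized to run routinely: bootstrap coverage uses
the node-model entry rate over 200 synthetic datasets with 99 bootstrap
replicates each (percentile intervals at this depth are expected to sit
slightly below nominal 95%); the F-test size check uses 400 simulated
null datasets of the equal-exit node model. The 12-parameter migration fit
is certified by noiseless and noisy recovery tests instead of resampling
studies.

## Known limitations

* Lung and liver are single well-mixed vascular compartments; parenchymal
  retention is outside scope.
* The LN pools are aggregates; per-node chains and afferent-lymph entry are
  not modelled.
* The lung entry rate is weakly identified from a single noisy time course
  (flat ridge with lung exit); multi-start helps, but interval estimates
  should come from the bootstrap, not from the point fit.
* $\nu$ is a phenomenological description of cannulation-induced slowdown,
  applied uniformly to all LN/PP transitions.
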