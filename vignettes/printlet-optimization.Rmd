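---
title: "Models and methods for printlet formulation optimization"
author: "printletr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for printlet formulation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printletr)
```

## The problem

Extended-release tablets ("printlets") can be fabricated by digital light
processing (DLP) 3D printing from a photoreactive resin of PEGDA (the
crosslinkable monomer), PEG 400 (a non-crosslinking diluent), water,
riboflavin as photoinitiator (fixed at 0.10% w/w) and ibuprofen as model
drug (fixed at 5.00% w/w). The three variable components form a
constrained mixture summing to 94.9% w/w, with design bounds PEGDA
30.0–74.6%, PEG 400 10.0–54.6% and water 10.0–30.0%. Composition controls
everything of interest — tablet weight, hardness, drug load and above all
the dissolution profile — but the relationships are noisy and partly
non-linear, so the workflow combines four modelling layers:

1. **Scheffé mixture polynomials** relate composition to scalar tablet
   properties and support D-optimal design of the experiment;
2. **release-kinetics models** (zero-order, first-order, Higuchi,
   Korsmeyer–Peppas) describe each dissolution curve and classify its
   transport mechanism;
3. a **multilayer-perceptron surrogate** learns the composition →
   dissolution-profile map, which the polynomials capture poorly;
4. a **desirability function** turns release targets at 2/4/6/8 h into a
   single objective maximized over the bounded mixture simplex, and the
   optimized profile is compared with a reference using the
   model-independent f1/f2 factors.

`builtin_fixtures()` carries the published study tables (compositions,
printing parameters, tablet properties, kinetic parameters, and the
experimental-versus-predicted release values for the optimized
formulation) so that every desk-scale quantity can be recomputed.

## Mixture models and their statistics

For components $x_1, x_2, x_3$ that sum to a constant, polynomials are
fitted in the Scheffé canonical form without an intercept: linear
$\sum_i \beta_i x_i$; quadratic adds $x_i x_j$; special cubic adds
$x_1 x_2 x_3$; the full cubic adds the cross-difference terms
$x_i x_j (x_i - x_j)$ (10 terms in total). Fitting is done directly in
actual % w/w units rather than pseudo-components: the published blending
equations are stated in actual units, and with the mixture total nearly
constant across runs (94.6–94.9%) the two parametrizations are
near-equivalent up to a rescaling of coefficients (a property the test
suite checks exactly).

Model statistics follow the conventions of mixture-design software, which
the package reproduces to within a fraction of a percent on the reference
tables: $R^2$ is computed against the *mean-corrected* total sum of
squares even though the model has no intercept; because the fixed-sum
constraint absorbs one parameter, a model with $t$ canonical terms has
model df $t-1$ and residual df $n-t$, giving
$R^2_{adj} = 1-(1-R^2)(n-1)/(n-t)$. PRESS is the leave-one-out predicted
residual sum of squares, computed through the hat-diagonal identity
$e_{(i)} = e_i/(1-h_{ii})$ (the test suite verifies this against explicit
refits), and $R^2_{pred} = 1 - \mathrm{PRESS}/SS_{tot}$. Degrees whose
term count leaves no residual df are reported unavailable rather than
fitted.

```{r mixture}
fx <- builtin_fixtures()
design <- fx$formulations[fx$formulations$design_point, ]
fit <- fit_mixture_model(design, fx$tablet_properties$weight_mg,
                         "linear", "weight")
fit
```

**Model selection.** The selection criterion maximizes the adjusted and
the predicted R². Taken literally as "adjusted R² first", the criterion
would prefer the full cubic for weight (its adjusted R² is slightly
higher), yet its predicted R² is catastrophically negative — the
signature of an overfit polynomial on an 11-run design. `select_model()`
therefore deprioritizes any candidate whose leave-one-out predicted R² is
negative (worse than predicting the mean), then maximizes adjusted R²
with predicted R² as tie-break. On the reference data this selects the
linear blend for all three responses, matching the study's choice.

**D-optimal design.** `doptimal_design()` builds a candidate set from the
extreme vertices of the bounded simplex, edge midpoints, the centroid and
a seed-controlled uniform fill, then runs Fedorov point exchange,
accepting only swaps that increase $\det(X^\top X)$ — so the criterion
trace is non-decreasing by construction, and on the unconstrained simplex
with three runs it provably returns the three vertices. The original
study's candidate set and exchange settings are unknown, so reproducing
its exact 11 runs is not claimed; tests instead verify the optimality
contract (the exchanged design beats 100 random candidate subsets).

## Release kinetics

All four classical models are fitted on their linearized forms with the
intercept fixed by the model, because the published single-parameter
forms imply through-origin fits: $Q$ on $t$ (zero order), $\ln(100-Q) -
\ln 100$ on $t$ (first order), $Q$ on $\sqrt t$ (Higuchi), and $\ln Q$ on
$\ln t$ (Korsmeyer–Peppas, the only two-parameter fit). Three numerical
conventions matter:

* **Time unit.** Rate constants are reported per minute. The published
  magnitudes are only dimensionally consistent with minutes (e.g. a
  zero-order constant of ~0.07 %/min accumulates ~34% over an 8-h,
  480-min test); the hour-based sampling grid is converted internally.
* **Power-law window.** The Korsmeyer–Peppas model is fitted only to
  points with $Q \le 60\%$ (`q_max`, configurable). The power law is an
  early-time approximation; including near-saturation points biases the
  exponent. The source study does not state its window.
* **R² scale.** The R² of each model is computed on its own linearized
  regression against the mean-corrected total SS of the transformed
  response. This matches dissolution-software practice and makes the
  "highest R² wins" selection rule well defined; exact ties go to the
  simpler model.

The exponent classifies the transport mechanism for a cylindrical
non-swelling matrix: $n<0.45$ Fickian diffusion, $0.45\le n\le 0.89$
anomalous transport, and $n>0.89$ super-Case-II — the last label is an
extrapolation beyond the diffusion framework and is flagged as such.

```{r kinetics}
p <- dissolution_profile(c(0.5, 1, 2, 4, 6, 8),
                         22 * c(0.5, 1, 2, 4, 6, 8)^0.40)
fit_release_kinetics(p)$summary
```

## The synthetic-data generator

Per-formulation dissolution curves are not printed in the source study,
so the generator stands in for them wherever a full pipeline is
exercised. Its ground truth is a composition-linked power law
$Q(t) = k\,t^n$ (hours) with $k = k_{base} + k_{peg}\,x_{PEG400} +
k_{pegda}\,x_{PEGDA}$ and $n = n_{base} + n_{water}\,x_{water}$ clamped
to $(0.05, 1)$; Gaussian noise is added per point, then the curve is made
non-decreasing (running maximum) and capped at 100%.

The defaults — $k_{base}=20$, $k_{peg}=0.30$, $k_{pegda}=-0.10$
(%·h$^{-n}$ per % w/w), $n_{base}=0.32$, $n_{water}=0.004$,
$\sigma_{noise}=2\%$ — emulate the reported study conditions: 8-h release spanning roughly 35–90% of
dose between the PEG 400-rich and PEGDA-rich corners of the design
region, exponents in the Fickian-to-mildly-anomalous band (≈0.36–0.44),
and replicate scatter of a few percent (reported SDs reach ±5%). The
default grid is 1/2/4/6/8 h plus an added 0.5 h point that stabilizes
the log–log kinetic fits; the study's own early sampling times are not
printed, so this is a package choice. The power-law backbone makes
parameter-recovery tests analytic: noiseless synthetic curves must return
$k$ and $n$ to $10^{-6}$ relative.

What the generator does **not** emulate: printing-parameter effects on
release (exposure time influences curing and thus release in reality,
but the truth model depends on composition only), excipient
interactions (the reported F2 anomaly), heteroscedastic noise, and
inter-batch variability. Passing recovery tests therefore show the
estimators are correct for the assumed mechanism, not that the mechanism
exhausts real printlet behaviour.

The exposure-time rule is a monotone band function of water content
(<7.5% → 100 s, then 400/500/600 s in 5-point bands, ≥22.5% → 800 s)
fitted to the majority pattern of the published printing settings. Two
published formulations deviate from it, so the reference tables always
carry their printed exposure times; the rule is used only for de-novo
compositions.

## The MLP surrogate

The perceptron is implemented from scratch (the learning algorithm is
part of the method under study, not a commodity step): per-layer affine
maps with linear or log-sigmoid activations, full-batch backpropagation
of the halved mean-squared error, and momentum updates
$\Delta w_t = -\eta \nabla E + \mu \Delta w_{t-1}$ with the published
$\eta = \mu = 0.6$. Weights initialize uniform(−0.5, 0.5) from a seeded
generator; training is bit-reproducible given the seed. Inputs and
outputs are min-max scaled to [0, 1] — required by sigmoid layers, and
the scale on which a validation RMS of ~0.03 is meaningful; the original
software's scaling is unstated, so this is a package choice. Early
stopping keeps the weights of the best validation epoch (default
patience 200 epochs, cap 20,000; full-batch training is appropriate for
datasets of ~10 formulations).

Correctness is established structurally rather than by chasing the
published training metrics, which depend on unprinted training data and
unknown initialization: analytic gradients match central finite
differences to $10^{-6}$ relative at depths 1–5 for both activation
families; an all-linear network driven to convergence reaches the
closed-form least-squares loss; and on synthetic studies a 3-8-k network
trained on 8 formulations predicts held-out formulations with squared
correlation ≥ 0.9 at 2% noise. The two published input layouts are both
supported: composition-only (3 inputs, 5 outputs at 1/2/4/6/8 h) and
composition + exposure time (4 inputs, 4 outputs at 2/4/6/8 h, deep
log-sigmoid stack). `architecture_search()` reproduces the trial-and-
error protocol over a (hidden-layers × nodes) grid with a fixed seed
schedule, ranking by validation RMS. For the deep NN2 stack,
"linear and log-sigmoid activations" is read as log-sigmoid hidden
layers with a linear output — the usual regression design — and is
exposed as configuration rather than hard-coded.

## Desirability optimization

The release goals are: at most 30% at 2 h, at most 60% at 4 h, at most
70% at 6 h (importances 2, 2, 3), and at least 80% at 8 h (importance 3).
Each goal maps the predicted release to $d_i \in [0,1]$ by a one-sided
linear ramp of width 20 percentage points (default): $d=1$ inside the
limit, falling linearly to 0 at limit ± ramp width. The ramp shape is a
package choice — the source names the goals but not the transform — and
a hard 0/1 variant is available. Notably the study's own reported
optimum predicts 79.99% at 8 h against its "not less than 80%" goal,
which is only consistent with a ramped (not hard) desirability. The
overall objective is the importance-weighted geometric mean
$D = (\prod d_i^{r_i})^{1/\sum r_i}$, zero whenever any goal is fully
violated, bounded by the extreme $d_i$, and invariant to uniform
rescaling of the importances (all tested properties).

`optimize_formulation()` maximizes $D$ over the bounded simplex in the
(PEGDA, PEG 400) plane with water as the slack component: a
seed-controlled multi-start (uniform candidates plus the simplex vertices
and centroid), Nelder–Mead refinement of the five best starts, and
rejection of out-of-bounds moves. Nelder–Mead is used because the
clipped, ramped objective is piecewise linear and not smooth. The
optimizer is deterministic given its seed; global optimality is not
guaranteed, but tests verify the result is never worse than direct
evaluation at the study's printed optimum under the same surrogate, and
on noiseless synthetic truth it reaches the optimum found by grid
enumeration at 1% resolution (within the surrogate's approximation
error). For 4-input surrogates each candidate's exposure time is derived
from its water content by the exposure-time rule.

## Profile comparison

The difference and similarity factors are
$f_1 = 100\sum_t |R_t - T_t| / \sum_t R_t$ and
$f_2 = 50 \log_{10}\!\big(100 / \sqrt{1 + \tfrac1n \sum_t (R_t-T_t)^2}\big)$,
with the experimental curve as reference. By default **all** supplied
points enter $f_2$, including points above 85% release: this choice
reproduces the published comparison values exactly from the reference
table; the regulatory truncation (at most one point beyond 85%) is
available as an option. Two closed-form anchors are tested: $f_2 = 100$
for identical profiles and $f_2 = 50$ at a uniform offset of
$\sqrt{99} \approx 9.95$ points. The conventional verdict is "similar"
iff $f_1 \le 15$ and $f_2 \ge 50$.

```{r metrics}
opt <- fx$optimal_comparison
compare_profiles(opt$time_h, opt$experimental, opt$predicted_nn1)
```

## The pipeline

`run_pipeline()` chains the stages — simulate/load, mixture fits,
kinetics, surrogate training, desirability optimization, profile
comparison — with a single master seed, records every setting in the
results bundle, and writes `results.json` plus per-stage CSVs; reruns
with the same configuration are byte-identical. A thin command-line
wrapper with per-stage subcommands ships with the package
(`system.file("cli", "printletr.R", package = "printletr")`).
Test problem sizes (11–50 synthetic
formulations, training runs of a few thousand epochs) were set so the
full suite documents the method at the scale of the original study, an
11-run design.

## Known limitations

* The published kinetic-parameter table cannot be reproduced from
  printed data (the underlying curves appear only as figures); it is
  used as a format and classification fixture, not as a fit target.
  Likewise the networks' training metrics and the exact optimal
  composition depend on unprinted data and unknown initialization.
* Compositions are stored as printed (row sums 99.7–100.0 due to
  rounding) and are not renormalized before modelling; the source does
  not state whether its software renormalized.
* The optimizer is a local multi-start method; the desirability surface
  under a deep sigmoid surrogate can be multimodal.
* The mixture module covers three-component bounded simplex designs
  only; general n-component or process-variable designs are out of
  scope.
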