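---
title: "Comparing ANN, S-system and GRLOT models of gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ANN, S-system and GRLOT models of gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene-regulatory network (GRN) couples genes through the activating and
inhibiting influences of their products.  Continuous deterministic GRN
models describe the concentration `X_i` of each gene product by an
ordinary differential equation whose right-hand side encodes those
influences.  Three rate-law families are in wide use, and they are *not*
interchangeable: they process multiple regulatory inputs differently,
constrain expression rates differently, and expose different parameters to
a fitting algorithm.  `grncompare` implements all three, a common
synthetic-data stage, a common reverse-engineering engine, and a common
scoring suite, so that the methods can be compared under controlled
conditions.

The three rate laws, for genes `i = 1..N`:

* **ANN (recurrent-network) method** — additive input processing through a
  sigmoid:
  `dX_i/dt = v_i f(sum_j w_ij X_j - theta_i) - k_i X_i`,
  with `v_i >= 0` the maximal expression rate, `w_ij` signed connection
  weights, `theta_i >= 0` an external-input offset modulating
  responsiveness, `k_i > 0` a first-order degradation rate, and `f` a
  sigmoid transfer function.  Production is confined to `(0, v_i)`.
* **S-system (SS) method** — multiplicative power-law kinetics:
  `dX_i/dt = alpha_i prod_j X_j^g_ij - beta_i prod_j X_j^h_ij`,
  with rate constants `alpha_i >= 0`, `beta_i > 0` and real kinetic orders
  `g_ij` (production) and `h_ij` (degradation) whose signs encode
  activation/inhibition.  Expression rates are unbounded, and a negative
  kinetic order applied to a near-zero concentration produces a
  singularity.
* **GRLOT (general rate law of transcription)** — a product of Hill-type
  factors: activators contribute `X^n / (X^n + K^n)` and inhibitors
  `K^n / (X^n + K^n)`, each in `(0, 1)`, multiplied together and scaled by
  `v_i`, minus first-order decay `k_i X_i`.  `K` is the half-saturation
  concentration and `n` the cooperativity (Hill) exponent.

### Numerical choices in the rate laws

The sigmoid of the ANN law is the logistic `f(x) = 1/(1+e^-x)`, the
conventional transfer function for this recurrent-network formalism; it is
exposed as a single swappable function (`sigmoid_logistic()`, argument
`transfer` of `ann_rate()`).  For power-law evaluation the base is clamped
to `max(X, 1e-12)` before exponentiation, which avoids complex values while
preserving the blow-up behavior; a clamped evaluation paired with a
negative exponent still counts as a singularity (`ss_rate()` raises a
condition of class `grn_singularity_error`; the integrator converts it to a
flagged failure).  In parameter tables Hill exponents of inhibitors are
sometimes printed with a negative sign; the package stores the regulator
role explicitly and keeps the exponent as its magnitude, so the functional
form is fixed by the edge sign.

## Reference networks and synthetic data

Three five-gene case studies carry printed parameters for all three
methods (`build_case()`): a uniform activation cascade (case A), a
branched cascade with asymmetric branching and co-regulation (case B), and
case B extended by a positive (X3→X2) and a negative (X5→X2) feedback loop
(case C).  All nine models share a uniform degradation rate of 0.3
(`beta` for the S-system, whose `h` matrix is the identity), confining
regulation to the expression process.  Gene X1 has no regulators and acts
as the network input: its S-system/GRLOT production is zero and its
literal ANN production is the small constant `v f(-theta)`; no special
case is made for it.  Two further topologies are included as
parameter-open definitions — a three-gene ANN oscillator scenario (case D,
two variants differing only in `theta_1` = 3.0 vs 1.0) and a five-gene
power-law benchmark (case E) — because their literature parameter values
are not part of the package; they refuse to run until a configuration
supplies the values rather than guessing them.  A loader for externally
obtained switch-on/switch-off yeast expression series applies the study's
preprocessing contract (first 100 minutes, first 10-minute interval
dropped).

The data-generation stage (`generate_sparse()`, `generate_detailed()`)
integrates a model from fixed initial-condition sets: the *sparse* dataset
uses starting set 1 only, the *detailed* dataset starting sets 1–5, each
trajectory sampled at 200 evenly spaced points.  The time horizon is not
part of the printed study conditions; the package fixes `t_end = 20` time
units, about six degradation time-constants at `k = 0.3`, so each
trajectory contains both the transient and the approach to steady state.
This value is recorded in the dataset metadata and configurable in
`integration_settings()`.  The synthetic data are noise-free model output
by design — observational noise, measurement sparsity in time, and
biological variability of real expression data are deliberately absent, so
passing tests demonstrate method properties under idealized conditions,
not performance on laboratory data.

Integration uses an adaptive Dormand–Prince 4(5) scheme (rtol `1e-6`,
atol `1e-8`) stepping exactly onto the output grid, with a blow-up guard
at `|X| = 1e6` and a step-count cap.  Any failure — step-size collapse,
non-finite state, blow-up, or an S-system singularity — is returned as a
flagged trajectory rather than an exception, because candidate models
proposed during optimization fail routinely and must simply score badly
(the worst-fitness sentinel) instead of aborting a run.

## Two-phase reverse engineering

Reverse engineering is parameter estimation under a fixed structure: the
regulatory topology is taken as known, and only the signs/magnitudes of
parameters on existing interactions are searched.  The objective is the
summed squared deviation between observed and model-predicted
concentrations over all sampling points (and genes, for network fits).

The *bottom-up phase* fits one **node model** per gene: the gene's single
rate equation is integrated with all other genes' concentrations supplied
from the data by piecewise-linear interpolation between the 200 samples.
This decomposes an `O(N^2)`-parameter problem into `N` problems of
roughly `1/N`-th the size.  Node models fit their data very accurately but
cannot predict new conditions.  The *top-down phase* therefore assembles
the fittest node models into a full network model and re-optimizes all
parameters jointly, with the coupled system integrated from the data's
initial state only.  Because of error propagation, an assembled model's
coupled dynamics can differ substantially from its node-wise fits; the
assembly is a good starting position, not a result.  Assembled seeds (plus
mutated copies) form 10% of the top-down initial population.

The optimizer is a real-coded evolutionary algorithm: uniform random
initialization inside the per-parameter search box, roulette-wheel
selection over a rank-based fitness assignment, BLX-alpha crossover
(rate 0.6, alpha 0.5), creep mutation (rate 0.1 per position), clipping to
bounds, and elitist cloning of the best individual.  Defaults follow the
replicated study: population 500, 300 generations, five independent
repeats with the best run kept.  Design points that were genuinely open:

* *Selection weights.*  The default scheme weights individuals by their
  rank position itself (best of `n` gets weight `n`, worst gets 1), the
  literal reading of roulette selection "proportional to the positions" of
  a rank-based assignment; a linear-ranking alternative with selection
  pressure 1.8 is available (`selection_scheme = "rank_linear"`).
* *Creep law.*  Creep mutation is additive Gaussian with standard
  deviation `creep_scale` (default 5%) of the parameter's bound width,
  multiplied by a log-uniform factor spanning three decades.  The scale
  mixture gives the operator both of a creep operator's classic duties:
  frequent tiny refinements near a solution and occasional near-full-scale
  exploration steps.  A fixed-scale Gaussian at 5% explores well but
  cannot refine; in calibration runs on the case studies it stalled an
  order of magnitude short of the achievable objective.
* *Elitism.*  The single best-so-far individual is cloned into each next
  generation ("cloning" is listed among the operators without a rate).
* *Restarts.*  Independent repeats with different sub-seeds are the
  mechanism for escaping local minima; the best-of-repeats aggregation is
  used throughout, consistent with repeats existing to overcome stuck
  searches.  On the case studies, many small restarts reliably beat one
  long run at equal evaluation budget.

The searched intervals are: ANN `w` in [-15, 15], `v` in [0, 3], `theta`
in [0, 7], `k` in [0, 2]; S-system `g`, `h` in [-3, 3], `alpha`, `beta` in
[0, 15]; GRLOT Hill exponents in [0, 7] for activator-role and [-5, 5] for
inhibitor-role regulators (the printed per-role ranges are read as
exponent ranges, since concentrations are not free parameters), `K` in
[0.001, 40] — the positive floor keeps the rate law finite — and `k` in
[0, 2].  No bound is printed for the GRLOT `v`; the package uses the ANN
interval [0, 3].  For cases A–C the S-system `h` matrix is searched on its
diagonal only, matching the reference models' structure.  Candidate
failures (singularities, blow-ups) receive a large finite worst-fitness
sentinel.

### The optional local polish step

`two_phase_fit(polish = TRUE)` refines each restart's best vector with a
bounded Nelder–Mead search on the same objective (with simplex restarts),
before the best-of-restarts selection.  It is off by default: the
replication pipeline at full budget is EA-only.  The package's
scaled-down configurations enable it, for a measured reason: at
population 100 and 100 generations the evolutionary search reliably finds
the right basin but stops one to three orders of magnitude short of the
attainable objective, leaving percent-level parameter error.  The
validation protocol is exactly the place where that residual error shows:
a control experiment with hand-perturbed reference parameters shows ANN
and GRLOT models tolerating ~1% parameter noise (`|delta P_fit|` below
0.01) while S-system models collapse (`delta P_fit` near -0.5) — the
method contrast under study.  The polish step supplies the final decimals
that the full-scale evaluation budget would buy, without touching the
study conditions, the data, or the scoring.  Importantly, the polish
cannot manufacture the contrast: it is applied identically to all three
methods, and the S-system collapse persists even when its parameters are
recovered to `P_inf` above 0.999.

## Scoring

* `p_fit(observed, predicted)` `= 1/(1+E)`, `E` the mean squared
  deviation pooled over all points and genes.  On training data this is
  the verification score `P_ver` (`verify_model()`); on perturbed unseen
  data the validation score `P_val` (`validate_model()`);
  `delta P_fit = P_val - P_ver`.  Narrative quality bands
  (`classify_pfit()`): below 0.9 very poor, 0.95–0.99 same range with
  possibly different patterns, above 0.99 converging, above 0.999 highly
  accurate.  No band is stated for [0.9, 0.95); the package labels it
  "poor" as an interpolation.
* *Validation protocol.*  Gene X1 has no regulators, so its degradation
  rate is the network input: the reference model is rerun with `k_1`
  (`beta_1` for SS) set to 0.1 (increased input) and 0.5 (decreased
  input), the identical perturbation is applied to the inferred model, and
  each condition is scored with `p_fit`.  `P_val` is the arithmetic mean
  of the two condition scores, which are also reported separately since
  the increase and decrease behave differently.  Validation trajectories
  start from the training initial-condition sets.
* `p_inf(W, What)` `= 0.5 (1 + r)` with `r` the Pearson correlation of
  the reference and recovered parameter vectors.  The vectors concatenate
  all *free* (unmasked) parameters in a documented canonical per-gene
  order; structural zeros are excluded so they cannot inflate the
  correlation.  `P_inf` is only computed within a method — across methods
  the parameters are not comparable and the report says so explicitly,
  falling back to the qualitative comparison.
* `qcom_features()` evaluates the case-relevant qualitative features with
  fixed thresholds: uniform degradation (all rates within [0.2, 0.4]),
  constant signal propagation (strongest/weakest cascade signal ratio
  below 2), asymmetric branching and co-regulation (above 20% relative
  difference), and the sign of the two case-C feedback interactions.
  Signal strength is `|w_ij|` for ANN, `|g_ij|` for the S-system, and the
  Hill exponent (role carrying the sign) for GRLOT; the S-system
  degradation check uses `beta_i`.
* `relative_difference()` is the scale-invariant squared relative error
  used by the initial-value perturbation protocol (factors 3, 12, 48 per
  gene) when comparing simulated models of externally supplied data.

## Problem sizes used by the shipped tests

The package's own verification suite runs the full pipeline at a
scaled-down study budget chosen to keep a complete run on a single CPU
practical: population 100, 100 generations, five restarts per
optimization, with the local polish step enabled.  At this budget the
within-method cells reproduce the full study's regime: verification
scores above 0.999, near-exact parameter recovery from detailed data, the
S-system's collapse from excellent verification to poor validation under
input perturbations, and the GRLOT dissociation between low inferential
power and excellent predictive power.  Because the optimizer is
stochastic, these are regime reproductions under fixed seeds, not
bit-exact reproductions of any published figure.

## Known limitations

* The comparison is confined to fixed, known topologies; structure
  discovery is out of scope.
* Generalized mass-action systems (sums of power-law processes) and
  time-delay terms are documented contrasts, not implemented methods.
* The synthetic-data stage is noise-free; a multiplicative noise hook
  exists for extensions but defaults off, and no claim is made about
  robustness to measurement noise.
* The original study's integration horizon is not recoverable from its
  report; all quantitative targets are therefore defined relative to the
  package's own generated data under the documented horizon.
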