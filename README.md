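# grncompare

Comparative modeling and reverse engineering of gene-regulatory networks
(GRNs) with three continuous deterministic rate-law families:

* **ANN** — recurrent-network kinetics,
  `dX_i/dt = v_i f(Σ_j w_ij X_j − θ_i) − k_i X_i`, with `f` the logistic
  sigmoid;
* **SS** — S-system power-law kinetics,
  `dX_i/dt = α_i Π_j X_j^g_ij − β_i Π_j X_j^h_ij`;
* **GRLOT** — the general rate law of transcription, a product of
  Hill-type activator factors `X^n/(X^n+K^n)` and inhibitor factors
  `K^n/(X^n+K^n)` scaled by `v_i`, minus first-order decay.

These formalisms process regulatory inputs differently (additive vs
multiplicative), bound expression rates differently, and expose different
parameters to a fitting algorithm — so models reverse-engineered from the
same data can behave very differently under new conditions.  The package
is for systems-biology researchers and method developers who want to
study those differences under controlled conditions: it builds
parameterized five-gene reference networks, simulates noise-free
time-series expression data, reverse-engineers models with a two-phase
(per-gene node models, then seeded whole-network models) real-coded
evolutionary algorithm, and scores the results with

* `P_ver` / `P_val` — predictive power `1/(1+MSE)` on training data and on
  perturbed unseen data, with `ΔP_fit = P_val − P_ver`;
* `P_inf` — inferential power `0.5(1+r)`, the Pearson correlation between
  reference and recovered parameter vectors;
* `Q_com` — qualitative presence/absence of designed network features
  (uniform degradation, signal-propagation symmetry, feedback signs).

## Worked example

Fit an S-system model to data generated by the case-C reference network
(branched cascade with positive and negative feedback) and evaluate it:

```r
library(grncompare)

reference <- build_case("C", "SS")     # printed five-gene reference model
data <- generate_sparse(reference)     # 1 trajectory x 200 points x 5 genes

fit <- two_phase_fit(data, "SS", reference$topology,
                     ea_config(pop_size = 100, generations = 100,
                               repeats = 5, seed = 1221),
                     polish = TRUE)
report <- evaluation_report(fit$model, reference, data, case_id = "C")
report
#> Evaluation (SS data -> SS model, case C)
#>   P_ver = 1.0000 (highly accurate)
#>   P_val = 0.5001  [increased 0.0003, decreased 0.9999]
#>   dP_fit = -0.4999
#>   P_inf = 0.9996
#>   Q_com: uniform_degradation, asymmetric_signal_branching, asymmetric_co_regulation, positive_feedback, negative_feedback
```

Reading: the model reproduces its own training data essentially perfectly
(`P_ver` 1.0000) and recovers the reference parameters almost exactly
(`P_inf` 0.9996) — yet under an input perturbation (lowering the
degradation rate of the input gene X1 from 0.3 to 0.1) its predictions
collapse (`P_val` 0.5001, driven entirely by the increased-input
condition).  The S-system's multiplied unrestricted power terms amplify
even sub-percent parameter error.  Running the same cell with the ANN or
GRLOT method yields `|ΔP_fit|` well below 0.01: those models remain
robust under the identical perturbation.

`run_study()` orchestrates the full cross-method design (every
data-generating method × every inference method × cases A–C, sparse or
detailed data) and writes within-method, cross-method and feature-grid
CSV tables.

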