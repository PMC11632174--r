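# tldoe — transfer-learning Bayesian optimization for competitor DNA design

Competitive-PCR diagnostics need many engineered competitor DNA molecules,
each tuned so its amplification **rate** hits a predefined target while a
nuisance **drift** factor stays below a threshold. Every data point is a
wet-lab amplification experiment, so the design question is: how few
experiments can tune *all* the competitors? `tldoe` implements a
transfer-learning design-of-experiments workflow for this problem, aimed at
assay developers and at anyone optimizing many related response surfaces
under a tight experimental budget.

The package provides:

* **Four Gaussian-process surrogates** over the design inputs
  `(log BP, logit GC)` — pooled AvgGP, independent-output MOGP (the
  no-transfer reference), the linear model of coregionalization
  (`B = WW' + diag(kappa)`), and a latent-variable multi-output GP
  (LVMOGP) that augments the inputs with a learned latent coordinate per
  competitor, `y_p(x) = f(x, h_p) + eps`, with `h_p ~ N(mu_p, S_p)` trained
  by a variational bound. Latent-space distance controls transfer, so
  nonlinear families of surfaces are captured and negative transfer can be
  escaped.
* **Target-vector expected improvement**: for the scalar target the scaled
  squared distance `(y - T_rate)^2 / s^2` is noncentral chi-square
  (1 degree of freedom, noncentrality `(m - T_rate)^2 / s^2`), giving the
  expected improvement over the incumbent `delta_min` in closed form;
  a probability-of-feasibility factor `Phi((T_drift - m)/s)` penalizes
  candidates likely to exceed the drift threshold.
* **Amplification-curve fitting** extracting `(F0, nu, r, m)` from
  fluorescence traces via the drift-modulated logistic model
  `F_T = nu / (1 + ((nu-F0)/F0) e^{-r tau})`,
  `signal = F_T (1 + (F_T/nu) m ln(F0)/r)`.
* **Synthetic benchmark generators** (uncorrelated / linearly-correlated /
  offset-sigmoid surfaces, plus a competitor-like campaign with two drift
  regimes), and **cross-validation and retrospective-BO harnesses** that
  replay the optimization against a fixed candidate pool.

## Worked example

Fit the four surrogates to a synthetic offset-sigmoid benchmark and compare
their accuracy on ten initially-unobserved surfaces after two points each:

```r
library(tldoe)

gen <- gen_offset_sigmoid(seed = 1)        # 2 observed + 10 new surfaces
res <- benchmark_models(gen, checkpoints = 2, seed = 1)
aggregate(cbind(rmse, nlpd) ~ model, res, mean)
#>    model      rmse        nlpd
#> 1  avggp 0.5487135  2.54064851
#> 2    lmc 0.7533382 24.99804948
#> 3 lvmogp 0.3037845  0.06178369
#> 4   mogp 0.3745255  0.22871262
```

With two points per new surface the LVMOGP has the lowest error and the
best-calibrated predictions — it only needs to locate each sigmoid's slope
in latent space — while the LMC, whose linear structure cannot represent a
horizontal shift, is worse than pooling here and wildly over-confident
(NLPD of 25).

Retrospective Bayesian optimization on a competitor-like campaign:

```r
cdata  <- gen_competitor_like(n_surfaces = 8, seed = 17)
config <- bo_config(model = "lvmogp", scenario = "learning_many",
                    start_strategy = "center", target_rate = 2.5,
                    seeds = 1:3, max_iterations = 8)
runs <- run_bo(cdata, config)
bo_report(runs)
#>    model      scenario strategy penalized n_runs mean_iters_to_tol
#> 1 lvmogp learning_many   center     FALSE     12                 3
#>   frac_reaching_tol frac_first_to_best mean_final_cum_regret
#> 1                 1                0.5 0.5661837
```

Each of the 4 target competitors (3 seeds each, 12 runs) reaches a
measurement within 0.05 of its best attainable rate after 3 selections on
average; half the first selections are already at the best point, because
the latent space lets the model borrow the optimum location from related
competitors.

Rate/drift extraction from traces:

```r
tr  <- gen_traces(n_wells = 2, seed = 41)
fit_curve_table(tr$traces)[, c("well_id", "rate", "drift")]
#>   well_id      rate       drift
#> 1     W01 0.6825389 -0.16066318
#> 2     W02 0.7539089  0.08815557
```

(The generating rates were 0.705 and 0.777 — recovered within a few
percent. Drift is far more weakly identified from a single noisy trace,
which is exactly why the workflow models it with its own surrogate across
replicates.)

A command-line interface wrapping the same functions is installed as
`exec/tldoe` (subcommands `simulate`, `fit-curves`, `crossval`, `bo`,
`report`).

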