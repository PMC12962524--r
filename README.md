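# gformulaHTE

Target-trial emulation with G-computation and cluster-based discovery of
treatment-effect heterogeneity, for observational cohorts with a binary
"uncontrolled hypertension" endpoint (follow-up SBP ≥ 140 mmHg or DBP ≥ 90
mmHg) or continuous blood-pressure changes.

The package is written for epidemiologists and biostatisticians evaluating
a mobile-health (mHealth) disease-management program from routinely
collected health-checkup and claims data, where program uptake is
voluntary (here: 127 treated among 3,092 eligible) and randomization must
be emulated by covariate adjustment. The raw records such analyses use are
proprietary, so the package also ships a seeded synthetic-cohort generator
with the same covariate structure and a known ground-truth effect surface,
making every stage of the pipeline testable.

## What it computes

1. **G-formula (outcome regression).** An outcome model
   $\hat m(x, a)$ is fitted with a cross-validated stacking ensemble
   (Super Learner: GLM, random forest, neural network, adaptive
   piecewise-linear splines, gradient boosting; non-negative-least-squares
   meta-weights on out-of-fold predictions, normalized to the simplex).
   Counterfactual predictions under program ($a{=}1$) and control
   ($a{=}0$) give per-person effects
   $\tau_i = \hat m(x_i, 1) - \hat m(x_i, 0)$ (negative = benefit) and the
   plug-in summaries ATE $= \bar\tau$, RR
   $= \overline{p_1}/\overline{p_0}$, NNT $= 1/|\text{RD}|$, with
   percentile-bootstrap confidence intervals and VanderWeele–Ding E-values
   $E = \mathrm{rr}^* + \sqrt{\mathrm{rr}^*(\mathrm{rr}^*-1)}$,
   $\mathrm{rr}^* = \max(\mathrm{rr}, 1/\mathrm{rr})$.
2. **Heterogeneity discovery.** ITEs are jittered, standardized to mean 0 /
   SD 0.1, clustered with Ward.D2 (Euclidean, 2–10 clusters); the number of
   clusters is chosen by Beale's F-ratio index at α = 0.01; candidate
   effect modifiers are ranked by the between-cluster difference of
   covariate z-scores (threshold 0.25, sensitivity 0.20/0.30); each cluster
   gets CATE / RR / NNT / E-value and a baseline profile.
3. **Supporting stages.** Iterative random-forest imputation of missing
   covariates, a propensity-overlap (positivity) diagnostic, and a
   baseline characteristics table with the usual display conventions.

See `vignettes/methods.Rmd` for the model, conventions and validation
design.

## Worked example

The validation scenario — the same data-generating process as the emulated
cohort, but with treatment randomized 1:1 — shows the full pipeline
recovering a planted effect-modifier structure:

```r
library(gformulaHTE)
schema <- default_schema()
sim <- generate_cohort(recovery_config(n_total = 5000, seed = 42), schema)

X <- build_design(sim$cohort, schema)
model <- cv_stack(X, sim$cohort$y_uncontrolled,
                  library = list(learner_spec("glm", "glm", interactions = TRUE)),
                  V = 5, seed = 42)
cf  <- counterfactual_predict(model, X)
ite <- compute_ite(cf)
sprintf("plug-in ATE %.3f (truth %.3f)", mean(ite$ite),
        attr(sim$oracle, "true_ate"))
#> "plug-in ATE -0.124 (truth -0.121)"

z      <- jitter_standardize(ite, seed = 42)
beale  <- beale_select_k(ward_cluster(z))
beale$k
#> 2
labels <- cut_labels(ward_cluster(z), beale$k)
head(covariate_importance(sim$cohort, labels, schema)[, 1:2], 4)
#>    variable importance
#>   intention  2.6704836
#>     smoking  0.8836366
#>  sleep_rest  0.1584271
#>         cci  0.1125747
cluster_cate(ite, cf, labels, n_boot = 200, seed = 42)[
  , c("cluster", "n", "CATE", "RR", "NNT", "E_value")]
#>  cluster    n       CATE        RR      NNT  E_value
#>        1 4332 -0.1669316 0.3105532 5.990476 5.893770
#>        2  668  0.1578484 1.5692105 6.335192 2.514309
```

The average effect is recovered to ±0.003; Beale's index finds the two
planted clusters; both planted modifiers (intention to improve lifestyle
habits, smoking) clear the 0.25 importance threshold while every other
covariate stays far below it; and the high-benefit cluster (CATE −0.17,
RR 0.31, NNT 6.0) is the intender group, as planted.

## The analysis workflow

Numbered drivers under `analysis/` run the emulated observational study on
a synthetic 3,092-person cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohort, schema, oracle, baseline table
Rscript analysis/02_impute.R         # random-forest imputation + convergence
Rscript analysis/03_effects.R        # ensemble fit, ATE/RR/NNT/E-value, overlap
Rscript analysis/04_heterogeneity.R  # Ward/Beale clusters, importance, CATEs
Rscript analysis/05_report.R         # one-call orchestrated run + report.md
```

On the emulated design the stack favors additive learners (127 treated
cannot support interaction learning), Beale's index flags the absence of
significant ITE structure (`no_significant_structure`, k floored at 2),
and the importance ranking is led by baseline blood pressure — a faithful
picture of what this method can and cannot see at that treated fraction;
the vignette discusses why, and the validation scenario above shows the
same machinery succeeding when the design supports it.

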