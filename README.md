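# rctdistill

Distillation analysis for randomized trials diluted by low uptake.

## The problem

Randomized evaluations of care-delivery interventions — complex case
management, care coordination, social-needs programs — are routinely
weakened by *dilution*: a sizeable share of subjects randomized to the
intervention arm never enrolls or barely engages, so the intent-to-treat
(ITT) contrast averages the effect over many untreated people and a useful
program can look null. The usual repairs are biased: "as-treated"
comparisons and propensity matching cannot account for the unmeasured
motivation and perceived-benefit factors that drive uptake.

`rctdistill` implements a three-stage analysis that addresses dilution while
keeping the randomization intact, for analysts re-evaluating diluted trials
and for methodologists studying when the approach buys power:

1. **Predict uptake** — gradient-boosted trees predict enrollment from
   baseline covariates within the intervention arm (where uptake is
   observed); every randomized subject in both arms is scored.
2. **Distill** — both arms are trimmed with one pooled score threshold to
   nested subsets (default 100/80/60/40/25%) concentrated in likely
   participants. Because the threshold uses baseline information only and
   is applied identically to both arms, each subset is still a randomized
   comparison.
3. **Re-estimate** — on each subset, a difference-in-differences
   generalized linear mixed model with a per-subject random intercept and
   log-exposure offsets:

   ln λ<sub>it</sub> = β<sub>0i</sub> + β<sub>t</sub>·I(t=post) +
   β<sub>int</sub>·I(intervention) + τ·I(t=post)·I(intervention),
   &nbsp; β<sub>0i</sub> ~ N(β<sub>0</sub>, σ²),

   Poisson for utilization counts, gamma (log link) for costs. τ is the
   treatment effect; e<sup>τ</sup> − 1 reads as an approximate percent
   change.

The estimand changes with the trimming: each distilled estimate targets the
average treatment effect in the subpopulation with high predicted uptake.
The package also ships a Monte-Carlo framework for the method's operating
characteristics (type-I error and power across retention levels under
correlated participation/benefit latents) and a synthetic-trial generator,
since real trial data of this kind are proprietary.

## Worked example

```r
library(rctdistill)

trial <- generate_synthetic_trial(synthetic_trial_config(seed = 42))
trial
#> Two-arm randomized trial dataset
#>   subjects: 805 (404 intervention, 401 control)
#>   intervention-arm enrollment: 66.1%
#>   covariates: 10 (10 real, 0 categorical)

ans <- distill(trial, outcomes = c("ed_visits", "cost"), periods = "fu1",
               max_trees = 2000, learning_rate = 0.01, seed = 42)
summary(ans)
#> Stage-one AUC: 0.859 (CV), 0.971 (in-sample)
#> Top covariates by relative influence:
#>  covariate influence
#>         x1     27.21
#>         x2     23.65
#>         x3     16.04
#>         x5     12.03
#>         x4     10.31
#>
#> Treatment-effect estimates (tau, log scale):
#>    outcome period retention_fraction    tau ci_low ci_high p_value converged
#>  ed_visits    fu1               1.00 -0.112 -0.249   0.025  0.1100      TRUE
#>  ed_visits    fu1               0.80 -0.139 -0.295   0.017  0.0798      TRUE
#>  ed_visits    fu1               0.60 -0.147 -0.329   0.034  0.1110      TRUE
#>  ed_visits    fu1               0.40 -0.113 -0.333   0.107  0.3130      TRUE
#>  ed_visits    fu1               0.25 -0.231 -0.514   0.052  0.1100      TRUE
#>       cost    fu1               1.00 -0.167 -0.329  -0.005  0.0438      TRUE
#>       ...
```

Reading the output: the stage-one model separates enrollees from
non-enrollees well (cross-validated AUC 0.859; the in-sample 0.971 is
optimistic and labeled). Down the ladder, the emergency-department effect
estimate deepens from −11% (e<sup>−0.112</sup> − 1) in the full ITT sample
to −21% in the quarter of subjects most likely to enroll, with confidence
intervals widening as the sample shrinks — the power-versus-concentration
trade-off the method navigates. `plot(ans)` draws the grid of estimates and
intervals; `run_analysis()` runs the same workflow from a trial-table CSV
and writes scores, ladder, effects and logs to files; a thin command-line
wrapper lives at `inst/cli/distill.R`.

For the method's operating characteristics:

```r
sc <- sim_scenario(taumax = c(0, -0.1), n_per_arm = 2000, reps = 500, seed = 1)
estimate_power_grid(sc)   # rejection rate per (taumax, retention) cell
```

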