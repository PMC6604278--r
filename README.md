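# prevcomb

Estimating disease prevalence from routinely collected health data usually
means applying a case-ascertainment algorithm to a single error-prone
source — administrative health records (AHRs) or electronic medical records
(EMRs) — and living with the misclassification bias. When a population can
be linked across *two* such sources, their information can be combined.
`prevcomb` is for epidemiologists and biostatisticians who want to do that
combining, and to understand when each combining rule can be trusted.

The package implements four data-combining prevalence estimators for two
binary source indicators $Y_1, Y_2$ with unknown true status $D$:

| method | estimator | key assumption |
|---|---|---|
| OR  | $\Pr(Y_1{=}1 \lor Y_2{=}1)$ | sources are error-free |
| AND | $\Pr(Y_1{=}1 \land Y_2{=}1)$ | sources are error-free |
| RSSA | mean of per-source Rogan–Gladen corrections $\dfrac{\bar y_j + Sp_j - 1}{Sn_j + Sp_j - 1}$ | assumed $Sn_j, Sp_j$ are correct |
| PSSA | posterior mean of $\frac1n\sum_i D_i$ under a Bayesian latent-class model: probit outcome model $\Pr(D_i{=}1)=\Phi(x_i'\alpha)$ on disease markers, per-source reporting model $(Sn_j, Sp_j)$, Gibbs sampling | $Y_1 \perp Y_2 \mid D$ |

Wald intervals are attached to OR/AND, percentile-bootstrap intervals
(B = 999) to RSSA, and posterior percentile intervals to PSSA, which also
reports Gelman–Rubin PSRF convergence diagnostics and a marginalized-
likelihood DIC for model comparison.

Around the estimators sits a full simulation engine: Gaussian-copula
generation of correlated binary disease markers, a calibrated logistic
truth model, conditional-Bernoulli misclassification with shared-error
dependence calibrated to a target *tetrachoric* between-source correlation,
and a replication framework that evaluates percent absolute relative bias
(RB) and mean squared error (MSE, ×100) over grids of conditions. A
synthetic linked-cohort generator stands in for real AHR/EMR data. See the
methods vignette (`vignettes/combining-two-sources.Rmd`) for the model and
every calibration rule.

## Worked example

Simulate a linked two-source cohort and estimate prevalence with every
method:

```r
library(prevcomb)

tab <- generate_cohort_fixture(cohort_fixture_spec(n = 20000, seed = 1))
tetrachoric_correlation(tab$y_source1, tab$y_source2)
#> Tetrachoric correlation: 0.898 (95% CI 0.878-0.918), n = 20000

estimate_all(tab, methods = c("source1", "source2", "or", "and", "rssa"),
             seed = 1)
#>   stratum  method    point    ci_low   ci_high            ci_method     n
#> 1 overall source1 0.313750 0.3073192 0.3201808                 wald 20000
#> 2 overall source2 0.250650 0.2446437 0.2566563                 wald 20000
#> 3 overall      OR 0.348400 0.3417967 0.3550033                 wald 20000
#> 4 overall     AND 0.216000 0.2102968 0.2217032                 wald 20000
#> 5 overall    RSSA 0.294653 0.2866969 0.3035243 percentile_bootstrap 20000
```

The two sources disagree (31.4% vs 25.1%; the realised true prevalence in
this synthetic cohort is 27.7%). OR and AND bracket them; RSSA, correcting
each source with the assumed accuracies (0.72/0.95 and 0.87/0.90), lands
between at 29.5%.

Fit the latent-class model on the cohort's comorbidity and demographic
markers:

```r
fit <- pssa(tab$y_source1, tab$y_source2,
            markers = as.matrix(tab[c("diabetes", "obesity", "depression",
                                      "copd", "chd", "female")]),
            n_iter = 2000, burn_in = 500, n_chains = 2, seed = 2)
print(fit)
#> PSSA latent-class prevalence model (probit outcome, Gibbs sampling)
#>   n = 20000, 6 markers, 2 chain(s) x 2000 iterations (500 burn-in)
#>   posterior prevalence: 0.2558 (95% CrI 0.2483-0.2688)
#>   max PSRF = 1.002; DIC = 37970.9 (p_D = 9.1)
```

All parameters converge (PSRF ≈ 1) and the posterior prevalence (25.6%)
sits between the AND and RSSA estimates, below the OR rule. `summary(fit)` tabulates the
posterior of every coefficient and each source's sensitivity/specificity;
`plot(fit)` draws traceplots; `export_chains(fit, "chains.csv")` writes the
draws for external MCMC tooling.

Run a simulation cell and compare methods under controlled error:

```r
cond <- sim_condition(true_prev = 0.20, obs_prev = c(0.18, 0.15),
                      source_corr = 0.85, n_markers = 16, marker_corr = 0)
run_condition(cond, reps = 100, methods = c("or", "and", "rssa"),
              base_seed = 1)
#> Condition result (100 replications, population 10000)
#> Simulation condition
#>   true prevalence      : 0.200
#>   observed prevalences : 0.180, 0.150
#>   source correlation   : 0.85 (tetrachoric)
#>   markers              : 16, mean corr 0.00 (exchangeable)
#>   population size      : 10000
#>   or       mean 0.2199  RB   9.97%  MSE(x100) 0.0418
#>   and      mean 0.1094  RB  45.31%  MSE(x100) 0.8223
#>   rssa     mean 0.1290  RB  35.51%  MSE(x100) 0.5070
```

With both sources under-capturing a 20% condition and correlating at 0.85,
the OR rule is least biased (RB ≈ 10%), the AND rule loses every case the
sources disagree on, and RSSA is dragged down because the generating
sensitivities differ from the assumed ones — the pattern the simulation
framework exists to expose.

A thin command-line wrapper covers the same workflows
(`exec/prevcomb simulate|fixture|estimate|chains`), driven by a YAML
configuration (`load_config()`), and every run can write a reproducibility
manifest (`write_manifest()`).

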