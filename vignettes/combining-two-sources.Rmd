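---
title: "Methods: prevalence estimation from two error-prone case-ascertainment sources"
author: "prevcomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prevalence estimation from two error-prone case-ascertainment sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Disease surveillance often ascertains cases from routinely collected
electronic databases — administrative health records (claims, hospital
abstracts, drug dispensations) and electronic medical records from primary
care. Each source applies a deterministic case-ascertainment algorithm and
yields, per person, a binary indicator of disease. Both indicators are
error-prone: false negatives (imperfect sensitivity, $Sn$) and false
positives (imperfect specificity, $Sp$) bias the naive prevalence estimate
$\bar{y}_j$ of either source alone. When a population can be linked across
two such sources, their information can be combined.

`prevcomb` implements four data-combining prevalence estimators and the
simulation machinery needed to study their bias:

* **OR** — a person is a case if *either* source flags them:
  $\hat\pi_{OR} = \Pr(Y_1 = 1 \lor Y_2 = 1)$.
* **AND** — a case only if *both* sources agree:
  $\hat\pi_{AND} = \Pr(Y_1 = 1 \land Y_2 = 1)$.
* **RSSA** (rule-based sensitivity–specificity adjusted) — each source's
  observed prevalence is de-biased by the Rogan–Gladen correction
  $\hat\pi_j = (\bar{y}_j + Sp_j - 1)/(Sn_j + Sp_j - 1)$ using
  externally assumed accuracy values, and the two corrected estimates are
  combined.
* **PSSA** (probabilistic sensitivity–specificity adjusted) — a Bayesian
  latent-class model: true status $D_i$ is unobserved, a probit outcome
  model $\Pr(D_i = 1) = \Phi(x_i'\alpha)$ links binary disease markers
  (comorbidities, demographics) to the truth, and an intercept-only
  reporting model links truth to each source
  ($\Pr(Y_{ji}=1 \mid D_i=1) = Sn_j$,
  $\Pr(Y_{ji}=1 \mid D_i=0) = 1 - Sp_j$), with the two sources
  conditionally independent given $D_i$. The population prevalence is
  estimated by the posterior distribution of $\frac1n\sum_i D_i$.

The OR and AND rules implicitly assume perfectly accurate sources; RSSA
assumes the externally supplied $Sn/Sp$ are correct; PSSA assumes the
reporting model (in particular conditional independence) is correct. The
simulation engine exists to quantify what happens when these assumptions
fail.

## The PSSA sampler

The model is fit by Gibbs sampling (compiled in C++, driven by R's RNG so
chains are bit-reproducible under `set.seed()`):

1. each latent $D_i$ is drawn from its Bernoulli full conditional, with odds
   $\Phi(x_i'\alpha)\,P(y_{1i}\mid D=1)P(y_{2i}\mid D=1)$ against
   $(1-\Phi(x_i'\alpha))\,P(y_{1i}\mid D=0)P(y_{2i}\mid D=0)$;
2. the probit coefficients $\alpha$ are updated by Albert–Chib
   truncated-normal data augmentation with independent
   $\mathcal N(0, 10^2)$ priors — diffuse relative to any plausible
   log-scale marker effect;
3. each source's $Sn_j, Sp_j$ are drawn from conjugate Beta full
   conditionals with Beta(2, 1) priors, rejecting draws with
   $Sn_j + Sp_j \le 1$.

The Beta(2, 1) priors favour informative sources and, together with the
$Sn + Sp > 1$ rejection step, pin the labelling of the latent classes:
without the constraint the likelihood is invariant under swapping
$D \to 1 - D$, $Sn \to 1 - Sp$, and chains can drift between the two mirror
modes. Degenerate inputs are handled explicitly: constant marker columns
produce a warning (their coefficients are prior-dominated, not an error);
sources that are constant and identical are rejected as unfittable.

Defaults follow common practice for this model family: 10,000 iterations
with the first 500 discarded as burn-in, and at least two chains. Between-
chain convergence is summarised by the Gelman–Rubin potential scale
reduction factor (PSRF) for every parameter; a single chain falls back to
split-halves PSRF. Replication-level simulation runs use shorter single
chains (2,000 iterations, 500 burn-in), which diagnostics in the test suite
show is ample for these well-identified fits; any fit whose prevalence PSRF
exceeds 1.2 is flagged in the results rather than silently kept.

Model fit is compared by DIC, computed on the *observed-data* likelihood of
$(y_1, y_2)$ with the latent statuses summed out analytically:
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$. The
marginalized focus avoids the pathologies of conditioning DIC on a latent
configuration. Credible intervals for the PSSA prevalence default to
posterior 2.5/97.5 percentiles; a percentile bootstrap over full refits is
possible in principle but costs 999 refits per interval, so it is not the
default.

## The simulation engine

Each simulated population is built in three layers:

1. **Markers.** A panel of $N_x$ binary disease markers is generated from a
   Gaussian copula: latent multivariate normal draws with a specified
   correlation matrix, dichotomised so marker $k$ has its target
   prevalence (success = latent value above the $1-p_k$ normal quantile).
   The correlation matrix is either exchangeable at the target mean, or
   "unstructured": off-diagonals drawn uniformly within $\pm 0.15$ of the
   mean, projected to the nearest positive-definite correlation matrix and
   recentred until the realised mean is within 0.01 of target. Marker
   prevalences default to one draw per condition from $U(0.05, 0.35)$ —
   the range typical of comorbidity flags in adult cohorts — and marker
   log-odds coefficients default to an equally spaced grid from
   $\log 1.5$ to $\log 2.5$, the magnitude of association reported for
   hypertension risk markers. Both are overridable.

2. **Truth.** $D_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 +
   x_i'\beta))$, with $\beta_0$ calibrated by monotone root-finding so the
   population mean probability hits the condition's true prevalence to
   within $10^{-5}$ (calibration panel of 50,000 by default).

3. **Observed sources.** Given $D_i$, source $j$ reports positive with
   probability $Sn_j$ ($D_i = 1$) or $1 - Sp_j$ ($D_i = 0$) — the
   uniform-threshold conditional Bernoulli construction. Within each
   stratum of $D$ the two sources' uniforms are coupled by a shared
   Gaussian copula with a stratum-specific correlation, because
   independent draws cannot reach the high between-source correlations
   seen in real linked cohorts; the marginal $Sn/Sp$ are unaffected.

**Accuracy calibration.** A simulation condition specifies the *observed*
marginal prevalence of each source and the between-source correlation, not
the generating $Sn/Sp$. The marginal constraint
$Sn_j\,p + (1 - Sp_j)(1 - p) = \mathrm{obs}_j$ leaves one degree of freedom
per source; it is closed by fixing the generating specificity at the same
values the RSSA correction assumes (0.95 and 0.90), so that RSSA
misspecification arises only through sensitivity. When the observed
prevalence lies below the false-positive floor $(1 - Sp_j)(1 - p)$ this has
no solution, and the source falls back to an even split — half its observed
positives are false positives: $Sp_j = 1 - \mathrm{obs}_j/(2(1-p))$,
$Sn_j = \mathrm{obs}_j/(2p)$. The even split is the neutral choice in the
absence of any information about the error mix, and it keeps the fallback
source informative ($Sn + Sp > 1$) whenever $p < 0.5$. The
between-source correlation target is interpreted on the **tetrachoric**
scale (the scale on which agreement between such sources is reported in
practice, and the only scale on which values like 0.85 are attainable at
these margins); the shared-error correlation is solved by monotone
root-finding so the implied 2×2 cell probabilities reproduce the target
exactly. If the fixed-specificity solution leaves a source too
uninformative for any dependence to reach the target, the fallback is
engaged for that source too, in a fixed preference order; perfect-test
conditions, where dependence cannot move the cells at all, return zero
dependence with a `dependence_saturated` flag.

**Seeding.** Every condition derives its seed as a stable hash of its
fields offset by the user's base seed, and every replication derives its
seed from the condition's, so any cell or single replication can be
reproduced in isolation and grids are resumable per condition.

**Evaluation.** Across $R$ replications, each method is summarised by
percent absolute relative bias
$\mathrm{RB} = 100\,|p_T - \overline{\hat\pi}|/p_T$ and by
$\mathrm{MSE} = \sigma^2_{\hat\pi} + |p_T - \overline{\hat\pi}|^2$,
reported ×100. The variance term uses the divide-by-$R$ (plug-in)
convention so that MSE/100 decomposes exactly into variance plus squared
bias; the sample-variance convention is available by argument.

## Tetrachoric correlation

Association between binary indicators is measured by the tetrachoric
correlation: the correlation of the latent bivariate normal whose
thresholds reproduce the margins and whose orthant probability reproduces
the 2×2 table. The orthant probability is computed by one-dimensional
adaptive quadrature of
$\int_h^\infty \phi(x)\,\bar\Phi\!\big((k - \rho x)/\sqrt{1-\rho^2}\big)\,dx$
(accurate to ~$10^{-10}$), and the correlation is found by monotone
root-finding. Standard errors use the delta method through Plackett's
identity ($\partial p_{11}/\partial\rho$ is the bivariate normal density at
the thresholds), ignoring threshold variability — adequate at the cohort
sizes involved. Tables with an empty off-diagonal cell return ±1 with a
boundary flag.

## The synthetic linked-cohort fixture

No real linked cohort ships with the package. `generate_cohort_fixture()`
emulates one at the structural level: ~69,000 adults with sex, three age
groups and ten binary comorbidity flags generated through the same copula
machinery (mild exchangeable correlation 0.1), a logistic truth model
dominated by age, true prevalence 0.28, and two calibrated sources whose
margins straddle the truth (0.31 over-capturing, 0.25 under-capturing) with
tetrachoric correlation 0.90 — the association level reported between
administrative and EMR hypertension case definitions. The covariate
prevalences are synthetic values shaped like a primary-care cohort's
descriptive table, not a resample of any real data, and the fixture
includes the (normally unobservable) `true_status` column precisely
because it is synthetic. What passing tests on this fixture show is that
the estimators behave correctly when the generating process matches their
assumptions to the degree stated; they cannot show that real claims/EMR
errors follow a shared-Gaussian-copula dependence, that real marker effects
are logistic, or that real accuracy is constant across subgroups.

## Problem sizes used by the tests and the acceptance script

The reference design uses 500 replications of each of 144 conditions with
an unstated population size. This package defaults to populations of
10,000 per replication — large enough that estimator bias, not population
noise, dominates — and its shipped evaluation runs at desk scale:
rule-based cells at 200 replications × 10,000 people; latent-class (PSSA)
cells at 100 replications × 5,000 people with 2,000 Gibbs iterations (500
burn-in, one chain); qualitative ranking checks at 200 replications for
rule-based methods and 100 × 2,000-person populations with 800 iterations
for PSSA. These sizes are the package's choice of Monte-Carlo scale: the
estimator biases being measured are structural, and checks at larger
scales move the numbers by less than the tolerances used.

## Known limitations

* Under the dependence calibration above, the PSSA conditional-independence
  assumption is violated by construction whenever the correlation target
  exceeds what conditionally independent errors can produce. This
  misspecification, not marker-panel redundancy, dominates PSSA's bias in
  the shipped simulation cells; consequently the sensitivity of PSSA bias
  to the *marker* correlation is weak here, in contrast to study designs
  where the reporting model is correctly specified.
* RSSA's point estimate depends on the data only through the two observed
  margins. When a margin falls below the assumed false-positive floor
  $1 - Sp_j$, the corrected estimate truncates to zero; conditions with
  very low observed prevalence therefore produce severe RSSA
  underestimation unless the assumed accuracy is close to the truth.
* The tetrachoric CI ignores threshold estimation error; the RSSA
  inverse-variance weighting uses a delta-method variance that ignores the
  truncation at 0 and 1.
* Only two sources are supported, reporting models are intercept-only, and
  markers must be complete (no missing-data handling).
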