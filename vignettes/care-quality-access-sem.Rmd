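---
title: "Latent care quality, latent access, and unplanned admissions: the model behind caresem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent care quality, latent access, and unplanned admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caresem)
```

## The problem

Primary-care quality and patients' access to primary care are both believed
to influence unplanned (emergency) hospital admissions for long-term
conditions such as diabetes, but neither can be observed directly. What is
observed, per general practice, is

* a handful of **clinical quality indicators**: of $N_{ij}$ registered
  diabetes patients, $Z_{ij}$ attain a clinical target (blood pressure,
  cholesterol, HbA1c control, influenza immunisation);
* a handful of **patient-survey access indicators**: of $V_{ik}$ surveyed
  patients, $W_{ik}$ rate an aspect of access as poor (opening hours,
  appointment convenience, overall experience, waiting times);
* the count of **diabetes-related emergency admissions** $Y_i$;
* covariates: income deprivation $D_i$, age-standardised diabetes morbidity
  $M_i$, GP supply $S_{1i}$ (FTE GPs per 1000 patients) and list size
  $S_{2i}$ (thousands).

Summarising the indicators into official attainment scores ignores both the
sampling variability of proportions with very different denominators and
the correlation between indicators. caresem instead treats quality and
(poor) access as latent variables in a Bayesian structural equation model
of the multiple-indicators-multiple-causes (MIMIC) type, and estimates
their effects on admissions jointly with the measurement step.

## The model family

**Measurement (quality).** For practice $i$ and indicator $j$,

$$Z_{ij} \sim \mathrm{Binomial}(N_{ij}, \pi_{ij}), \qquad
\mathrm{logit}(\pi_{ij}) = \delta_j + \lambda_j F_i + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathrm{N}(0, \sigma_j^2),$$

with $\lambda_1 = 1$ anchoring the scale and orientation of the latent
quality score $F_i$. The logit-normal term $\varepsilon_{ij}$ captures
extra-binomial dispersion; it composes additively with the loading
structure, which is why it is preferred here over a beta-binomial
formulation. The access block is the mirror image:
$W_{ik} \sim \mathrm{Binomial}(V_{ik}, p_{ik})$,
$\mathrm{logit}(p_{ik}) = \eta_k + \kappa_k G_i + e_{ik}$, $\kappa_1 = 1$,
where $G_i$ is *poor* access (higher = worse).

**Structure.** $(F_i, G_i)$ are bivariate normal with correlation $\rho$
and covariate-driven means,

$$\mathrm{E}(F_i) = \beta_1 D_i, \qquad
\mathrm{E}(G_i) = \beta_2 D_i + \beta_3 S_{1i} + \beta_4 S_{2i},$$

so deprivation can erode quality, and deprivation, GP supply and list size
can shift perceived access. Under the robust variant (model 4) the pair is
bivariate Student-t with 4 degrees of freedom, implemented exactly as the
Gamma$(\nu/2, \nu/2)$ scale mixture on the latent covariance; the mixture
weights get a conjugate Gibbs update and the degrees of freedom are fixed,
not estimated.

**Outcome.** With expected counts $E_i$ fixing the exposure scale,

$$Y_i \sim \mathrm{Poisson}(E_i \nu_i), \qquad
\log \nu_i = \gamma_0 + \gamma_1 F_i \;[+\; \gamma_2 D_i + \gamma_G G_i +
\gamma_M M_i] \;+\; u_i, \qquad u_i \sim \mathrm{N}(0, \alpha^2).$$

The bracketed terms define the model ladder: model 1 is quality-only,
model 2 adds deprivation and morbidity, models 3–4 add the latent access
term. $\alpha$ is the log-scale overdispersion sd of the admission counts;
a single residual-sd parameter of this kind is consistent with its observed
shrinkage when strong covariates enter the outcome model. Because the
package names outcome terms (`intercept`, `quality`, `deprivation`,
`poor_access`, `morbidity`) rather than numbering coefficients, the model-2
and model-3 ladders do not collide even though the third slope means
different things in each.

**Expected counts.** $\nu_i$ is a relative risk, so an exposure is needed.
`compute_expected_counts()` sets $E_i \propto$ the mean quality-indicator
denominator (a diabetes-register proxy — the natural exposure for
diabetes-related admissions) or, optionally, list size, internally
standardized so $\sum_i E_i = \sum_i Y_i$ and $\nu_i = 1$ is the no-effect
reference.

**Priors.** Normal$(0, 10^2)$ on coefficients, intercepts and free
loadings — crucially *sign-neutral*, which is what licenses reading a
posterior sign probability $p$ as a marginal Bayes factor $p/(1-p)$;
Half-Normal$(0,1)$ on all sds; Uniform$(-1,1)$ on $\rho$. After covariate
standardization (`standardize_covariates()`, an explicit pipeline step)
these are weakly informative on every axis.

## Inference

`fit_admissions_sem()` runs an adaptive Metropolis-within-Gibbs sampler
written for this model rather than delegating to a generic engine. Latent
quantities ($F_i$, $G_i$, $\varepsilon_{ij}$, $e_{ik}$, $u_i$) have
practice-wise (or cell-wise) random-walk updates — their full conditionals
factor across practices, so proposals are vectorised with per-element
accept/reject. Scale parameters move on the log scale and $\rho$ on the
Fisher-z scale, with Jacobians. Proposal scales adapt in batches of 50
towards a 20–50% acceptance rate during burn-in and are frozen afterwards,
so the post-burn-in chain is a fixed Markov kernel and runs are exactly
reproducible from the seed.

Two families of extra moves matter in practice:

* **Recentring:** adding $d$ to every $F_i$ while subtracting
  $\lambda_j d$ from every $\delta_j$ leaves the measurement likelihood
  invariant; a Metropolis step along this direction breaks the strong
  posterior coupling between intercepts and the latent mean (likewise for
  $G/\eta$, and for $u/\gamma_0$).
* **Funnel rescaling:** jointly proposing
  $(\varepsilon_{\cdot j}, \sigma_j) \to (c\,\varepsilon_{\cdot j}, c\,\sigma_j)$
  (with the $c$ Jacobian) walks along the funnel axis that traps
  single-site updates when an overdispersion sd approaches zero — exactly
  the regime the outcome sd $\alpha \approx 0.03$ lives in.

Both are ordinary Metropolis–Hastings moves on the exact posterior. In
pilot runs at study scale (90 practices) they raised the minimum effective
sample size by more than an order of magnitude at unchanged cost.

Defaults of 4 chains × 20,000 iterations (half burn-in, thin 5) give
comfortable effective sizes for reporting; the package's own experiments
use shorter single chains (stated below) because they average over many
replicates. `convergence_report()` provides split-$\widehat{R}$ and an
effective sample size based on chain-averaged autocovariances with Geyer's
initial-positive-sequence truncation; both are verified in the test suite
against white-noise and AR(1) closed forms.

Degenerate inputs are handled at initialization: measurement intercepts
start at pooled empirical logits with a $(x+0.5)/(n+1)$ continuity
correction, so an all-zero survey column is finite; an all-zero column's
$\tau_k$ remains proper under its half-normal prior without special
casing. All binomial likelihood evaluation happens on the logit scale
($Z\theta - N\,\mathrm{softplus}(\theta)$), finite at $Z = 0$ and $Z = N$
for any finite $\theta$.

## Model criticism

* `waic()` computes WAIC per likelihood component (admissions, quality
  indicators, access indicators) from stored pointwise log-likelihood
  cells — one per practice for the outcome, one per practice × indicator
  for the measurement blocks — with log-sum-exp stabilization.
* `posterior_predictive_check()` simulates a replicate of one observed
  variable per retained draw and compares chi-square discrepancies
  $T(x;\theta) = \sum_i (x_i - \mathrm{E}[x_i\mid\theta])^2 /
  \mathrm{Var}(x_i\mid\theta)$ between replicate and observation. The
  chi-square statistic is a deliberate package choice — an omnibus default
  for counts; p-values between roughly 0.1 and 0.9 indicate satisfactory
  fit, and the meaningful contract is that band, not any particular value.
* `sign_probability()` and `marginal_bayes_factor()` convert coefficient
  draws into $\Pr(\text{coef} < 0 \mid \text{data})$ and posterior odds;
  a probability of 0.918 corresponds to a Bayes factor of 11.2.
* `factor_risk_curve()` pairs posterior-mean factor scores with
  posterior-mean relative risks and adds a locally weighted linear smooth
  (tricube weights, span 2/3 by default), the standard way to display a
  possibly non-linear quality–risk relation.

## Geography

`aggregate_to_areas()` turns practice scores into small-area scores via a
row-stochastic population crosswalk (area × practice shares). Rows whose
raw weights sum below 1 — partial coverage — are renormalized, preserving
convexity, and the original row sum is reported as `covered_fraction`
rather than silently dropped. Aggregation is offered both draw-wise (then
summarized, propagating posterior sd to areas) and on posterior means; the
two agree exactly on the mean by linearity, so the choice only matters for
uncertainty display.

## The synthetic-data generator

`simulate_practice_data()` draws from exactly the generative model above,
and its defaults *are* the study conditions the package is calibrated to:
90 practices, 4 + 4 indicators, register-sized quality denominators
(uniform 50–600) and survey-sized access denominators (uniform 50–200),
reflecting how much denominators vary across indicators and practices.
Generative parameter values (`default_parameters()`) use the reported
posterior means of the full structural model — e.g. quality effect
$-0.17$, deprivation effect $0.24$, poor-access effect $0.18$, morbidity
$0.09$, $\beta_2 = 0.45$, $\rho = -0.38$ — with measurement intercepts at
the logits of the observed overall indicator rates (92.1%, 79.4%, 74.6%,
93.0%; 12.6%, 9.7%, 13.1%, 13.4%).

Quantities the study does not print were fixed once, as follows, and not
revisited:

* **latent sds** $\psi_F = 0.5$, $\psi_G = 0.8$, calibrated to the
  observed 10th–90th percentile spread of practice rates on the logit
  scale;
* **overdispersion sds** $\sigma_j = \tau_k = 0.15$, mild logit-scale
  heterogeneity; $\alpha = 0.03$ as reported for the full model;
* **exposure scale** mean $E_i = 50$ admissions per practice-year, a
  realistic scale for diabetes-related emergency admissions;
* **covariates** drawn standardized, with the deprivation–morbidity
  correlation 0.70 as reported for the study region; coefficients are
  interpreted on that standardized scale throughout.

The generator emulates the *structure* of the real data — heterogeneous
binomial denominators, correlated latent factors with covariate-driven
means, overdispersed counts — but not every feature of it: no spatial
autocorrelation beyond what deprivation induces, no missingness, no
reporting artefacts in survey responses, and independent uniform
denominators rather than the real joint distribution of register and
survey sizes. Passing recovery tests therefore demonstrates that the
inference machinery is correct and well calibrated under the stated
conditions, not that the substantive findings would replicate on other
real data.

## Verification experiments

Four experiment drivers double as the package's acceptance evidence; the
replicate counts and chain lengths below are the package's declared
problem sizes.

1. **Grid oracle** (`grid_oracle_experiment()`): on a 3-practice toy with
   latents fixed, the MCMC posterior of the quality coefficient is
   compared with fine-grid numerical integration (step 0.001). Agreement
   is to ~$10^{-3}$ on the mean in typical runs.
2. **Parameter recovery** (`recovery_experiment()`): 50 datasets at the
   calibrated truths, I = 90, single chains of 3,500 iterations (1,500
   burn-in, thin 4). 95% intervals cover the true structural parameters in
   well over 85% of replicates, and the posterior mean of $\rho$ is
   negative in essentially all of them.
3. **WAIC ordering** (`waic_comparison_experiment()`): with genuine
   deprivation and morbidity effects in the generator, the outcome-component
   WAIC of model 2 beats model 1 in nearly all of 20 replicates — the
   qualitative pattern expected when strong covariates are omitted.
4. **Simulation-based calibration** (`sbc_experiment()`): 200 prior-draw
   replicates on a reduced toy (3 practices, 2 indicators, unit-normal
   priors, heavy thinning); rank statistics of the true parameters among
   100 posterior draws are uniform by chi-square test.

## Known limitations

* The sampler is random-walk based; for much larger registries (thousands
  of practices) a gradient-based sampler would mix faster per second.
* No cross-loadings (quality indicators load only on F, access indicators
  only on G) and at most two latent factors, by design.
* The Student-t degrees of freedom are fixed at 4, not estimated.
* WAIC is the only fit criterion; no LOO-CV or formal Bayes-factor model
  comparison between the four variants.
* Area aggregation assumes the crosswalk is measured without error and
  ignores any spatial process beyond composition.
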