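---
title: "Estimating hypothetical estimands in non-inferiority trials with non-compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hypothetical estimands in non-inferiority trials with non-compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicomply)
```

## The problem

In a non-inferiority (NI) trial comparing a new treatment against an active
standard, non-adherence that is *trial-specific* — deviations that happen in
the trial but would not happen in routine care — makes the arms artificially
similar and so makes a spurious declaration of non-inferiority more likely.
An intention-to-treat (ITT) analysis, which targets the treatment-policy
estimand, is anti-conservative in exactly this situation.  The natural
target is instead a *hypothetical estimand*: the expected difference in
potential outcomes had every participant complied with their assigned
treatment,

$$\theta = E[Y(Z=1, C=1)] - E[Y(Z=0, C=1)],$$

where $Z$ is the randomized arm (0 = standard, 1 = new), $C$ compliance
with the assigned treatment, and $Y$ a continuous outcome (higher is
better).  Compliance is all-or-nothing in both active arms: a participant
receives their allocated treatment in full or receives no treatment, with
no switching.  Non-inferiority is declared when the lower limit of the
two-sided 95% interval for $\theta$ exceeds a (negative) margin, $-0.3$
throughout.

`nicomply` implements five estimators of $\theta$, a trial simulator with
named compliance scenarios, and a simulation-study engine that computes the
frequentist operating characteristics used to compare the estimators.

## Estimators

Let $R_0 = (1-Z)C$ and $R_1 = ZC$ indicate actual receipt of the standard
and new treatment, $X$ an observed binary baseline covariate and $U$ an
unobserved one.  All analyses adjust for $X$.

* **ITT** (`fit_itt`): OLS of $Y$ on $Z$ and $X$ over everyone.  Unbiased
  for $\theta$ only under full compliance (or when non-compliance leaves
  outcomes unchanged).
* **Per-protocol** (`fit_pp`): the same regression restricted to
  compliers.  Needs conditional exchangeability given $X$, a correctly
  specified $X$–outcome association, and no treatment-effect heterogeneity
  (TEH) across $X$.
* **IPW** (`fit_ipw`): per-arm logistic regressions of $C$ on $X$ give
  weights $1/\hat P(C=1\mid Z, X)$; a weighted regression of $Y$ on $Z$
  among compliers with a robust (HC1) sandwich SE then recovers $\theta$
  under exchangeability given $X$ and positivity.  Fitted probabilities of
  0 or 1 (perfect prediction while compliance still varies in the arm)
  cause the affected observations to be dropped and the fit to be flagged;
  an arm that complies in full is treated as probability exactly 1.
* **IV(interaction)** (`fit_iv_interaction`): two-stage least squares with
  endogenous $R_0, R_1$ and instruments $Z$ and $Z X$.  Identified only
  when the predicted compliances are not proportional across levels of
  $X$; the covariance is the standard asymptotic 2SLS form (structural
  residual variance divided by $n$).
* **IV(Bayes)** (`fit_iv_bayes`): linear stage-1 models for $R_0$ and
  $R_1$ on $Z$ (and $X$), a stage-2 normal model of $Y$ on the predicted
  receipts and $X$, and a normal prior on the standard-receipt effect
  $\beta_{C0}$ that resolves the collinearity between the predicted
  receipts.  The estimate is the posterior mean of
  $\beta_{C1} - \beta_{C0}$, the SE its posterior SD, and the NI decision
  uses the 2.5th posterior percentile.

### The Gibbs sampler behind IV(Bayes)

Because the stage-1 design takes only the four $(Z, X)$ values, every full
conditional of the model is normal or inverse-gamma and depends on the data
only through per-cell counts and sums; the sampler (written in C++) is
therefore fast enough to run inside replicated simulation studies.  Three
variants are provided:

* `"joint"` (default for single fits): fully Bayesian; the outcome
  likelihood also informs the stage-1 coefficients.
* `"sampled"`: stage 1 is modularized — its coefficients are drawn from
  their own posterior, with no outcome feedback.  When an arm's compliance
  is constant the stage-1 residual variance degenerates and joint feedback
  becomes ill-behaved, so `"joint"` falls back to `"sampled"`
  automatically.
* `"plugin"` (default inside `run_study` grids): stage 1 fixed at least
  squares.  On scenario A1 the three variants agree on the point estimate
  within Monte-Carlo error (a unit test checks this).

Defaults are 4 chains of 2500 iterations (500 warm-up), split-$\hat R$
threshold 1.01 (non-convergence flags the result rather than failing),
inverse-gamma(0.001, 0.001) priors on the three error variances, and flat
priors on all coefficients except $\beta_{C0}$.

A calibration remark: the two-stage Bayesian formulation conditions on the
compliance model and therefore cannot exploit the negative sampling
covariance between arm outcome means and arm compliance rates.  Its
posterior SD consequently runs some 10–15% above the empirical SE in the
core scenario, and the credible-interval NI test is conservative (type-I
error near 1.5% against the nominal 2.5% with a unit-SD well-centered
prior; wider priors push it lower still, mirroring the behavior of vague
priors).  This is a property of the method, not of the implementation: the
package reports what the estimator does.

## The simulator

`generate_trial(config, seed)` draws $X, U \sim$ Bernoulli(0.5),
$Z \sim$ Bernoulli(1/2), then compliance from

$$\text{logit}\, P(C=1) = \gamma_0 + \gamma_Z Z + \gamma_X X + \gamma_U U +
  \gamma_{ZX} ZX + \gamma_{ZU} ZU$$

and the outcome from

$$Y = \beta_0 + \beta_{C0} R_0 + \beta_{C1} R_1 + \beta_X X + \beta_U U +
  \delta_X R_1 X + \delta_U R_1 U + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2).$$

The implied true estimand is
$\beta_{C1} - \beta_{C0} + \delta_X p_X + \delta_U p_U$
(`true_hypothetical_estimand`).  A $Z$-by-$X$ interaction in the
compliance model creates *measured* confounding between compliance and
outcome, a $Z$-by-$U$ interaction *unmeasured* confounding.

### Scenario presets and reconstructed magnitudes

The preset registry (`scenario_preset`, `scenario_labels`) encodes the
compliance scenarios of the core simulation study: 1 (no covariate
dependence), 2a–c ($X$ only), 3a–b ($X$ and $U$), 4a–b ($U$ only), with
"same" or "reversed" associations between arms.  The core study fixes
$n = 100$, overall compliance 70%, true estimand $-0.3$ and margin $-0.3$.

Where exact coefficient magnitudes were open, the package fixes them once
as follows and does not revisit them:

* outcome model $\beta_0 = 0$, $\beta_{C0} = 1$, $\beta_{C1} = 0.7$
  (an effective standard treatment and a slightly inferior new one, so
  $\theta = -0.3$), $\beta_X = \beta_U = 0.5$, $\sigma = 1$;
* covariate-compliance slopes of $\pm 1$ on the log-odds scale, i.e.
  roughly 20-percentage-point compliance differences across covariate
  levels — a "large interaction" in the sense used when discussing the
  interaction instrument;
* scenarios advertising higher compliance to the new treatment use arm
  means 0.65/0.75; "same overall compliance" scenarios use 0.70/0.70.
  Intercepts are solved numerically so the arm means hold exactly;
* `A4a_balanced` keeps the 4a structure with equal 70% compliance in both
  arms — the configuration under which IV(Bayes) is robust to a
  mis-centered prior (with equal compliance rates the prior term cancels
  from the contrast);
* `B1` ($n = 1500$, 90% compliance, no covariate dependence) is the
  package's reconstruction of a larger trial with 10% trial-specific
  non-compliance, used to demonstrate the two- to three-fold ITT type-I
  inflation; the analytic rate at these settings is about 7%;
* TEH presets ($n = 500$) vary the heterogeneity term
  ($\delta = 0.25$ or $0.5$, with $\beta_{C1}$ shifted so the truth stays
  $-0.3$) against the between-arm compliance-level difference
  (0.65/0.75 or 0.60/0.80), with a fixed $-1$ slope on the relevant
  covariate in both arms supplying the confounding.  An earlier symmetric
  design with arm-reversed slopes turned out to make X-adjusted
  per-protocol exactly unbiased (the reversal equalizes the within-stratum
  OLS weights across arms), which is why the compliance-level difference
  is the factor varied here.
* The mis-centered prior displaces the prior mean by $0.5\sigma$ from the
  true $\beta_{C0}$; "precise" and "vague" prior SDs default to $1\sigma$
  and $10\sigma$ (`prior_grid`).

What the generator deliberately does not emulate: time-varying or partial
compliance, treatment switching between active arms, non-normal outcomes,
missing outcome data, and block or stratified randomization (allocation is
simple Bernoulli(1/2)).  Passing tests therefore speak to the all-or-nothing
compliance setting only.

## The simulation-study engine

`run_study` derives one sub-seed per replication from a master seed,
generates a trial, fits every requested estimator (failures are recorded,
never fatal) and applies the NI decision rule.  `filter_replications`
reproduces the reporting conventions: interaction-IV replications whose
model SE exceeds 10 times the ITT empirical SE are marked as outliers, and
IPW replications with perfect-prediction drops are marked; marked
replications are excluded from filtered summaries but never deleted, so
unfiltered summaries remain available.  `summarize_study` computes mean
estimate, bias, empirical SE, mean model SE and its relative error, the NI
declaration rate (the type-I error when the truth equals the margin — the
boundary-null convention), the precision increase of ITT versus each
estimator, $100[(SE_{\text{alt}}/SE_{\text{ITT}})^2 - 1]$, and Monte-Carlo
standard errors (empirical SE$/\sqrt{n}$ for the bias, binomial for
rates).

```{r, eval = FALSE}
cfg <- scenario_preset("A2b")
rec <- run_study(cfg, c("itt", "pp", "ipw"), n_reps = 2000, master_seed = 1)
summarize_study(rec)
```

Numerical conventions worth stating: intervals are normal-quantile based
(not $t$), one-sided $\alpha = 0.025$ by default; the NI rule uses a strict
inequality at the margin; replication seeds are drawn as integers below
$2^{31}$; the default replication count of 2000 puts the MC-SE of a 2.5%
rate at about 0.35 points.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the study at the sizes the
method comparison itself uses: 2000 replications for the fast estimators
(ITT, PP, IPW), 500–2000 for IV(Bayes) (with the plug-in variant and 2
chains of 1250 draws inside grids), and 1000 for the credible-interval
type-I check.  One full acceptance run takes on the order of a minute on a
single CPU.

## Known limitations

* The interaction-IV estimator is included for comparison; it is unstable
  exactly as the simulation literature warns (its SE filter exists for
  that reason), and nothing here improves on that.
* The IV(Bayes) credible-interval test is conservative in the core
  scenario (see the calibration remark above).
* Estimators assume a single binary observed covariate in the weight and
  instrument constructions; extending to richer covariates would change
  the cell-sufficient-statistic sampler.
* The per-study-day, time-varying-treatment extension of IPW is out of
  scope, as are margin elicitation, g-estimation and multiple-imputation
  comparators.
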