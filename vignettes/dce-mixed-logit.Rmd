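---
title: "Designing, simulating and estimating discrete choice experiments with dcemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, simulating and estimating discrete choice experiments with dcemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcemix)
```

## The model

A discrete choice experiment (DCE) presents each respondent with a series of
choice tasks, each offering alternatives described by policy attributes. The
package works with the random-utility model

$$U_{ij} = \beta_i' x_j + \epsilon_{ij},$$

where $x_j$ is the dummy-coded description of alternative $j$ (one indicator
per non-reference level of each categorical attribute, the money value of a
one-time fee, and an alternative-specific constant for the left-listed
option), and $\epsilon_{ij}$ is i.i.d. type-1 extreme value. Individual
tastes follow

$$\beta_i = \beta + \eta_i, \qquad \eta_i \sim N(0, \mathrm{diag}(\sigma^2)),$$

the panel mixed logit (MXL): $\beta$ is the population mean and $\sigma$ the
heterogeneity SDs of the predictors declared random. The mixed-mixed
multinomial logit (MMML) adds a finite-mixture layer: respondents belong to
one of $K$ latent classes, each with its own $(\beta_c, \sigma_c)$, and
class membership follows a multinomial logit on respondent covariates
(class 1 is the reference). The class count is chosen by the Bayesian
information criterion, $\mathrm{BIC} = -2\log L + p\log n$ with $n$ the
number of respondents — respondents, not choice observations, because the
respondent is the independent sampling unit of a panel.

The package's defaults emulate a stated-preference study of COVID-19
nonpharmaceutical interventions (NPIs) in Singapore: seven attributes
(masking, dining-group limits, vocalization activities, large-scale events,
post-travel quarantine, booster mandate, and a one-time fee of S\$0/10/30/50),
20 questionnaire blocks of 7 binary choice tasks, and a panel of about 1,550
adults. Reference levels are always the least stringent policy option, so a
positive coefficient means the restriction is valued.

## Design construction

`generate_design()` builds blocked designs by a seeded swap heuristic that
minimises a composite of three criteria:

* **level balance** — mean absolute deviation of each level's usage from
  uniform;
* **D-error** — $\det(M)^{-1/P}$ of the information matrix of the encoded
  design under zero coefficients, with the fee column scaled to $[0,1]$ so
  one attribute cannot dominate;
* **overlap** — squared distance of the per-task fraction of attributes
  sharing a level from a target (default 1/3).

The overlap term implements the "balanced overlap" compromise: some
attribute overlap within a task reduces respondent burden, but full overlap
makes a task uninformative, so both extremes are penalised. The commercial
algorithm used by survey vendors is proprietary; a seeded swap optimiser
with an explicit, auditable criterion reproduces its intent and is exactly
reproducible. The optimiser proposes `n_iter` single-attribute changes
(default 4,000), accepting those that do not worsen the score; duplicate
alternatives within a task are never admitted.

Two sample-size rules are reported by `sample_size_requirements()`: the
Johnson–Orme rule of thumb $n > 500c/(ta)$ (rounded up, so the canonical
design with $c=4$, $t=2$, $a=7$ gives 143) and the 20-respondents-per-block
rule (400 for 20 blocks); the recommendation is the larger of the two.

## The synthetic panel

`simulate_profiles()` draws covariates independently from the marginal
distributions of the reference sample (58.2% female, 84.7% Chinese
ethnicity, 92.8% with three or more vaccine doses, and so on), age from a
normal distribution with mean 48 and SD 14 truncated at the eligibility age
of 18 (by inverse-CDF sampling, which keeps the draw count fixed and the
stream reproducible), and a health-risk-attitude sum score from
$N(42, 8^2)$. Cross-tabulations of the original sample are not published,
so covariates are independent by construction — recovery results therefore
say nothing about confounded covariate structures.

`simulate_choices()` assigns each respondent to one block uniformly at
random, draws $\beta_i$ once per respondent (diagonal normal around the
class mean), adds fresh Gumbel noise per respondent–task–alternative, and
records the argmax. Two taste patterns ship as defaults
(`npi_simulation_config()`):

* `"pooled"` — the population-level pattern of the reference analysis
  (e.g. masks in public +0.54, full dining prohibition −0.89, fee −0.02 per
  SGD, left ASC −0.08), with SD 0.8 on the five predictors that exhibited
  individual-level heterogeneity (both mask levels, the dining prohibition,
  facility quarantine, the booster mandate).
* `"two_class"` — a pro-NPI class (masks in public +1.98) and an anti-NPI
  class (−0.37, with strong aversion to dining bans and facility
  quarantine), about 39/61 in share. Membership uses an intercept of 0.13
  and a male coefficient of 0.8, chosen so the implied population share of
  the anti-NPI class is ≈0.61 and men are about 2.2 times as likely (odds)
  to be in it. Within-class SDs are set to 0.5 — smaller than the pooled
  0.8 because the mixture itself absorbs part of the taste spread.

The fee coefficient is fixed (non-random) by default so willingness to pay
is a well-defined ratio of a normal to a constant rather than a ratio of
normals, whose moments do not exist. The mixing covariance is diagonal;
correlated taste draws can be emulated by supplying a custom draw array,
but no correlated default is offered because only SDs, not correlations,
are identifiable from the reference outputs.

## Estimation

`fit_mxl()` maximises the simulated log-likelihood: for each respondent the
product of conditional-logit probabilities over their tasks is averaged over
`R` draws of $\eta_i$ (default 500), and the sum of log averages is
maximised by BFGS with analytic gradients, warm-started at the
conditional-logit solution (`fit_clogit()`, an exact damped-Newton fit).
Numerical choices that matter:

* **Draws.** Scrambled Halton sequences (one prime base per random
  dimension, first 100 points dropped, seeded random shift modulo 1),
  mapped through the normal quantile function; each respondent owns a
  contiguous block of draws held fixed throughout the optimisation, so the
  objective is smooth and deterministic. Draws are antithetic (each point
  paired with its negation), which halves simulation variance of symmetric
  functionals and makes the likelihood exactly invariant to the sign of a
  single heterogeneity SD; SDs are reported as $|\sigma|$.
* **Scaling.** Internally every predictor column is divided by its maximum
  absolute value (the fee spans 0–50 while dummies are 0/1), so BFGS works
  on comparably scaled parameters; estimates and covariances are mapped
  back afterwards. This cut typical fit times by an order of magnitude.
* **Convergence.** The optimiser stops on a relative function tolerance of
  1e-9 (cap 400 iterations); a fit is flagged converged if the optimiser
  reports success or the gradient max-norm at the solution is below
  $0.01\sqrt{n}$ — a displacement of well under a thousandth of a standard
  error at typical curvatures. Non-converged fits are returned but flagged,
  and `select_k()` excludes them from model choice with a warning.
* **Standard errors.** Default is the inverse numerical Hessian
  (forward differences of the analytic gradient, symmetrised); the BHHH
  outer-product-of-scores estimator (`se = "bhhh"`) is essentially free and
  useful in replicate studies; a robust sandwich combines the two. When an
  SD estimate sits on the zero boundary its score vanishes identically and
  the information matrix is singular; a Moore–Penrose fallback keeps the
  remaining standard errors usable.

`fit_mmml()` maximises the simulated mixture likelihood directly (one code
path with the MXL rather than an EM loop). Multistart protects against
local maxima: the first start splits the MXL solution along the
`relabel_by` coordinate (one class shifted up, one down), further starts
add seeded noise; with more than one start the exploration runs at a
quarter of the draws and only the best coarse optimum is polished at full
`R` — a standard coarse-to-fine economy that changes nothing at the
reported solution. Label switching is resolved after fitting by ordering
classes on their `relabel_by` mean (default the public-mask coefficient,
so class 1 is the most pro-intervention segment, matching how such classes
are conventionally reported). Membership odds ratios come from the joint
fit, $e^{\gamma}$ with Wald intervals on the log scale.

The simulated likelihood is computed in C++ (via Rcpp): per draw only
scalar per-row weights are accumulated and the fold against the design
matrix happens once per respondent, which makes a full-scale fit
($n=1500$, $R=300$) take seconds rather than minutes on one core.

## Willingness to pay and reporting

`compute_wtp()` converts coefficients to money: $\mathrm{WTP}_k = \beta_k /
|\beta_{fee}|$, positive when respondents would pay to have the measure
implemented, negative when they would pay to avoid it. A non-negative fee
coefficient aborts — the ratio is then meaningless. Intervals come from the
delta method or from Krinsky–Robb resampling (10,000 seeded multivariate
normal parameter draws, percentile interval; draws with a non-negative fee
coefficient are discarded, and the computation aborts if more than half
are, since the ratio distribution is then too ill-behaved to summarise).
For mixtures, WTP uses each class's own fee coefficient. Tables round WTP
to whole currency units; the R objects keep full precision.
`preference_summary()` classifies each attribute level as
preferred / opposed / indifferent by whether its 95% CI lies above,
below, or across zero.

## What the tests do and do not show

The test-suite oracles are independent of the estimation path: brute-force
softmax products for the conditional logit, Gauss–Hermite quadrature for
the one-dimensional mixing integral, closed-form binary-logit shares for
the simulator, direct enumeration for the tiny mixture, and
`survival::clogit` as an external cross-check of the Newton conditional
logit. The acceptance-level studies are parameter-recovery experiments on
synthetic panels generated at the reference study's conditions (20 blocks
× 7 binary tasks; $n=1500$ with $R=300$ and 20 replicates for the MXL,
$n=800$ with $R=200$, candidate $K \in \{1,2,3\}$ and 10 replicates for
the mixture — sizes chosen to keep a full run in minutes on one core while
leaving Monte Carlo margins wide). Passing them shows the estimators
recover the truth under the model's own assumptions — independent
covariates, diagonal normal heterogeneity, i.i.d. Gumbel noise, no
inattention or straight-lining. They cannot validate those assumptions for
any real survey, and the original study's respondent-level data are not
distributed, so its published coefficient values are not reproduced here;
the synthetic suite is the evidence that the machinery estimates what it
claims to estimate.

## Known limitations

* Only diagonal mixing distributions are estimated; correlated or
  non-normal (lognormal, triangular) mixing is out of scope.
* One latent dimension: no scale heterogeneity or mixed-scale models.
* The design optimiser targets main effects under zero priors; it does not
  produce Bayesian-efficient or interaction-supporting designs.
* Simulated covariates are mutually independent, and choices are simulated
  i.i.d. across a respondent's tasks given $\beta_i$ (no fatigue or
  ordering effects).
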