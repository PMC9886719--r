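---
title: "Modal controllability of structural connectomes and executive function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal controllability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efcontrol)
```

## The scientific question

Executive functions — inhibitory control, set shifting, working memory —
decline with age, and a candidate structural substrate for that decline is
the capacity of the white-matter network to steer the brain between
activity states. `efcontrol` implements a complete analysis chain for
testing that idea in an aging twin cohort: per-parcel *modal
controllability* computed from streamline-count connectomes, aggregation
over two networks of interest (the frontoparietal control network and the
multiple demand system, which overlap in their frontoparietal core),
scoring of a common executive-function (EF) factor from six
neuropsychological tasks, and twin-clustered mixed models relating the two
— cross-sectionally at each wave, longitudinally via difference scores,
and with APOE-ε4 or young-adult cognitive ability as moderators.

Because the motivating study's data are restricted, the package ships a
synthetic-cohort generator with known ground truth. Every statistical
claim the test suite makes is a claim about this generator plus the
package's own code path, not about any restricted dataset.

## Modal controllability

The structural connectome of one subject-timepoint is a symmetric,
nonnegative matrix $A$ whose entry $A_{ij}$ counts the tractography
streamlines between parcels $i$ and $j$ (self-connections are discarded).
The matrix is stabilized by the eigenvalue normalization

$$A_{\text{norm}} = \frac{A}{1 + \lambda_{\max}(A)},$$

where $\lambda_{\max}$ is the largest absolute eigenvalue, so the
discrete-time linear system $x_{t+1} = A_{\text{norm}}\,x_t$ has spectral
radius strictly below one. We use the discrete-time convention throughout
(no continuous-time variant): the "+1" normalization is exactly the
discrete-time stabilization, and tractography matrices are undirected, so
only the symmetric eigendecomposition is supported — asymmetric inputs
are rejected rather than handled by a generalized scheme.

With the orthonormal eigendecomposition
$A_{\text{norm}} = V\,\mathrm{diag}(\xi)\,V^{\top}$, the modal
controllability of parcel $i$ is

$$\phi_i = \sum_j \left(1 - \xi_j^2\right) v_{ij}^2 .$$

Parcels with high $\phi$ couple preferentially into fast-decaying modes —
the "difficult-to-reach" states that require substantial input energy.
Because each row of $V$ has unit norm, $\phi_i$ is a convex combination of
the quantities $1 - \xi_j^2$, which yields the invariants the tests
enforce:

* $1 - \max_j \xi_j^2 \le \phi_i \le 1 - \min_j \xi_j^2$ and
  $\phi_i \in (0, 1]$;
* invariance to eigenvector sign and to the basis chosen inside a
  degenerate eigenspace (the sum over an eigenspace is a projection
  norm); rather than special-casing repeated eigenvalues we test that
  perturbing a degenerate matrix moves $\phi$ continuously;
* permutation equivariance and equal values on automorphic nodes;
* the two-node closed form $\phi_1 = \phi_2 = 1 - (w/(w+1))^2$ and
  $\phi \equiv 1$ for the empty graph.

The identity $\sum_j \xi_j^2 v_{ij}^2 = (A_{\text{norm}}^2)_{ii}$ gives an
eigendecomposition-free oracle $\phi = 1 - \mathrm{diag}(A_{\text{norm}}^2)$;
the test suite checks the implementation against both this and an explicit
double-loop summation.

Network summaries are unweighted means of $\phi$ over the member parcels —
no per-parcel re-scaling before averaging. Group topography is the
per-parcel mean of $\phi$ across subjects with average-rank ties, compared
between timepoints by Spearman correlation (t-approximation p-value on
$n-2$ df).

## Executive-function scoring

Six task scores feed one common factor:

| indicator | raw input | transformation |
|---|---|---|
| stroop | color-word correct | OLS residual on word + color conditions |
| trails | switching time | OLS residual on single-task time, negated |
| catswitch | correct switches | OLS residual on category-fluency correct |
| letter_number | total | used directly |
| reading_span | total | used directly |
| digit_span | total | used directly |

Residualization removes variance due to elementary task components;
negating the trails residual is the only direction flip needed so that
every indicator points "higher = better". Each indicator is z-scored over
the wave's non-missing scoring sample; residualization, z-scoring and
factor estimation are all done per timepoint.

The factor model is a one-factor maximum-likelihood fit
(`stats::factanal`) with regression-method (Thomson) scores, z-scored.
The loadings used by the motivating study were estimated in prior work
and are not public, so exact replication of its scoring is impossible;
the package's default is the reproducible ML fit, with a fixed-loadings
escape hatch (`ef_factor_score(ind, loadings = ...)`, uniquenesses
$1-\lambda^2$) for users who have external estimates. Loading signs
follow a majority-positive convention. A Heywood case (uniqueness at the
boundary) is reported as an error with diagnostics rather than silently
accepted. By default a subject with any missing indicator gets a missing
EF score; `allow_partial = TRUE` re-derives Thomson weights from the
model-implied covariance of the observed subset instead.

Covariates: AFQT percentiles (young-adult general cognitive ability) are
probit-transformed — $\Phi^{-1}(p/100)$, strict bounds, no clamping — and
z-scored within the analysis sample (the original study may have used an
external reference sample; that choice is not recoverable from what is
printed). The comorbidity-based health index is capped at 3. A
practice-effect adjustment hook accepts externally pre-adjusted scores;
no formula is implemented because none is available.

## Association models

All models are REML linear mixed models with a twin-pair random intercept
(`lme4`/`lmerTest`), Satterthwaite degrees of freedom, and 95% CIs from
$\hat\beta \pm t_{0.975,\,df}\,\mathrm{SE}$. Continuous variables (dv, iv,
continuous covariates) are z-scored within the analyzed rows *before*
fitting, so reported estimates are standardized effects per SD; binary
covariates (race/ethnicity, APOE-ε4) stay on their 0/1 coding, so their
coefficients are group contrasts in dv SD units — a documented convention,
since the original reporting does not state how binaries were scaled.

* **Cross-sectional**: `ef ~ mc_<network> + age + race + health + afqt_z
  + (1 | pair)`, per network per timepoint.
* **Longitudinal**: difference scores, Time 1 *minus* Time 2, for EF,
  controllability, age and health; race and AFQT enter undifferenced. The
  pair intercept is retained even though differencing removes
  subject-level intercepts — twins remain correlated; when the fitted
  pair variance is ~0 this costs nothing (the fit is flagged singular,
  not warned about).
* **Moderation**: the product of the standardized controllability term
  with the (standardized-if-continuous) moderator enters as an explicit
  `interaction` column, so the interaction estimate is on the
  product-of-standardized scale and is not re-standardized.

Numerical choices: listwise deletion per model with the analyzed n
reported; a boundary (singular) random-intercept fit is an expected
outcome and recorded as a flag; if the Satterthwaite computation fails,
residual df ($n - p$) are used with a warning; a cohort of singletons
(every subject its own pair) is accepted and collapses to OLS, which the
tests verify against both `lm` and a closed-form exchangeable GLS oracle.

Outliers: network-level controllability values beyond 3 SD of their
timepoint's mean are flagged (mean and SD computed with candidates
included) and the flagged subjects excluded before modeling; the
threshold is configurable and `outlier_sd = Inf` disables exclusion for
sensitivity re-runs. FDR control is Benjamini–Hochberg over *explicitly
declared* families; the default family is the four cross-sectional
network tests across the two timepoints, and the worked four-value
example from the motivating results is frozen in the tests.

## The synthetic cohort generator

The generator defines the study conditions; its defaults were fixed
before any acceptance measurement and are not tuning knobs.

**Connectomes.** A cohort-level node-propensity profile
$g_i \sim \mathrm{LogNormal}(0, 0.6)$ (jittered per subject with SD 0.2
on the log scale) sets strength heterogeneity; edges exist independently
with probability 0.3 and carry counts $1 + \mathrm{Poisson}(\mu_{ij})$
with $\mu_{ij} \propto p_i p_j$ scaled to a mean count of 20. This is a
stand-in for real streamline-count distributions, for which no public
reference exists; it reproduces the qualitative regularity the analysis
relies on — weakly connected nodes have high modal controllability
(strength–$\phi$ anticorrelation) — but not geometric, distance-dependent
or hemispheric structure of real connectomes, so passing tests say
nothing about those features. Time 2 matrices mix the Time 1 matrix with
a fresh draw from an *independent* cohort profile,
$W_2 = \mathrm{round}(s\,W_1 + (1-s)\,F)$ with default stability
$s = 0.95$, emulating the empirically observed high between-wave
stability of group topography; at $s = 0$ the two waves' topographies are
unrelated.

**Cohort.** 120 twin pairs + 20 singletons (260 subjects, the scale of
the larger cross-sectional wave), age $\sim N(61.75, 2.7^2)$ with a
5.7-year follow-up, APOE-ε4 prevalence 0.24, 87% white non-Hispanic,
AFQT percentiles generated as $100\,\Phi(N(0.36, 0.65^2))$ to match the
reported sample moments, and a Poisson(1) comorbidity count that worsens
with probability 0.3 by Time 2. Zygosity is not modeled: a single
pair-intercept variance (ICC 0.3) stands in for all within-pair
correlation, as the analysis models themselves assume.

**Phenotype.** Latent EF at Time 1 is
$\beta\,z(\text{mc}) + \gamma_h\,z(\text{health}) + \gamma_a\,z(\text{AFQT probit})
+ u_{\text{pair}} + \varepsilon$ with $\beta = 0.12$ (the scale of the
reported cross-sectional effect), $\gamma_h = -0.2$, $\gamma_a = 0.4$
(health and early cognitive ability are the reliably strong predictors in
this literature), and the residual variance closing the decomposition to
1. The Time 2 latent subtracts a decline with mean 0.3, between-person SD
0.5, and a standardized coupling of 0.3 to the subject's controllability
change. Controllability enters through the *realized* network means of
the generated matrices — the generator runs the actual controllability
code rather than injecting the predictor — so variance bookkeeping is
approximate by design and test tolerances reflect that. Six raw task
scores are emitted by inverting the scoring conventions (trails as times,
integer counts at realistic scales) from indicators with loadings
(0.8, 0.7, 0.6, 0.7, 0.5, 0.6).

**Determinism.** Every draw flows from the config seed through a
counter-based child-seed scheme (`derive_seed`), so any
(seed, subject, stream) triple is reproducible in isolation and the
global RNG state is left untouched.

**What passing means.** Because the EF factor score is an estimate, not
the latent variable, the fitted cross-sectional coefficient is attenuated
by the Thomson score validity (≈ 0.915 at the default loadings): the
expected estimate under $\beta = 0.12$ is ≈ 0.110. The recovery criterion
(mean estimate within ±0.02 of truth) was chosen with this attenuation in
mind, and it is the reason the moderation-recovery unit test regresses on
the latent EF directly — it isolates the model machinery from scoring
attenuation, which the acceptance suite characterizes separately.

## Problem sizes used by the test and acceptance runs

Simulation-based checks use 100-node connectomes and cohorts of 260
subjects (cross-sectional) or 105 subjects with both waves
(longitudinal); replicate counts are 400 for the null-calibration and
recovery suites and 15–60 elsewhere, with smaller replicate counts in
module-level tests that re-exercise the same machinery. `scripts/acceptance.R`
reports means over 40 cross-sectional, 20 longitudinal and 120 null
replicates. 400-node configurations are supported
(`sim_config(n_nodes = 400)`) and behave identically up to scale.

## Known limitations

* The factor loadings and practice-effect adjustments of the motivating
  study are not public; defaults here are reproducible but not identical
  to its pipeline.
* The edge model has no spatial embedding, no hemispheric symmetry, and
  no scanner or tractography artifacts; the exact-symmetry requirement on
  input matrices reflects streamline counting, and deviations beyond
  1e-8 are treated as data errors rather than silently symmetrized.
* Average controllability, control-energy trajectories, multi-node
  control sets, and ACE/biometric twin decompositions are out of scope.
* Whether the original analyses z-scored binary covariates, or z-scored
  AFQT against an external sample, is unstated; both choices here are
  documented above and configurable where they matter.
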