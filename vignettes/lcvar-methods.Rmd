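---
title: "Latent-class VAR for EMA data: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class VAR for EMA data: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ecological momentary assessment (EMA) studies prompt participants several
times a day — here six fixed "beeps" over fourteen days — to rate momentary
states (positive and negative affect, stress coping, hunger, food craving)
on 0–100 sliders. Individuals plausibly differ in *how* these states drive
each other over time: in some people craving may dampen calmness hours
later, in others the dynamics may run the other way or be absent. `lcvar`
clusters individuals by these lagged multivariate dynamics: it fits a
finite mixture of vector-autoregressive (VAR) models in which every
participant belongs to exactly one latent class, and all members of a class
share one set of dynamic coefficients.

# The model

For participant $i$ in class $k$, the $d$-vector of items at occasion $t$
follows

$$
y_{it} = B_k x_{it} + \sum_{l=1}^{p_k} A_{kl}\, y_{i,t-l} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim \mathcal N(0, \Sigma_k),
$$

where $x_{it}$ collects the exogenous covariates (an intercept plus
beep-of-day indicators by default), $A_{kl}$ are the lagged coefficient
matrices (diagonal entries: autoregressive inertia; off-diagonal entries:
cross-lagged effects), and $\Sigma_k$ is a class-specific innovation
covariance. Mixing proportions $\pi_k$ complete the mixture. The
likelihood is *conditional*: the first $p_k$ occasions per participant are
conditioned on rather than modeled, the standard choice for VAR maximum
likelihood. Each participant contributes the product of row densities over
their whole series, so class membership is decided by entire trajectories,
not single occasions.

Within a participant, occasions are chained in (day, beep) order with no
gap at day boundaries: each day's last beep is the lagged predictor of the
next day's first beep. This is a deliberate simplification — the overnight
interval is much longer than the 2.5 h between beeps — but it keeps every
within-day transition in the likelihood and matches how the analysis this
package operationalises treats its data; the alternative (dropping
cross-night rows) is easy to add but not implemented.

## Estimation

The EM algorithm alternates:

* **E-step** — posterior responsibilities
  $r_{ik} \propto \pi_k \exp(\ell_{ik})$, normalised per participant with a
  log-sum-exp so that log-likelihood differences up to $\pm 700$ cannot
  overflow. In well-separated data responsibilities saturate at 0/1; that
  is expected, not a numerical fault.
* **M-step** — responsibility-weighted multivariate least squares per class
  for $(A_k, B_k)$, the weighted residual covariance for $\Sigma_k$ (with a
  `1e-8` eigenvalue floor when near-singular), and $\pi_k$ as the mean
  responsibility.

Each EM start runs for at most 50 iterations or until the log-likelihood
changes by less than `1e-07`. When a class degenerates — expected
membership below the two-member minimum, a hard-label count below it, or a
non-invertible $\Sigma_k$ — every element of that class's $\Sigma_k$ is
increased by 10, the matrix is projected back to positive definiteness if
needed, the class's responsibilities are re-drawn uniformly, and EM
continues; the event is counted and the monotone-likelihood guarantee
restarts after it. At most ten resets are attempted per start.

## Starts

Mixture likelihoods are multimodal; the package therefore runs, per grid
cell:

* 15 **pseudo-random starts** (default): $K$ participants are drawn as
  centres, each centre's own ridge-stabilised VAR is fitted, and everyone
  is assigned to the centre that likes them best (one-hot softened by
  `1e-3`);
* one **rational start**: $k$-means (10 restarts) on the per-participant
  VAR-plus-covariate coefficient vectors;
* a **warm start** from the best previous fit with the same $K$.

The best valid converged fit per cell is kept. The test suite demonstrates
why multiple starts matter: a single badly drawn pair of centres can leave
EM in a local optimum that mixes two true classes.

## Model selection

Cells cover $K \in [2, 3]$ and lag $p \in [1, 3]$ by default (configurable;
heterogeneous non-decreasing per-class lag vectors optionally). Each cell
is scored by

$$
\mathrm{HQC} = \frac{-2\,\hat\ell + 2\,q \ln \ln N}{N}, \qquad
\mathrm{AIC} = \frac{-2\,\hat\ell + 2\,q}{N},
$$

with $q = \sum_k \left[d^2 p_k + d\,q_x + d(d+1)/2\right] + (K-1)$ free
parameters and $N$ the number of modeled outcome rows. Lower is better;
ties break toward fewer parameters, then smaller $K$, then lower lag. The
absolute scale of these criteria depends on the normalisation convention,
which differs between software implementations; only the *ranking* of
cells is meaningful, and only the ranking is asserted anywhere in this
package. When classes have unequal lags, all classes are conditioned on
the same $\max_k p_k$ initial occasions so that per-participant
likelihoods compare over identical rows.

# Preparation choices

* **Compliance** is all-or-nothing per prompt: a prompt with any missing
  item counts as not completed, because the measurement app expired whole
  questionnaires. The inclusion rule keeps participants with at least 50
  completed prompts of the scheduled 84 (60%). Item-level partial
  missingness remains representable and is imputed.
* **Scaling**: items are z-scored pooled across the sample before fitting
  (so coefficients read as standardized effects); this is configurable
  off. Scaling is a free choice here — it changes coefficient units, not
  the clustering, since it is an affine per-variable transformation shared
  by all classes.
* **Time of day** enters as categorical beep indicators (reference = first
  beep) rather than continuous clock time, because per-beep means are the
  descriptive target; continuous coding is available as an option.

# Imputation

`impute_chained()` is a single-imputation chained-equations routine for
continuous items: missing cells are initialised at variable means, then
each incomplete variable is regressed on all others and its missing cells
are redrawn from the Bayesian predictive distribution (posterior draws of
coefficients and residual variance, then a noise draw), for 500 sweeps by
default. Predictive-mean matching is available as an option. Observed
cells are never altered; imputed values are clamped to the 0–100 scale.

The chains pool occasions **across participants** with no person-level
effects and no temporal terms — the simplest faithful reading of a single
cross-sectional imputation model. This has a real cost for dynamic
analyses: an imputed occasion carries cross-sectional but no lagged
information, so every imputed cell attenuates lagged coefficients in the
rows where it appears (once as outcome, once as predictor). With ~10%
item-level missingness this attenuation measurably narrows the
information-criterion margin between competing $K$; the integration test
documents this behaviour rather than hiding it. Imputation quality should
therefore be judged on marginal summaries (the test suite checks
per-variable means move by less than half a slider point under 10% MCAR),
not on dynamic recovery.

# The synthetic generator

The study's raw data are not publicly deposited, so the package carries a
first-class generator that emulates the data-generating features the
analysis depends on:

* the 6-beeps × 14-days schedule with fixed clock times;
* class-specific stable VAR dynamics (companion spectral radius capped
  below 1, enforced by rescaling with an explicit failure if the cap
  cannot be met);
* beep-specific diurnal mean profiles, including the two-peak "M-curve"
  (mid-morning and late-afternoon highs) for hunger/craving-like items;
* item-level MCAR missingness (a beep-dependent MAR variant and a
  whole-prompt dropout rule are available);
* a trait table with class-specific means and gender mixes for the
  characterisation stage.

Mechanics worth knowing: series are generated as deviations around the
diurnal profile, with a 50-step burn-in so recording starts near
stationarity; values are clamped to [0, 100], a mild nonlinearity absent
from the VAR model — default innovation SD (5 points around a mid-scale
profile) keeps clamping below 1% of values so recovery tests are not
distorted; class assignment is resampled (boundedly) until every class has
at least two members, mirroring the estimation-side minimum.

What the generator does **not** emulate: non-Gaussian slider distributions
(floor/ceiling spikes), within-day nesting or random effects,
time-varying dynamics, and missingness tied to state values (MNAR).
Passing recovery tests on this generator therefore shows the estimator is
correct and well-conditioned under its own model class — not that real
EMA data satisfy that model.

The temporal-shuffle null (`shuffle_null()`) permutes each participant's
observations within variable, preserving all marginals while destroying
lagged structure; fitted lag coefficients on shuffled panels collapse
toward zero (mean absolute value below 0.05 in the test conditions),
which is the package's randomised-data control.

## Study conditions used in the verification suites

The recovery suite uses $K=3$, $d=4$, $p=1$, $n=60$ participants, $T=84$
occasions — the schedule's natural length — with classes differing in two
designated cross-lagged entries, $(2,1)$ and $(4,3)$ at lag 1, at effects
$+0.5 / 0 / -0.5$ (adjacent separation 0.5), innovation SD 5, no
missingness, over 5 seeds. Two entries rather than one is the package's
reading of "cross-lagged entries" separated by 0.5: with a single entry
the maximum-likelihood solution itself (verified by truth-initialised EM)
leaves several participants genuinely ambiguous and the criterion margin
between $K=2$ and $K=3$ is within noise, so the condition would test data
ambiguity rather than estimator correctness. The null suite uses $n=50$,
$T=84$, 3 seeds. Verification runs use 4 pseudo-random starts plus the
rational start per cell — a runtime choice; more starts can only improve
the found optimum. The package default remains 15.

# Numerical choices

* All densities and mixture weights are handled in log space;
  responsibilities via log-sum-exp.
* Weighted least squares adds `1e-10` to the normal-equation diagonal;
  per-participant VARs used by start strategies use a relative `1e-6`
  ridge (they may be rank-deficient at higher lags).
* Covariance floors: `1e-8` eigenvalue floor in the M-step; PD projection
  after a reset flattens negative eigenvalues at `1e-6`.
* Hard labels are the responsibility argmax, ties toward the lowest class
  index. Lag vectors are canonicalised ascending so label permutations
  cannot duplicate grid cells.
* Every stochastic component draws its own sub-seed from one master seed
  through a fixed integer recurrence, so stages and grid cells are
  independently reproducible; all derived seeds stay below $2^{31}$.
* The exact Fisher test enumerates all margin-consistent tables via
  log-factorial accumulation and uses the probability-ordering two-sided
  rule (sum of probabilities of all tables no more probable than the
  observed one, with the customary `1e-7` tie tolerance) — the convention
  of the software family this analysis style uses. Two-sided definitions
  for $r \times c$ tables vary; this one is stated explicitly because the
  choice moves third-decimal p-values.

# Characterisation stage

Between-class trait differences use one-way ANOVAs with generalised
eta-squared ($\eta^2_g = SS_{num}/(SS_{num}+SS_{den})$, which in a one-way
design equals plain eta-squared), Tukey HSD contrasts on the studentized
range (Tukey–Kramer for unequal sizes, $\Delta_{(b-a)}$ sign convention),
Pearson chi-squared for balanced categorical tables, and the exact Fisher
test for sparse ones (gender). Participants with missing trait data are
dropped listwise per test. No multiplicity correction is applied by
default, matching the descriptive presentation style this package
supports; `p_adjust_method` turns it on.

# Known limitations

* Within-day nesting (beeps in days in persons) is not modeled; the
  day-boundary chaining treats the overnight gap like any other lag step.
* The imputation model ignores persons and time (see above).
* No standard errors or inference on the VAR coefficients are provided;
  the method is descriptive-exploratory at the coefficient level.
* Information-criterion values are comparable only within one run of this
  package, not across implementations with other normalisations.
* The mixture assumes Gaussian innovations on a bounded slider scale;
  clamping makes this approximate, mildly but by construction.
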