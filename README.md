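# lcvar — latent-class vector autoregression for EMA data

People differ not only in *how much* affect, stress, hunger and craving
they report, but in *how these states drive each other over time*.
Ecological momentary assessment (EMA) studies — here six smartphone
prompts a day over fourteen days, fourteen 0–100 slider items — produce
exactly the intensive longitudinal data needed to see those dynamics, but
a single pooled time-series model hides the heterogeneity. `lcvar`
addresses this for applied researchers in affect and eating-behaviour
science: it clusters individuals by their lagged multivariate dynamics,
so that subgroups with, say, positive, absent, or negative cross-lagged
appetite–affect coupling fall into separate latent classes.

## The model

Participant $i$ in latent class $k$ follows a VAR($p_k$) with exogenous
time-of-day covariates:

$$
y_{it} = B_k x_{it} + \sum_{l=1}^{p_k} A_{kl}\, y_{i,t-l} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim \mathcal N(0, \Sigma_k),
$$

estimated as a finite mixture by EM: posterior class responsibilities in
the E-step (log-sum-exp safe), responsibility-weighted least squares,
covariances and mixing proportions in the M-step. Each day's last beep is
the lagged predictor of the next day's first beep. Degenerate classes are
rescued by adding 10 to every element of $\Sigma_k$ and re-randomising
their responsibilities. Multiple starts (15 pseudo-random, one k-means
"rational", warm starts) guard against local optima, and the
cluster-count × lag grid is ranked by the Hannan–Quinn criterion
(lower = better). Around the core sit the standard stages of this kind of
analysis: compliance filtering (≥ 50 of 84 completed prompts),
chained-equations single imputation, pooled z-scoring, per-cluster
daytime-course means and coefficient heatmap matrices, and between-cluster
trait tests (one-way ANOVA with generalised $\eta^2$, Tukey HSD, Pearson
chi-squared, exact $r \times c$ Fisher).

A synthetic EMA generator with known cluster structure (stable VAR
dynamics, M-shaped diurnal appetite profiles, configurable missingness,
cluster-linked traits) makes every stage testable end to end; a
temporal-shuffle null panel provides the randomised-data control.

## Worked example

Simulate three clusters of 60 participants (4 items, 14 days × 6 beeps)
whose dynamics differ in two cross-lagged effects (+0.5 / 0 / −0.5), fit
the full grid, and inspect the selection:

```r
library(lcvar)
models <- lapply(1:3, function(k)
  make_var_params(4, 1, cross_effect = c(0.5, 0, -0.5)[k], seed = k,
                  cross_entries = rbind(c(2, 1, 1), c(4, 3, 1))))
spec <- simulation_spec(60, models, c(0.4, 0.35, 0.25),
                        missing_rate = 0, seed = 1)
sp <- simulate_panel(spec)
grid <- fit_grid(sp$panel,
                 fit_config(k_min = 2, k_max = 3, lag_min = 1, lag_max = 2,
                            n_pseudo_random_starts = 4, seed = 2))
grid
#> LCVAR grid (ranked by HQC):
#>     cell K  lags    loglik n_params      hqc converged n_resets
#>  K3_p111 3 1,1,1 -60368.08      152 24.37494      TRUE        0
#>  K3_p222 3 2,2,2 -59635.03      200 24.41588      TRUE        0
#>   K2_p11 2   1,1 -60592.03      101 24.42102      TRUE        0
#>   K2_p22 2   2,2 -59869.10      133 24.45274      TRUE        0
#> selected: K3_p111
```

The criterion picks the true structure (three clusters, lag 1; the
penalty rejects the over-lagged cells despite their higher likelihood),
and the partition matches the simulated truth exactly up to label
switching:

```r
table(truth = sp$truth$labels,
      fitted = grid$selected$hard_labels[names(sp$truth$labels)])
#>      fitted
#> truth  1  2  3
#>     1  0 22  0
#>     2 24  0  0
#>     3  0  0 14
```

Fitted cluster 2 is the "+0.5" class; its lag matrix recovers the
designated cross-lagged entries (rows = outcome, columns = predictor;
true values 0.50 at (2,1) and (4,3), autoregressive diagonal ≈ 0.25–0.38):

```r
round(grid$selected$clusters[[2]]$A[[1]], 2)
#>        item_1_lag1 item_2_lag1 item_3_lag1 item_4_lag1
#> item_1        0.27       -0.02        0.00       -0.01
#> item_2        0.53        0.27       -0.04        0.02
#> item_3        0.01        0.01        0.32       -0.01
#> item_4       -0.01        0.00        0.50        0.39
```

The characterisation helpers work directly on printed-count tables too;
the exact Fisher test of a sparse 3 × 2 gender-by-cluster table:

```r
fisher_exact_rxc(rbind(c(41, 12), c(34, 1), c(20, 6)))
#> [1] 0.0194142
```

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study on synthetic
data and write all tables under `results/analysis/`:

| script | stage |
|---|---|
| `01_simulate.R` | three-cluster EMA panel, ground truth, trait table |
| `02_prepare.R`  | compliance, the 50-of-84 filter, scaling record |
| `03_impute.R`   | 500-sweep chained-equations single imputation |
| `04_fit.R`      | grid fit (15 starts/cell), HQC selection, membership, coefficients |
| `05_profiles.R` | daytime-course means, heatmap matrices, figure |
| `06_characterize.R` | trait ANOVAs, Tukey contrasts, gender Fisher test |
| `07_null_control.R` | temporal-shuffle null refit |

Run them in order with `Rscript analysis/01_simulate.R` etc.; each prints
a one-line summary of what it found. `run_pipeline()` offers the same
chain as a single call driven by one YAML config with per-stage derived
seeds and a reproducibility manifest.

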