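---
title: "Methods: a biomarker hazard-profile atlas of disease space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a biomarker hazard-profile atlas of disease space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazardatlas)
```

## Overview

`hazardatlas` asks whether diseases that share a prognostic biomarker
signature also co-occur in health records. The pipeline has five stages:

1. **Hazard models** — for every disease, an ensemble of L2-penalized Cox
   proportional-hazards models over a penalty grid, combined with weights
   proportional to each model's held-out concordance index, yielding one
   weighted hazard ratio per biomarker per disease.
2. **Similarity space** — Pearson correlations between the diseases'
   log-hazard-ratio profiles, a permutation null for those correlations, and
   a sparse partial-correlation network from a cross-validated graphical
   lasso.
3. **Cluster atlas** — UMAP projection of the profiles to 2D followed by
   DBSCAN, with both stages' hyper-parameters grid-searched under the
   silhouette coefficient.
4. **Comorbidity** — per-disease lasso-penalized logistic regressions on
   binary co-occurrence records, giving a directed disease–disease
   association matrix, plus cross-cohort concordance summaries.
5. **Cluster validation** — the true match rate (TMR) of cluster labels
   against comorbid pairs as a function of the association threshold, its
   trapezoidal AUC, and a validation score against a permuted-matrix
   baseline.

Because the package is developed against synthetic data, a seeded generator
(`simulate_cohort()`, `simulate_ehr()`) plants known archetype structure so
every stage can be checked against ground truth.

## Survival model

For disease $d$ with onset time $T_d$, the hazard for subject $i$ is modeled
as

$$ h_d(t \mid x_i) = h_{0,d}(t)\,
   \exp\!\big( f_d(\mathrm{age}_i) + \gamma_d' z_i + \beta_d' b_i \big), $$

where $f_d$ is a degree-4 B-spline in age (interior knots at the training-age
quintiles, boundary knots spanning the full cohort so test-split ages never
leave the basis support), $z_i$ are the fixed covariates (sex, deprivation,
BMI, smoking, systolic blood pressure) and $b_i$ the biomarkers, z-scaled
with means and standard deviations estimated on the training split only.
Before fitting, biomarkers are pruned greedily in column order so that no
retained pair has $|r| \ge 0.7$.

Each disease is fit once per penalty $\lambda$ in a grid (default: 20 evenly
spaced values in $[0.01, 0.2]$) by ridge-penalized partial likelihood
(`glmnet`, $\alpha = 0$), on a 70/30 split stratified by event status. Each
model is scored by Harrell's C-index $c_\lambda$ on the held-out 30%, and
the ensemble coefficient is the weighted average on the log scale,

$$ W_\lambda = \frac{c_\lambda}{\sum_{\mu} c_\mu}, \qquad
   \mathrm{HR}_{d,j} = \exp\!\Big( \sum_\lambda W_\lambda\,
   \beta_{d,j}^{(\lambda)} \Big), $$

so hazard ratios remain positive and the weights sum to one exactly.
Diseases with fewer than `incidence_threshold` cases (default 100) are
excluded.

## Similarity and network

Disease similarity is the Pearson correlation between rows of the
diseases × biomarkers log-HR matrix. The permutation null shuffles entries
*within each row* — each disease keeps its distribution of effect sizes but
loses biomarker identity — and reports the tail probability
$P(r_{\text{perm}} > \text{cutoff})$. Its confidence interval is a
t-interval over the per-permutation exceedance fractions: correlations from
one permuted matrix share rows and are dependent, so a binomial interval
over all pairs would be too narrow.

The network treats diseases as variables and the biomarker dimensions as
observations. A graphical lasso (blockwise coordinate descent on the
penalized Gaussian log-likelihood) estimates a sparse precision matrix; the
penalty is chosen by K-fold cross-validation over biomarker dimensions on
held-out log-likelihood. Edges are partial correlations exceeding 0.1 in
magnitude.

## Clustering and noise handling

`grid_search_clustering()` scores the full Cartesian product of UMAP
(`n_neighbors`, `min_dist`) and DBSCAN (`eps`, `min_samples`) parameters by
the silhouette coefficient of the resulting labels on the 2D embedding, with
ties broken by higher Calinski–Harabasz, then lower Davies–Bouldin, then
grid order. Grid points with fewer than two clusters score $-\infty$.

One design choice deserves emphasis. If DBSCAN noise points are simply
*excluded* before computing the silhouette, the search is drawn to degenerate
optima: labeling almost all diseases as noise while keeping two tiny, tight
clusters produces a near-perfect silhouette on the survivors. On synthetic
data with four planted archetypes this "optimum" discarded 36 of 40 diseases
(silhouette 0.997, adjusted Rand index 0.008 against truth). The default
therefore scores noise points as **one additional group**
(`cluster_quality(..., noise = "own_cluster")`), the same convention as
applying a standard silhouette to raw DBSCAN labels; scattered noise then
penalizes the score and the same search recovers the planted archetypes
exactly. The exclusion behavior remains available via `noise = "exclude"`.

## Comorbidity models

For binary co-occurrence records, each disease $k$ gets a lasso-penalized
logistic regression on all other disease indicators:

$$ \operatorname{logit} P(y_{k,i} = 1) = \alpha_k + \textstyle\sum_{j \ne k}
   \theta_{kj}\, y_{j,i}, $$

with the penalty chosen by cross-validated deviance at `lambda.min` —
deliberately the less conservative choice, since downstream threshold curves
need weak associations to survive; a pair with coefficient $\ge 0.1$
(odds ratio > 1.1) counts as comorbid. The matrix is directed
($\theta_{kj} \ne \theta_{jk}$ in general); pair-level statements use the
maximum of the two directions.

## Validation statistic

For an association threshold $\tau$, the **true match rate** is

$$ \mathrm{TMR}(\tau) = \frac{\#\{\text{pairs with association} > \tau
   \text{ in the same cluster}\}}{\#\{\text{pairs with association} >
   \tau\}}, $$

evaluated by default on the grid of unique positive association values (the
exact jump points of the step function). The AUC is the trapezoidal integral
of TMR over $\tau$, unnormalized. The random baseline permutes the hazard
submatrix within rows, re-embeds and re-clusters with the *already chosen*
UMAP/DBSCAN parameters, and recomputes the AUC; the **validation score** is
actual AUC divided by mean baseline AUC. Scores above 1 indicate that
biomarker clusters are enriched for comorbid pairs beyond chance.
Noise-labeled diseases are excluded from the pair universe by default
(`include_noise = TRUE` keeps them as automatic non-matches).

## Synthetic data generator

The generator's defaults are the package's study conditions:

- **Biomarkers** (`generate_biomarkers`): blocks of equicorrelated standard
  normals (default 4 blocks, within-block $r = 0.3$).
- **Archetypes** (`archetype_spec`, `generate_disease_effects`): each of the
  $K$ archetypes is a sparse coefficient vector (entries
  $\mathcal{N}(0, \text{effect\_scale}^2)$, a `sparsity` fraction zeroed);
  each disease is its archetype's vector plus
  $\mathcal{N}(0, \text{noise}^2)$ perturbation. Archetype membership is the
  ground-truth clustering.
- **Survival** (`simulate_survival`): exponential onset with rate
  $h_0 \exp(x_i'\beta_d + \text{offset}_i)$ (default $h_0 = 0.01$/year),
  administratively censored at a 12-year horizon.
- **Covariates**: age $\sim U(40, 70)$ years, sex Bernoulli(0.5),
  deprivation $\mathcal{N}(0, 3)$, BMI $\mathcal{N}(27, 4)$ kg/m², smoking
  Bernoulli(0.45), systolic blood pressure $\mathcal{N}(138, 18)$ mmHg, with
  modest default log-hazard contributions.
- **Co-occurrence** (`simulate_ehr`): within each true cluster, a latent
  binary susceptibility (default fraction $q = 0.25$) shifts every member
  disease's prevalence between two points chosen by root-finding so the
  marginal same-cluster odds ratio equals `within_cluster_or` exactly while
  the marginal prevalence stays at `base_prevalence`; diseases in different
  clusters are independent. The equal-prevalence two-point mixture caps the
  attainable odds ratio, which is why $q$ is a parameter: at
  `base_prevalence = 0.15`, $q = 0.25$ supports odds ratios well beyond the
  default 4.

What the generator emulates: planted, recoverable structure linking biomarker
risk profiles to co-occurrence. What it does not emulate: real-world
registry features such as competing risks, informative censoring, diagnosis
coding noise, or survey sampling weights.

## Numerical choices and problem sizes

- `glmnet` is called with `standardize = FALSE` (biomarkers are already
  z-scaled on the training split) and a tight convergence threshold
  (`thresh = 1e-10`) so the per-penalty coefficients are stable test oracles.
- The graphical lasso is solved to a tolerance scaled by the mean absolute
  off-diagonal covariance; non-positive-definite iterates are retried on a
  damped (diagonal-inflated) covariance.
- UMAP runs single-threaded (`n_threads = 1`, `n_sgd_threads = 0`) under a
  set seed, making embeddings bit-reproducible.
- Development-scale runs use 24–40 diseases, 10–16 biomarkers and cohorts of
  2,000–20,000 subjects; a full pipeline run at those sizes takes on the
  order of 10–20 seconds on one CPU.

## Limitations

- The concordance index is computed by an $O(n \cdot \text{events})$
  vectorized sweep — fine at these cohort sizes, not tuned for millions of
  subjects.
- The exponential baseline hazard is constant in time; age enters only
  through the linear predictor.
- The validation score is a ratio of means with a replicate spread, not a
  calibrated hypothesis test.
- Under independence-generated co-occurrence the lasso may return no
  positive associations, in which case the TMR curve — and hence the score —
  is undefined; callers should treat that outcome as "no evidence", not as a
  score of zero.
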