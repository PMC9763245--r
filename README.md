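# hazardatlas

Builds a disease atlas from prognostic biomarker survival models and asks
whether diseases with similar biomarker hazard profiles also co-occur in
health records.

For every disease, an ensemble of L2-penalized Cox proportional-hazards
models (one per penalty in a grid, combined with weights proportional to each
model's held-out concordance index) yields a weighted hazard ratio per
biomarker. Diseases then become points in "biomarker risk space": the package
computes profile correlations with a permutation null, a cross-validated
graphical-lasso partial-correlation network, a grid-searched UMAP + DBSCAN
cluster atlas, lasso-logistic comorbidity associations from binary
co-occurrence records, and a cluster validation score — the area under the
true-match-rate curve relative to a permuted-matrix baseline.

Real cohort data of this kind is access-controlled, so the package ships a
seeded synthetic generator with planted archetype structure; every stage is
testable against ground truth. See the methods vignette
(`vignettes/disease-atlas-methods.Rmd`) for the model, the design decisions
and the generator's assumptions.

## Core model

For disease *d*, subject *i* with age spline *f_d*, fixed covariates *z* and
z-scaled biomarkers *b*:

```
h_d(t | x_i) = h_0d(t) · exp( f_d(age_i) + γ_d' z_i + β_d' b_i )
```

Per penalty λ the ridge Cox fit gives β^(λ) and a held-out C-index c_λ; the
ensemble hazard ratio per biomarker *j* is

```
W_λ = c_λ / Σ_μ c_μ          HR_dj = exp( Σ_λ W_λ β_dj^(λ) )
```

The validation statistic compares cluster labels to comorbidity: among
disease pairs with association > τ, TMR(τ) is the fraction in the same
cluster; the score is the trapezoidal AUC of TMR over τ divided by the mean
AUC under within-row permutations of the hazard matrix.

## Worked example

```r
library(hazardatlas)

# 4 archetypes, 24 diseases, 16 biomarkers, 4000 subjects, 12-year horizon
spec <- archetype_spec(n_archetypes = 4, n_diseases = 24, n_biomarkers = 16,
                       effect_scale = 0.4, within_archetype_noise = 0.05,
                       sparsity = 0)
cohort <- simulate_cohort(4000, spec, baseline_rate = 0.02, seed = 1)

# one Cox ensemble per disease -> weighted hazard-ratio matrix
hazards <- build_hazard_matrix(
  cohort, model_design(penalty_grid = c(0.02, 0.05, 0.1, 0.2), seed = 1),
  incidence_threshold = 50)
print(hazards)

# similarity space: correlations, permutation null, partial-correlation network
sim <- similarity_analysis(hazards, n_permutations = 200, seed = 2)
print(sim)

# cluster atlas: grid-searched UMAP + DBSCAN on the log-HR submatrix
sub <- biomarker_submatrix(hazards)
atlas <- grid_search_clustering(
  sub, umap_grid = list(n_neighbors = c(5, 10), min_dist = c(0, 0.1)),
  dbscan_grid = list(eps = seq(0.1, 1, 0.1), min_samples = c(2, 3, 5)),
  seed = 3)
print(atlas)

# co-occurrence records aligned to the true clusters, association matrix
ehr <- simulate_ehr(cohort$truth$cluster, 3000, base_prevalence = 0.15,
                    within_cluster_or = 4, seed = 4)
assoc <- association_matrix(ehr, cv_folds = 5, seed = 4)
print(assoc)

# validation: TMR curve AUC vs permuted-matrix baseline
report <- validate_clusters(sub, assoc, atlas, n_replicates = 5, seed = 5)
print(report)
```

Output of the `print()` calls:

```
Hazard matrix: 24 diseases x 29 covariates ( 13 fixed ), mean C-index 0.81
Similarity over 24 diseases x 16 biomarkers; P(permuted r > 0.25 ) = 0.174 ; 49 network edges
UMAP+DBSCAN atlas: 4 clusters over 24 diseases ( 0 noise ); silhouette 0.965
Comorbidity associations: 24 diseases, 202 nonzero directed coefficients
Cluster validation: actual AUC 1.025 vs baseline 0.1746 +/- 0.0553 -> validation score 5.875
```

The search recovers the four planted archetypes exactly
(`mclust::adjustedRandIndex(atlas$labels, cohort$truth$cluster)` is 1), and
cluster-aligned co-occurrence produces a validation score well above 1.

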