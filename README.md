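# crossmet

Cross-platform metabolomics imputation with importance-weighted
autoencoders.

## The problem

Epidemiological cohorts measure metabolomes on different platforms
(e.g. a targeted commercial panel such as Metabolon vs an untargeted
LC-MS feature panel), which blocks pooling, replication and
meta-analysis across studies. When a subset of samples has been
measured on *both* platforms, one platform's panel can be treated as
missing data in the other and reconstructed: metabolites are highly
inter-correlated, so a deep latent-variable model trained on the
paired subset can impute an entire absent panel for samples measured
on only one platform.

`crossmet` is for analysts who have two sample-aligned feature
matrices (samples × features) and want (i) an imputed target panel for
new cohorts, (ii) honest per-metabolite quality and uncertainty
estimates, and (iii) a downstream check that imputed data reproduce
real metabolite–outcome associations.

## The method

1. **QC** — features that are invariant or more than 25% missing are
   removed (`filter_features()`); outlier samples are removed by local
   outlier factor with default settings (`detect_outlier_samples()`);
   samples are split 70/10/20 into train/validation/test
   (`split_samples()`); features are min–max scaled to [−1, 1] using
   training-set statistics only (`fit_scaler()`).
2. **Feature clustering** — all features of both platforms are
   embedded jointly into 2-D under a cosine-distance neighbourhood
   geometry and k-means-clustered, with k chosen by silhouette with an
   elbow tie-break; clusters are named by their predominant compound
   class, falling back to "Others" (`cluster_features()`).
3. **IWAE ensemble** — an incomplete-data importance-weighted
   autoencoder is trained per cluster plus once on all features
   (`train_iwae()`, `train_ensemble()`). The training objective is the
   K-sample importance-weighted bound

   L_K = E[ log (1/K) Σₖ p(x_vis | z_k) p(z_k) / q(z_k | x) ],

   with the decoder likelihood evaluated only on the loss-target
   entries; artificial masking mixes uniform value masking with
   whole-target-column masking so the model learns the deployment
   condition (an entirely absent panel). Mix-up, dropout, batch
   normalisation and the error function are tunable grid axes
   (`iwae_grid_search()`).
4. **Greedy selection and multiple imputation** — for every target
   metabolite the best model by validation performance is chosen
   (`greedy_select()`); the test set is imputed over 51 stochastic
   cycles (`impute_dataset()`): cycle 1 gives the baseline R²
   (squared Pearson correlation of imputed vs observed), cycles 2–51
   give the mean R² and the **R² variance**, the uncertainty measure
   (`evaluate_imputation()`). The well-imputed subset is
   R² ≥ 0.55 with R² variance ≤ 0.025 (`select_well_imputed()`).
5. **Association concordance** — standardised metabolite–outcome
   associations adjusted for age and sex are fitted on real and
   imputed data (`fit_association()`, `run_association_panel()`) and
   compared by Spearman ρ of the paired betas plus Bland–Altman limits
   of agreement at mean ± 1.96 SD (`concordance()`,
   `match_external_panel()`).

A synthetic two-platform cohort generator with known latent structure
(`generate_cohort()`, `inject_missing_and_outliers()`) makes the whole
pipeline testable without any external data: compound classes are
block-correlated factors, the cross-platform loading λ controls how
much of a target feature's variance is recoverable from the input
platform, and outcomes are linear in the class factors.

## Worked example

```r
library(crossmet)
cfg <- cohort_config(n_samples = 450, n_classes = 3,
                     n_input_per_class = 20, n_target_per_class = 12,
                     cross_platform_loading = c(0.9, 0.7, 0.3),
                     noise_sd = 0.2, seed = 61)
cohort <- generate_cohort(cfg)
split  <- split_samples(cohort$input_matrix$sample_ids, seed = 61)
panel  <- platform_matrix(cbind(cohort$input_matrix$values,
                                cohort$target_matrix$values))
scaler <- fit_scaler(panel, train_ids = split$train_ids)
scaled <- scaler_transform(panel, scaler)$values

clusters <- cluster_features(cohort$input_matrix, cohort$target_matrix,
                             cohort$feature_metadata,
                             embedding_params(seed = 61),
                             sample_ids = c(split$train_ids, split$val_ids),
                             k_range = 2:6)
ens <- train_ensemble(scaled[split$train_ids, ], scaled[split$val_ids, ],
                      cohort$target_matrix$feature_ids, clusters,
                      iwae_config(latent_dim = 4, hidden = c(32, 16),
                                  K = 3, L = 30, value_mask_rate = 0.2,
                                  target_mask_rate = 0.5, max_epochs = 120,
                                  patience = 12, val_L = 10, seed = 61))
sel <- greedy_select(validation_metrics(ens, scaled[split$val_ids, ],
                                        metric = "r2", seed = 2))
cycles <- impute_dataset(ens, sel, scaled[split$test_ids, ],
                         n_cycles = 51, seed = 3)
ev <- evaluate_imputation(cycles, scaled[split$test_ids,
                                         colnames(cycles[[1]])])
well <- select_well_imputed(ev, cohort$feature_metadata)
```

Output printed by the objects above:

```
synthetic_cohort: 450 samples; 60 input + 36 target features; 3 classes
sample_split: 315 train / 45 val / 90 test (seed 61)
cluster_assignment: 96 features in 3 clusters
  Fatty acids          32
  Phospholipids        32
  Sphingolipids        32
ensemble_model: 4 models (Fatty acids, Sphingolipids, Phospholipids, all)
greedy selection: 32/36 metabolites use a cluster model
imputation_evaluation: 36 metabolites, 51 cycles
  baseline R2 mean 0.430; R2 variance mean 0.0001; sample rho mean 0.599
well-imputed (R2 >= 0.55, variance <= 0.025): 12 metabolites, 2 unique to target platform
         class  n n_selected   mean_r2      sd_r2
   Fatty acids 12         12 0.7554228 0.02357953
 Sphingolipids 12          0 0.4026869 0.05984561
 Phospholipids 12          0 0.1333591 0.03576596
```

Reading it: the three planted classes carry cross-platform loadings
0.9 / 0.7 / 0.3, so their recoverable variance is ~λ². The pipeline
finds the three clusters, the per-class mean baseline R²
(0.76 / 0.40 / 0.13) tracks λ² (0.81 / 0.49 / 0.09), only the
high-loading class clears the R² ≥ 0.55 quality gate, and the mean
per-sample Spearman ρ between imputed and real profiles is 0.60.

## Documentation

The methods vignette (`vignettes/crossmet-methods.Rmd`) describes the
model, its assumptions, the synthetic world the tests rely on, the
numerical choices, and known limitations.
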