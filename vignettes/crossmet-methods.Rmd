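---
title: "crossmet: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossmet: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what is
modelled, what is assumed, which knobs matter, what the synthetic
world does and does not establish, and where genuinely open design
choices were resolved. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The imputation model

Let $x \in \mathbb{R}^D$ collect one sample's features from both
platforms, scaled to $[-1, 1]$, with an observation mask $o$. The
generative model is a deep latent-variable model
$p_\theta(x, z) = p(z)\, p_\theta(x \mid z)$ with a standard normal
prior over $z \in \mathbb{R}^h$ and a decoder whose likelihood
factorises over entries. Training maximises the $K$-sample
importance-weighted bound

$$
\mathcal{L}_K \;=\;
\mathbb{E}_{z_{1:K} \sim q_\phi(z \mid x_{in})}
\log \frac{1}{K} \sum_{k=1}^{K}
\frac{p_\theta(x_{vis} \mid z_k)\, p(z_k)}{q_\phi(z_k \mid x_{in})},
$$

which is tighter than the usual variational bound and non-decreasing
in $K$; at $K = 1$ it reduces exactly to the ELBO (both facts are
asserted numerically in the test suite). The encoder sees the
zero-filled visible values concatenated with the visibility mask
(input width $2D$) — the standard convention for autoencoders on
incomplete data.

Two variants differ only in which entries enter the decoder
likelihood: the missing-data variant (`"miwae"`, default) uses all
truly observed entries, so artificially hidden entries remain loss
targets; the denoising variant (`"denoising"`) scores only the
artificially hidden entries. Truly missing entries never contribute
to the loss in either variant.

**Masking during training.** Each batch hides `value_mask_rate` of
its observed entries uniformly at random and, with probability
`target_mask_rate`, every target-platform column. The column masking
is what teaches the network its deployment condition — imputing an
entire absent panel — while the value masking regularises the
representation.

**Imputation.** One *imputation cycle* draws $L$ samples
$z_l \sim q_\phi(z \mid x_{in})$, forms self-normalised importance
weights $w_l \propto p_\theta(x_{vis} \mid z_l) p(z_l) /
q_\phi(z_l \mid x_{in})$ (normalised in log space) and returns
$\sum_l w_l\, \mathbb{E}[x \mid z_l]$ at hidden entries; observed
entries pass through unchanged. This is a self-normalised
importance-sampling estimate of $\mathbb{E}[x_{miss} \mid x_{obs}]$;
it is stochastic across cycles, which is exactly what the
uncertainty measure consumes.

## 2. Parameters that matter

| parameter | default | why |
|---|---|---|
| `latent_dim` | 8 | enough for a handful of correlated factor blocks; scale with panel size |
| `hidden` | (64, 32) | capped at 3 layers — small cohorts (hundreds of samples) overfit quickly |
| `K` (training) | 5 | bound tightness vs cost; gains beyond ~10 are marginal at this scale |
| `L` (imputation) | 50 | self-normalised IS variance shrinks with L; 50 matches the reference protocol |
| `value_mask_rate` | 0.3 | in [0, 1); grid axis {0.1, 0.3, 0.5} |
| `target_mask_rate` | 0.5 | in [0, 1]; grid axis {0.25, 0.5, 1.0} (1.0 = mask the panel every batch) |
| `loss` | gaussian | Gaussian NLL with learned per-feature variance; `mse`/`mae` are fixed-scale surrogates implementing the "error function" grid axis |
| `learning_rate` | 5e-3 | Adam; chosen on the linear synthetic cohort where the least-squares optimum is known |
| `patience` | 15 | early stopping on the validation imputation error, capped at 20 |
| `n_cycles` | 51 | 1 baseline + 50 uncertainty cycles |
| quality gate | R² ≥ 0.55, R² variance ≤ 0.025 | the reference operating point balancing accuracy and uncertainty |

The per-epoch validation error (all target columns masked, `val_L`
draws) uses a fixed draw seed so that early stopping compares
like-for-like across epochs; the training RNG stream is saved and
restored around it, keeping whole-run determinism.

## 3. Feature clustering and the embedding contract

Features (not samples) are embedded into 2-D from their value vectors
across training+validation samples only — test rows are excluded
because the clustering feeds model training, and letting test data
shape the ensemble would leak. Whether to cluster on raw or scaled
values is not externally fixed; the package uses the scaled matrix.

The embedding contract is deliberately pluggable: any method that
produces one 2-D coordinate per feature from a cosine-similarity
neighbourhood qualifies. The default backend (`knn_mds`) builds the
35-nearest-neighbour graph under cosine distance, finds its connected
components, lays out each component by classical MDS of its internal
cosine distances (normalised to unit RMS radius) and places component
centres on a wide circle. The rationale is geometric: $c$ mutually
near-orthogonal feature blocks form a $(c{-}1)$-simplex that cannot
embed isometrically in the plane, so *global* MDS necessarily crowds
some blocks together and the silhouette criterion then under-counts
clusters. Neighbourhood-embedding methods sidestep this by rendering
disconnected manifolds as compact, well-separated islands, and
`knn_mds` reproduces that behaviour deterministically. When the graph
is fully connected it reduces to global MDS (also available as
`method = "cmds"`). `min_dist` is retained in the parameter object for
interface compatibility but not used by either backend.

k is chosen by mean silhouette over k-means fits (10 restarts, seeded)
with near-ties (within 0.01) broken toward the elbow (largest second
difference) of the within-cluster sum of squares. Clusters are named
by their modal compound class; a modal share below 50% yields
"Others". The 50% threshold is a package choice (`others_threshold`) —
no numeric rule is externally given.

## 4. Preprocessing decisions

* **Scaling.** The source description of the scaling is ambiguous
  (min–max to $[-1,1]$ "using mean and standard deviation"). The
  primary path is true min–max: centre = training mid-range,
  half-range = training half-range, clipping validation/test values to
  $[-1, 1]$. A `method = "zscore"` switch standardises by training
  mean/SD and then clips, covering the other reading. Both fit on
  training rows only; the no-leakage property is asserted by test.
* **Split.** 70/10/20 by seeded permutation with
  floor-then-largest-remainder rounding (ties resolved train → val →
  test). For n = 979 this gives 685/98/196; the reference cohort's
  reported 706/78/195 is not a 70/10/20 of 979 under any rounding rule
  and is treated as bookkeeping of record, not something to
  reverse-engineer.
* **Missingness.** Entries surviving the 25% filter stay missing and
  are handled inside the model likelihood via the mask — no
  pre-imputation.
* **LOF.** Run on mean-completed values with k = 20 and decision
  threshold 1.5 (the cited method's default behaviour); boundary ties
  are kept. Whether outlier removal preceded or followed scaling is
  not externally specified; the package runs it before scaling.

## 5. The synthetic world

`generate_cohort()` states a world rather than tuning one: per class
$c$, shared factors $U_c$, input-private factors $P_c$ and
target-private factors $V_c$ are i.i.d. standard normal; a feature
with loading direction $w$ (random unit vector in the positive
orthant, so same-class features correlate positively) is

$$
x \;=\; \sqrt{\lambda}\, U_c w \;+\; \sqrt{1-\lambda}\, (\text{own
platform's private factors})\, w' \;+\; \sigma \varepsilon .
$$

Both platforms load the shared factor at $\sqrt\lambda$, which makes
two stated properties hold simultaneously: the share of a target
feature's signal variance explained by factors also loaded by the
input platform equals $\lambda$, and (at latent dimension 1, zero
noise) the input–target correlation equals $\lambda$ exactly. At
$\lambda = 1, \sigma = 0$ every target feature is an exact linear
function of same-class inputs, giving the linear-oracle regime used in
the acceptance tests. Outcomes are linear in the first shared factor
of each class (standardised effect scale, defaults 0.30→0.05 across
classes for BMI and half that for CRP — the magnitude of reported
metabolite–adiposity associations), plus age and sex effects, then
standardised. Missingness is MCAR by default; age is uniform, sex
Bernoulli(0.5); ground-truth factors are stored for tests only.

What a green test does establish: recovery of planted cluster counts,
monotone response of imputation quality and association concordance to
$\lambda$, calibration of the Bland–Altman flag rate, and
oracle-relative efficiency in the linear regime. What it does not:
chemical realism, instrument artefacts (retention-time drift, batch
effects), non-MCAR missingness, heavy-tailed noise, or performance on
any real cohort — the reference study's headline numbers (mean ρ 0.61,
199 well-imputed metabolites, ρ_BMI 0.93) are properties of a
restricted-access cohort and are format contracts here, not
reproduction targets.

## 6. Numerical choices

* Log-sigma of the encoder is clamped to $[-5, 3]$ and the decoder's
  per-feature log-variance to $[-6, 3]$ (gradients zeroed outside):
  prevents likelihood collapse on noise-free features.
* Importance weights are always normalised via log-sum-exp; an
  all-underflow weight vector raises rather than silently returning
  noise.
* Gradients of the full objective (including batch normalisation) are
  hand-derived; the test suite checks them against central finite
  differences at $10^{-6}$ absolute tolerance. Mix-up acts upstream of
  the objective (it rewrites the batch), so it does not alter the
  gradient derivation.
* Mix-up on incomplete data combines the zero-filled inputs and
  intersects the two examples' visibility/loss masks — a conservative
  approximation that never creates loss targets at unobserved entries.
* R² is the squared Pearson correlation of imputed vs observed
  (bounded in [0, 1], matching the uncertainty definition); the
  $1 - SS_{res}/SS_{tot}$ variant is reported alongside as `r2_ss`.
* Cycle 1 uses the same stochastic procedure as cycles 2–51; the
  per-sample Spearman ρ uses the cycle-mean of cycles 2–51.
* Greedy ties prefer the cluster model (smaller input space); the
  winning margin is recorded.
* Sex is coded 0/1 and not standardised; age is standardised;
  exposures and outcomes are standardised. No multiple-testing
  correction — the comparison is of effect sizes, not significance.
* Seeds: one master seed fans out to split/mask/init/sampling streams;
  all derived seeds stay below $2^{31}$.

## 7. Open choices resolved here

* **Which IWAE variant, K, L, widths, learning rate won the original
  tuning is unpublished** — all are grid axes with documented
  defaults, and `default_iwae_grid()` reproduces the published axes
  (432 coarse configurations); desk-scale runs subset it.
* **The selection metric for greedy choice** (R² vs MAE vs MSE on
  validation) is configurable (`validation_metrics(metric=)`) and
  logged; default R².
* **"Unique to the target platform"** is operationalised by
  annotation tags: a selected metabolite counts as unique when no
  input-platform feature shares its annotation.
* **Oracle-equivalence regime.** At loading 1 the least-squares
  oracle's error is exactly zero, so a "within 2× of the oracle" bound
  is unattainable by any stochastic imputer; the acceptance test
  therefore uses a noise-free cohort at loading 0.8, where the
  oracle's irreducible MSE is the target-private variance and the
  bound has content. The loading-1 limit is covered separately by the
  R² > 0.95 requirement.
* **Per-class information-restriction dominance** (a cluster model
  beating the all-feature model on its own class) is an expectation
  statement; with ~26 validation samples the per-class comparison is
  noise-dominated, so the tests assert class-average dominance exactly
  and the per-class version within 0.05.

## 8. Known limitations

* Pure-R training: fine for panels of a few hundred features and
  cohorts of a few thousand samples; not for GPU-scale data.
* The embedding backend is not UMAP; it reproduces UMAP's
  island-rendering behaviour for well-separated feature blocks but
  will differ on data with continuous manifold structure.
* Self-normalised IS imputation degrades when the visible-entry
  likelihood makes weights degenerate (very high D with a poor
  posterior); the package raises on underflow rather than guessing.
* MCAR-only missingness in the generator; MAR/MNAR worlds would need
  a config extension.
* The coarse-to-fine grid search refines only the value-mask rate
  around the coarse winner; a full second-stage grid is the caller's
  choice.
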