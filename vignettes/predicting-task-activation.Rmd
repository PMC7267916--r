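---
title: "Predicting individual task activation from resting-state connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual task activation from resting-state connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskpred)
```

# The problem

Task-fMRI activation maps differ between people in reproducible ways: the
same cognitive contrast activates slightly different territory, with
different strength, in different individuals. Resting-state functional
connectivity carries much of that individual signature, so a subject's
task activation map can be *predicted* from their resting-state data
alone, given a model trained on other subjects. taskpred implements such a
framework end to end — connectivity feature extraction, per-parcel
regression with three model families, ensemble averaging, hyperparameter
search, and evaluation — together with a synthetic cohort generator that
makes every stage testable against known ground truth.

# The prediction model

Each subject $j$ is described by a feature matrix $X_j$ (grayordinates
$\times$ F connectivity features) and a task map $y_j$ (z-scores per
grayordinate). The cortex is divided into parcels and one regression model
per parcel maps features to activation.

**GLM.** Per parcel, training subjects' rows are stacked and
$\beta = X^{+} y$ (Moore–Penrose pseudoinverse, i.e. the minimum-norm
least-squares solution); prediction is $\hat y_j = X_j \beta$. With P
parcels and F features the fitted object is an $F \times P$ coefficient
matrix.

**Feed-forward network.** Per parcel, a network with a tanh hidden layer
and a linear output unit, trained full-batch by resilient backpropagation
(Rprop: per-weight step sizes adapted from the *sign* of the gradient
only, $\eta^+ = 1.2$, $\eta^- = 0.5$, steps clipped to
$[10^{-6}, 50]$; the `learning_rate` hyperparameter sets the initial step).
Rows are split 60/20/20 into training/validation/test; training stops at
the validation-MSE minimum (patience 6 epochs, checked every epoch) or at
1000 epochs. Weights are initialized from a seeded uniform distribution
scaled by fan-in, recorded in the model metadata.

**Random-forest bagging.** Per parcel, bootstrap-aggregated regression
trees with a fresh random subset of features considered at every split
(variance-reduction splits, leaf means, prediction = mean over trees);
defaults are 100 trees, F/3 predictors per split, minimum leaf size 5.
The trees are fit by `ranger`, seeded for reproducibility.

**Ensembles.** NN and RFbag models are trained $M$ times with different
derived seeds (hence different splits, initializations and bootstraps) and
the $M$ predicted maps are averaged. The GLM is deterministic, so its
ensemble members coincide and its averaging curve is exactly flat — a
useful self-check.

# Connectivity features

Features follow the dual-regression recipe. All runs are normalized per
grayordinate to mean 0, SD 1. Group PCA reduces the temporally
concatenated cohort (computed incrementally from the accumulated spatial
covariance, equal to exact PCA within numerical tolerance). Spatial ICA
(fixed-point negentropy maximization with a tanh contrast, deflation;
sign fixed to non-negative skewness, components ordered by back-projection
energy) is run per hemisphere, and components are filtered for left-right
symmetry by greedy one-to-one matching on mirrored spatial correlation
(default threshold 0.5; the retained count is data-driven). Dual
regression then yields subject-level maps: spatial regression of each
timepoint onto the group maps gives per-component time courses, temporal
regression of each grayordinate onto those courses gives subject maps.
Finally, the subject maps plus binary subcortical-structure indicator maps
are jointly regressed against the time series to give one course per
feature, and each course is correlated with every grayordinate's series;
columns are z-scored. Subcortical structures thus contribute features the
same way cortical components do, which mirrors the 2×components +
structures = F accounting of the full-scale analysis (2×34 + 32 = 100).

Two numerical details matter. The plain fastICA fixed-point update can
enter a period-2 limit cycle on weakly non-Gaussian data; when the
contraction stalls, the implementation switches to sign-aligned averaged
(damped) updates, which share the same fixed points and converge. And
rank-deficient dual-regression designs fall back to minimum-norm solutions
with a warning rather than failing.

# Parcellation

A random contiguous parcellation: seed vertices drawn uniformly without
replacement per hemisphere, every cortical vertex assigned to the nearest
seed by unweighted graph geodesic distance, ties to the lower seed index —
which provably keeps every parcel connected. Parcels deliberately carry no
functional meaning. Subcortical nodes are grouped by anatomical structure,
one parcel per structure, rather than tessellated.

# Hyperparameter search

A sequential one-parameter-at-a-time sweep on dedicated hyperopt subjects,
with no parcellation (one whole-domain model per candidate) and RMSE on a
held-out 20% test subset as the objective. NN order: hidden-layer size,
then number of hidden layers, then learning rate; RFbag order: trees, then
predictors per split, then minimum leaf size; each parameter is fixed at
its RMSE-minimizing value before the next sweep. When the objective is
separable across parameters this coordinate sweep provably attains the
full-grid minimum, which the test suite checks against exhaustive
enumeration. Tuning rows can be subsampled under a fixed seed to bound
cost; the defaults keep the full historical grids (size 1–50, layers 1–3,
learning rate 0.001–0.1 in steps of 0.002; trees 1–200, predictors
1–(F−1), leaf 1–30), and sensible fixed choices are one hidden layer and
learning rate 0.001.

# Evaluation

**Correlation matrices.** Entry $(i,j)$ is the Pearson correlation between
test subject $i$'s predicted map and subject $j$'s actual map. A strong
diagonal means predictions are individual-specific, quantified here by a
permutation test on mean(diagonal) − mean(off-diagonal) that permutes the
predicted-to-actual pairing. Accuracy is the mean diagonal of the *raw*
matrix. A normalized variant alternates row and column z-scoring to its
fixpoint; a single rows-then-columns pass is not idempotent (reapplying it
moves entries by ~0.2 on generic matrices), while the fixpoint has exactly
standardized columns, near-standardized rows, and is stable under
renormalization.

**Mixture-model thresholding and Dice.** Each map's histogram is modelled
as Gaussian (null) + positive shifted gamma + mirrored negative gamma, fit
by binned EM (1024 bins) with deterministic multistart over
initializations, a joint Nelder–Mead maximum-likelihood polish, and BIC
selection against the reduced models (Gaussian-only, Gaussian+one gamma).
Two constraints keep the model identifiable: a gamma must start at or
beyond the null mean, and its mode must lie at least two null SDs away —
without them a high-shape gamma degenerates into a second Gaussian and the
decomposition is arbitrary. The activation threshold is the median of the
upper gamma (`loc + qgamma(0.5, shape, scale)`); masks keep positive
activation only, and overlap is the Dice coefficient
$2|A_1 \cap A_2| / (|A_1| + |A_2|)$, defined as 0 for two empty masks.
Thresholds are computed separately per subject, per map, per model.

A caution from the simulation-recovery study: the three parameters of a
*shifted* gamma are nearly unidentifiable when the shape is large (a
high-shape gamma is close to a Gaussian, so location trades off against
shape and scale along a flat likelihood ridge — the maximum-likelihood
estimate itself scatters by ~12% in shape at n = 50,000 under such a
truth). Recovery checks therefore simulate a strongly skewed activation
component (shape 2, scale 1, location 2, the `rmix_gg()` defaults) whose
sharp support edge pins the location; there the estimator recovers the
Gaussian mean within ~0.02, the shape within a few percent, and the
threshold within ~0.03.

**Model comparison.** One-way repeated-measures ANOVA (model as the
within-subject factor) from the standard sums-of-squares partition,
followed by one-sided paired t-tests for the ordered contrasts (NN > GLM,
RFbag > GLM, RFbag > NN), Bonferroni-corrected by the number of pairwise
tests. Degenerate inputs are handled explicitly: identical score vectors
give F = 0, p = 1; a constant shift with zero within-subject noise gives
p = 0.

# The synthetic cohort

The generator plants everything the analysis assumes, at desk scale
(spaces of 100–200 vertices per hemisphere standing in for 91,282
grayordinates; cohorts of up to 60 subjects standing in for hundreds).

- **Geometry**: points area-uniform on a unit sphere per hemisphere with
  symmetrized 6-nearest-neighbour adjacency (patched to a single
  component if needed); the right hemisphere is the exact mirror image of
  the left, so the mirror map and mirrored-map comparisons are exact.
  Subcortical structures are small labelled node groups.
- **Networks**: smoothed indicator bumps around farthest-point-sampled
  seeds, one set per hemisphere, right = mirrored left; `smoothness`
  counts diffusion steps. Defaults keep mean pairwise map correlation
  below 0.3.
- **Subjects**: group maps plus a smoothed Gaussian random field per map,
  scaled by `subject_variability` relative to the group map's SD —
  additive smooth perturbations, not diffeomorphic warps.
- **Time series**: spatial design (subject maps + subcortical indicators)
  times independent unit-variance AR(1) courses (lag-1 autocorrelation
  0.3) plus white noise. No hemodynamics, motion or physiological
  artifacts are simulated.
- **Task maps**: per parcel, $y = g(X)\,w_p + \varepsilon$ with $g$ the
  identity (linear link) or the fixed saturation $\tanh(1.5x)$ (nonlinear
  link, which a GLM cannot fit exactly while trees and networks can); maps
  are z-scored over vertices by default. Link weights carry a
  focal-activation profile — a seeded ~30% of parcels get 10× stronger
  weights than the rest — because uniformly activated parcels produce
  near-Gaussian map histograms in which the (BIC-guarded) mixture model
  correctly finds no activation component and Dice collapses to zero;
  focality is what gives real z maps their heavy positive tail.

Because the pipeline analyses variance-normalized series, the stored
ground-truth maps are expressed in those units (each vertex's analytic
marginal SD is $\sqrt{\sum_f \text{loading}^2 + \sigma^2_{noise}}$); the
raw-amplitude maps are kept alongside. Two consequences worth knowing:

- With *zero* time-series noise, normalization gives every vertex unit
  total loading, which de-sparsifies the normalized network maps and makes
  them strongly correlated — ICA recovery then fails for any algorithm.
  Recovery checks therefore use moderate noise (SD 0.5), where the bumps
  survive normalization. Dual regression, by contrast, is an exact
  inversion in the noiseless case and is checked there.
- Per-subject z-scoring of task maps introduces an affine offset that a
  no-intercept GLM cannot represent, so exact-recovery checks generate
  with `standardize = FALSE`; all other analyses keep the z-scored
  default.

Determinism is end to end: a master seed derives every stage seed through
a fixed affine-modular map (`derive_seed()`), manifests record all
parameters, and replaying a manifest reproduces the cohort bitwise.

# Study sizes

The packaged studies use cohorts of 15–50 subjects on 80–150
vertices-per-hemisphere spaces with 2 runs of 80–400 timepoints: large
enough that the GLM's exactness, the dual-regression inversions, the
RFbag/NN > GLM ordering on nonlinear links, monotone learning curves, the
benefit of NN averaging, and mixture recovery at n = 50,000 all hold with
comfortable margins, and small enough that the entire validation suite
runs in a few minutes on one CPU.

# Known limitations

Synthetic cohorts emulate the *statistical* structure the method assumes
— smooth mirrored networks, additive individual variability, AR(1)
temporal structure, focal activation — not the physiology of real fMRI
(no hemodynamic response, registration error, motion, or physiological
noise), so green tests demonstrate correctness of the implementation, not
performance on real data. The random parcellation is graph-geodesic,
uniform over vertices rather than surface area. Ensemble training is
serial; there is no GPU path. Headline accuracies from full-scale human
datasets are not reproducible at desk scale and are not targeted by the
validation suite.
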