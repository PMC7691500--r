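---
title: "Confounder-free adversarial feature learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-free adversarial feature learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cfnet)
```

## The problem

Medical-image predictors are routinely confounded: a variable such as age,
sex or pubertal stage influences both the images and the outcome being
predicted. An end-to-end network trained on such data happily learns the
confounder's imaging signature as a shortcut, which inflates accuracy on
similarly confounded test data, collapses on cohorts where the association
is absent, and produces biased saliency interpretations. Classical remedies
(matching, stratification, residualisation) act on precomputed features or
shrink the sample, and do not fit end-to-end feature learning.

`cfnet` trains the predictor and a *confounder-prediction* head
adversarially, so that the learned features stay predictive of the outcome
while becoming conditionally independent of the confounders given the
outcome.

## Model

Three subnetworks share one objective. The feature extractor maps an image
$X_i$ to a feature vector $F_i$; the predictor head emits
$\hat y_i = \mathrm{P}(F_i)$; the confounder head emits
$\hat c_i = \mathrm{CP}(F_i)$, one output per confounder. With prediction
loss

$$L_p = \frac{1}{N}\sum_i \ell(y_i, \hat y_i)$$

(binary cross-entropy for classification, squared error for regression) and
the adversarial surrogate loss evaluated only on the outcome-conditioned
cohort $\rho$,

$$L_{cp} = -\sum_{\kappa=1}^{k} \mathrm{corr}^2(c^{\kappa}, \hat c^{\kappa}),$$

the network solves

$$\min_{\theta_{fe},\,\theta_p}\;\max_{\theta_{cp}}\;
  L_p - \lambda\, L_{cp}.$$

Driving every squared correlation to zero enforces *mean independence*
between the features and each confounder on the conditioned cohort. The
squared-correlation loss handles continuous confounders naturally, which
binary-domain adversaries (domain classifiers) do not.

**Why condition on the outcome?** The confounder is intrinsically
correlated with the outcome, so demanding marginal independence would
destroy legitimate outcome signal. Within a fixed outcome group that
intrinsic correlation vanishes; whatever association remains between
features and confounder is the direct, spurious pathway. For binary
outcomes the cohort is one outcome group (e.g. healthy controls when the
confounder-image relationship of interest is normal ageing;
`conditionBinary()`). For continuous outcomes the cohort is an outcome
interval — by default the full width at half maximum of the outcome
distribution (`fwhmInterval()`), the well-populated range — resampled by
bootstrap so that the outcome distribution is exactly matched across the
levels of a discrete variable (`bootstrapMatchedCohort()`).

## Optimisation

Each iteration performs three sub-updates (`trainStep()`):

1. backpropagate $L_p$ on a mini-batch from all training data, updating
   $\theta_{fe}$ and $\theta_p$;
2. with $\theta_{fe}$ frozen, minimise $L_{cp}$ on a conditioned-cohort
   batch, updating $\theta_{cp}$;
3. with $\theta_{cp}$ frozen, minimise $\lambda \sum_\kappa
   \mathrm{corr}^2$ with respect to $\theta_{fe}$ (equivalently, maximise
   $L_{cp}$).

Each sub-update owns an Adam optimiser (learning rate 2e-4 by default,
batch size 64, $\lambda = 1$). Batch-normalisation running statistics
advance only in sub-update (1), so a $\lambda = 0$ run is bit-identical to
a baseline network with the confounder head detached.

### Making the adversary strong enough

On short iteration budgets the bare 1:1:1 alternation has a failure mode
that is easy to miss: the extractor can *hide* from the current confounder
head faster than the head re-learns, so the recorded correlations collapse
while a freshly trained probe still reads the confounder from the features
almost perfectly. Four config options close that loophole; all are off by
default and documented in `trainingConfig()`:

- `cpSteps`: several Adam steps for the head per iteration (cheap — the
  conditioned batch's features are computed once);
- `cpExactOutput`: the head's output layer is refit in closed form (ridge
  least squares) each iteration, i.e. the inner maximisation is solved
  exactly given the hidden layer; by the envelope theorem the sub-update
  (3) gradient through the refit head is the gradient of the best-response
  loss, which the extractor cannot evade;
- `advSteps`: repeated extractor updates against the refreshed best
  response;
- `condBatchSize = NA`: the surrogate loss evaluated on the entire
  conditioned cohort, removing the $O(1/\sqrt{n_{batch}})$ correlation
  noise floor below which no adversarial gradient survives;
- `advEvalMode`: conditioned-cohort passes may use evaluation-mode batch
  normalisation, so the representation being deconfounded is the one
  deployed at test time (with max-pooling after normalisation the
  train-mode and eval-mode representations differ nonlinearly, and
  cleaning one does not guarantee cleaning the other);
- `selectBest`: the alternating search oscillates around the saddle
  point, so the final iterate is an arbitrary point of that oscillation.
  With selection enabled, training returns the second-half snapshot with
  the smallest ridge readout $R^2$ of the confounders from the
  evaluation-mode features of the conditioned cohort — a cheap,
  training-data-only surrogate for the post-hoc probe.

A small weight decay on the extractor and predictor (`weightDecay`) helps:
it shrinks feature components the predictor does not use, which is where
residual confounder information survives.

## Cohort construction and evaluation toolkit

- `greedyMatch()` builds a confounder-matched (c-independent) evaluation
  subset: candidate case-control pairs are accepted in order of smallest
  confounder difference (ties by id, so the result is order-invariant)
  while the running two-sample t-test p-value between the matched groups
  stays at or above `pStop` (default 0.5). Accuracy on this subset cannot
  be inflated by confounder leakage; the drop relative to the full cohort
  measures how confounded a model is.
- `zscoreConfounders()` normalises confounders with population-sd z-scores
  computed on a reference (training) subset only.
- `classificationMetrics()` / `stratifiedEval()`: balanced accuracy,
  precision, recall, F1 at the 0.5 operating point, overall and within
  confounder strata, with the largest pairwise balanced-accuracy gap as a
  fairness measure.
- `posthocProbe()`: a fresh two-layer head retrained on frozen features
  (2000-step budget); the Pearson correlation between its predictions and
  the true confounder on held-out samples measures residual confounder
  information. The probe optimiser uses learning rate 1e-3 so that the
  fixed budget reaches convergence; with the reference 2e-4 the probe
  undertrains and understates residual confounding.
- `distanceCorrelation()` (biased V-statistic, bounded in [0, 1]) and
  `mutualInformation()` (Kraskov-type k-NN estimator, k = 3, nats) measure
  feature-confounder dependence without a trained probe;
  `bootstrapDependence()` and `compareDependence()` give bootstrap
  distributions and replicate-level two-sample t-tests for comparing
  models.
- `saliencyMap()`: plain gradient magnitude of the pre-threshold score
  with respect to input intensities.

## The synthetic generator

`generatorSpec()` / `generateConfounded()` emulate a confounded imaging
study with known ground truth. The outcome writes a uniform intensity
shift $\mu_y$ into region A; the confounder writes $\mu_c\,c$ into a
disjoint region B; `ycAssociation` ($\alpha$) sets the intrinsic
outcome-confounder correlation: $c = \alpha(2y-1) + \sqrt{1-\alpha^2}\,
\varepsilon$, so $\mathrm{corr}(y, c) \approx \alpha$ and $c \mid y$ has
unit variance.

Two design points matter:

- **Local separability.** The confounder signal is modulated by a ±1
  checkerboard, so it has zero local mean while the outcome signal is a
  uniform shift. Convolutional weight sharing means a filter responds to a
  local *pattern* wherever it occurs; if both signals had the same local
  pattern (differing only in position), any extractor retaining the
  outcome signal would necessarily retain the confounder signal, and
  confounder-free features with retained accuracy would be unattainable by
  construction. Real imaging confounders (ageing vs disease signatures)
  are locally distinguishable textures, which the checkerboard stands in
  for.
- **A visible confounded-baseline regime.** Defaults ($\mu_y = 1.5$,
  $\mu_c = 6$, noise 1, 4x4 regions, n = 1000, 32x32 images,
  $\alpha = 0.5$) are calibrated so that a plainly trained network learns
  the outcome region only partially within a few hundred iterations and
  leans on the much louder confounder region: its accuracy drops on
  association-free test data and a probe reads the confounder from its
  features. This is the regime in which deconfounding can be demonstrated;
  with a much stronger outcome signal the baseline never takes the
  shortcut, with a much weaker one nothing learns.

`oracleBayesAccuracy()` gives the analytic ceiling of a classifier using
region A only, $\Phi(\mu_y \sqrt{|A|} / (2\sigma))$ — accuracy above it on
confounded data indicates shortcut use. What the generator does *not*
emulate: anatomical structure, registration artefacts, spatially
correlated noise, multi-site effects; passing the synthetic study shows
the adversarial mechanics work, not that any particular clinical dataset
is deconfoundable.

## The deconfounding study

`runDeconfoundingStudy()` is the end-to-end experiment: per seed it trains
a baseline (head detached) and a conditioned adversarial model on the same
initialisation and batch stream (300 iterations, learning rate 1e-3,
weight decay 5e-3, 4-filter plan, full-cohort exact-output adversary with
`cpSteps = 10`, `advSteps = 2`, snapshot selection), then reports balanced
accuracy on confounded and association-free test sets (n = 400 each), the
post-hoc probe on test controls, and mean saliency over the confounder
region. Problem sizes are chosen so the ten-seed study runs in minutes on
one CPU. Expected outcome: the baseline probe correlation is large
(r above 0.5), the adversarial model's is statistically indistinguishable
from zero, its confounded-vs-free accuracy gap is smaller, and its
confounder-region saliency is lower. Seeds where the base optimisation
itself fails (weak-signal draws where even the baseline barely learns) can
fail the probe clause; the study therefore asserts a large majority of
seeds, not all.

## Numerical choices and edge cases

- Predicted probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before the
  cross-entropy.
- A correlation with input variance below $10^{-8}$ is defined as 0 with
  zero gradient, so a collapsed head output exerts no adversarial push.
- Batch normalisation uses biased variances, $\varepsilon = 10^{-5}$,
  momentum 0.1; max-pooling ties resolve to the first position in scan
  order; convolution pads the trailing edge, keeping spatial size until
  pooling halves it.
- He-normal initialisation; the extractor and predictor draws are
  independent of whether the confounder head is built, so baseline and
  full models start identically.
- Two RNG streams (main batches vs conditioned batches) keep a detached
  run's batch sequence identical to a full run's.
- The k-NN mutual-information estimator standardises marginals and adds a
  deterministic $10^{-10}$-scale jitter so bootstrap resamples (tied
  points) remain well defined; estimates are clipped at 0.
- `fwhmInterval()` returns bin centres (a single qualifying bin is widened
  to its edges); the default bin width is the Freedman–Diaconis choice.
- Greedy matching stops *before* adding the pair that would push the
  balance p-value below `pStop`; with fewer than two pairs the t-test is
  undefined and pairs are accepted.

## Limitations

- The alternating optimisation is a saddle-point search; on unlucky
  initialisations it can trade substantial accuracy for independence, and
  no convergence guarantee exists.
- Mean independence (zero correlation against the best response of a
  finite head) is weaker than full statistical independence; the
  dependence measures (dcor, MI) are therefore reported alongside.
- Multiple confounders share one conditioned cohort; confounders that are
  not conditionally independent given the outcome would need separately
  conditioned heads.
- If the confounder's imaging signature is locally indistinguishable from
  the outcome's, no convolutional extractor can separate them (see the
  generator section); deconfounding is then impossible in principle, not
  just in practice.
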