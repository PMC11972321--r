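---
title: "Methods: predator-crow optimization, feature selection and ventricle segmentation in cardiopcso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predator-crow optimization, feature selection and ventricle segmentation in cardiopcso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiopcso` implements a cardiovascular-disease (CVD) risk-modelling
pipeline built around a hybrid population metaheuristic, the Predator Crow
Search Optimization (PCSO): information-gain feature selection over a
clinical tabular schema, a dense neural classifier whose weights are found
by PCSO rather than by gradient descent, a model-agnostic explanation
layer, and a U-Net for left-ventricle segmentation trained with Dice loss.
Because the clinical sources such a pipeline targets (cine-MRI challenge
data, registry tables with MACCE outcomes) are permission-gated, the
package ships synthetic generators with known ground truth; every claim the
test suite makes is a claim about those generators, a point this vignette
returns to at the end.

## The PCSO metaheuristic

PCSO is a bounded continuous minimizer over a box $[S_{\min}, S_{\max}]^d$.
It maintains $\tau$ candidate solutions ("prey" positions), a best-so-far
*elite* position, and a parallel flock of "crow" agents each remembering
the best point it has produced. One iteration has two parts.

**Phase steps.** The iteration budget $Q_{\max}$ is divided into thirds
that move the step distribution from exploration to exploitation, the
velocity-ratio scheme of the marine-predator family:

* Phase 1 ($Q < Q_{\max}/3$): Brownian steps. For each agent,
  $s_i = Y_A \otimes (e - Y_A \otimes x_i)$ with $Y_A$ standard normal and
  $e$ the elite; the proposal is $x_i + C\,Y \otimes s_i$ with
  $Y \sim U(0,1)^d$.
* Phase 2: the first $\lceil \tau/2 \rceil$ agents switch to heavy-tailed
  Lévy steps $Y_R$ against the elite; the rest keep Brownian steps
  $s_i = Y_A \otimes (Y_A \otimes e - x_i)$ damped by the adaptive
  multiplier $M(Q) = (1 - Q/Q_{\max})^{2Q/Q_{\max}}$, which equals 1 at the
  start, 0.5 halfway and 0 at the last iteration.
* Phase 3 ($Q \ge 2Q_{\max}/3$): all agents take damped Lévy steps
  $s_i = Y_R \otimes (Y_R \otimes e - x_i)$, proposals
  $x_i + C\,M \otimes s_i$.

Lévy steps use Mantegna's algorithm with tail exponent 1.5, so single
coordinates occasionally make long jumps; the tail index is verified
empirically in the tests by regressing the survival function on a log-log
grid.

**Hybrid predator-crow proposals.** Each agent also forms a *raid jump*
$x_i + M\,(S_{\min} + Y \otimes (S_{\max} - S_{\min})) \otimes H$, where
$H$ is an elementwise Bernoulli mask (probability `mask_prob`) choosing
which dimensions leap, and a *crow step*
$c_e + r\,FL\,(\mathrm{mem}_j - c_e)$ toward the memorized best of a
uniformly chosen other agent $j \ne e$. The two candidates are blended
50:50 and clipped to the box.

Design choices that the source formulation leaves open, fixed here once:

* The "raiding search agent" position that drives the phase steps is the
  global elite (best-so-far). This is the only reading that closes the
  update equations, and it matches how the predator-family algorithms this
  scheme mirrors use their elite matrix.
* Acceptance is greedy per agent for *every* proposal (phase and hybrid):
  a proposal replaces an agent's position only when its fitness improves.
  This extends the replace-on-improvement rule to all moves and guarantees
  the non-increasing best-fitness history that convergence claims
  presuppose; it is asserted as an invariant in the tests.
* The raid-jump expression is parenthesized as
  $S_{\min} + Y \otimes (S_{\max} - S_{\min})$ — a random point of the box
  — so that jumps land inside bounds before clipping.
* Crow memory is the per-agent best *evaluated* point. Crow positions move
  every iteration without being evaluated on their own; only the blended
  hybrid candidate is evaluated, which is what the memory update uses.
  This keeps the cost at two objective evaluations per agent per
  iteration: `evaluations = pop_size * (2 * max_iters + 1)` including the
  initial population, a count the result object reports and the tests
  check.
* Defaults $C = 0.5$, $FL = 2.0$, `mask_prob` $= 0.2$, Lévy exponent 1.5
  are the conventional values of the parent algorithm families; all are
  exposed in `pcso_config()`.
* Bounds are enforced by clipping (the simplest contract satisfying the
  containment invariant); termination is the fixed iteration budget, with
  an optional stagnation window that is off by default.

Calibration at desk scale: on the 5-D sphere with $\tau = 20$,
$Q_{\max} = 200$, the suite requires the median final best over 20 seeds
to fall below $10^{-2}$ and to beat an equal-budget uniform random search
on both sphere and Rosenbrock; the acceptance script recomputes these
medians from scratch.

## Information-gain feature selection

Features are scored by the entropy reduction of the binary label, in bits:
$IG(X, Y) = H(Y) - H(Y \mid X)$ with
$H(Y) = -\sum_i p_i \log_2 p_i$ and
$H(Y \mid X) = \sum_v P(X = v)\, H(Y \mid X = v)$. Numeric features are
discretized first; the fitted bin edges are reusable on held-out data, with
out-of-range values clipped into the end bins.

Choices: equal-width binning with 10 bins by default (deterministic and
friendly to schema-declared ranges; equal-frequency is available), base-2
logarithms throughout, and a selection threshold equal to the mean gain
across features — a parameter-free reading of "select what exceeds the
threshold" — with fixed-value and top-$k$ rules as alternatives. Ties keep
the original column order, so duplicated columns rank adjacently and
reproducibly. Tiny negative gains from floating-point cancellation
(magnitude below $10^{-12}$) are clipped to zero. Every entropy quantity is
tested against brute-force contingency-table enumeration at $10^{-10}$.

## The tabular generator

`gen_tabular()` emulates a 15-feature clinical table: demographic and
history flags, numeric measurements with the declared ranges (age 20–86
years, LVEF 18–88 %, haemoglobin 55–193.2, blood urea nitrogen 0.7–119,
total cholesterol 73–589, vessel count 0–3) and the binary MACCE outcome.
Numeric marginals are uniform within their ranges — the schema declares
only ranges, and uniform is the simplest distribution consistent with them
— and categoricals are uniform over their codes. The label follows a
logistic model on standardized informative features with user-set
coefficients, and the intercept is solved numerically so the expected
prevalence matches `imbalance_ratio` (default 0.3, which exercises the
SMOTE path). Where the suite needs a three-feature planted signal it uses
coefficients (2, 1.5, 1): a strong, a moderate and a weak predictor, so
recovery tests are not trivially easy.

What the generator does *not* emulate: correlated features, non-uniform
clinical marginals, label noise beyond the logistic link, and the joint
distribution of any real registry. A pipeline that recovers planted
features here has demonstrated correctness of its machinery, not clinical
validity.

## Preprocessing

* **Gaussian filtering** is a separable convolution with a unit-sum kernel
  truncated at $4\sigma$, reflect boundary (mirror without edge repeat), so
  constant images pass through unchanged and phantom borders are not
  darkened.
* **Z-scoring** uses the population (divisor-$n$) standard deviation by
  default so that re-applying fitted statistics to the training data is
  exactly idempotent; a flag switches to the sample divisor. Fitted
  statistics transfer to held-out data, and the pipeline tests assert that
  test rows never enter the fitted transform.
* **Outliers** are flagged at $|z| >$ threshold; the correction rule is
  flag-then-impute, consistent with mean/mode imputation used for missing
  values.
* **SMOTE** interpolates uniformly on segments between a minority row and
  one of its $k$ nearest minority neighbours (Euclidean distance, intended
  to run on z-scored features), appending enough rows to reach the target
  minority/majority ratio. Both SMOTE and the class-weighted loss are
  provided as independent switches, since either is a legitimate imbalance
  handle; they are not coupled.
* **Splitting** is stratified, with largest-remainder apportionment of
  per-class test counts so the overall test size is exact and class
  proportions stay within one sample.

## The PCSO-trained classifier and its explanations

The classifier is a fully connected network with hidden layers of 128, 64
and 32 ReLU units and a sigmoid output; the training split is 80:20. Its
entire flattened weight vector is the PCSO search point, inside a symmetric
box of half-width 3 (compatible with z-scored inputs; configurable). The
fitness of a weight vector is the class-weighted binary cross-entropy on an
internal validation split — matching the stated loss while guarding
against overfitting — with probabilities clipped at $10^{-7}$.

Batch normalization is applied to each hidden pre-activation using moments
computed on the training split for the weight vector under evaluation.
This makes fitness a deterministic function of the weights, which a
population search requires (there are no minibatch updates to average
over). The normalization is non-affine (no learned scale/shift), keeping
the search space smaller; the additive bias before a normalized layer
cancels exactly and is therefore skipped in that path. Dropout (default
0.1) has no role during population search and only acts in the optional
gradient refinement: a few epochs of Adam (learning rate 0.001, batch size
32) that can polish the PCSO optimum but is off by default, since the two
optimizers are alternatives rather than a prescribed combination. Epoch
and batch-size settings are meaningful only in that refinement mode.

The explanation layer makes no claim to a specific proprietary "XAI
algorithm"; it is the minimal model-agnostic pair. Global importance is
permutation importance — the mean increase in held-out loss when one
feature column is shuffled, over `n_repeats` draws, reported with its
standard deviation and cross-referenced against the information-gain
ranking. Local attribution is the central finite-difference sensitivity of
the predicted probability, step $10^{-4}$ on z-scored inputs. Permutation
importance is evaluated on held-out data deliberately: on training data a
network can earn genuinely positive importance for noise features it has
overfitted, while on held-out data noise importances center on zero, which
is the null the tests assert (within three standard deviations).

## U-Net segmentation

The segmentation network is a five-level encoder/decoder. Each block is
conv3×3 → batch norm → ReLU, twice, then 10 % dropout; encoder blocks end
in 2×2 stride-2 max pooling, decoder blocks start from a 2×2 stride-2
transposed convolution whose output is concatenated with the skip
connection from the same level. Channels run 8 → 16 → 32 → 64 → 128 on
contraction (`min(base * 2^level, max)`) and mirror back to 8; a final 1×1
convolution produces per-pixel class scores, softmaxed over background,
cavity and myocardium. Kernels are He-Normal initialized. Training is Adam
at learning rate 0.001 on soft Dice loss averaged over foreground classes
(a class absent from both prediction and reference scores 1). Everything —
im2col convolutions, batch-norm and pooling backward passes, the
transposed-conv adjoint, Adam — is implemented in-package in base R with
BLAS matrix products, and the full backward pass is verified against
central finite differences in the tests.

Padding: the network uses shape-preserving (same) padding, so predictions
align with inputs pixel-for-pixel. An unpadded 3×3 convolution would
shrink each side by 2 (256 → 254); `conv_output_size()` documents that
arithmetic, but a valid-padding network variant (which would force skip
cropping) is not built — the shape-preserving reading is the only one
consistent with mask-sized outputs.

"Context-based partitioning" is realized as perfect-ROI cropping:
`roi_crop()` takes the tight bounding box of a reference mask, expands it
by a margin (default 8 px), clips to the image and grows it to the
divisibility the network needs ($2^{\text{depth}-1}$); `roi_paste()` maps
predictions back losslessly. Only the reference-mask protocol is
implemented — an automatic ROI detector is a separate problem the package
does not claim.

The phantom generator supplies annulus-topology targets: a bright circular
cavity inside a mid-intensity myocardial ring on a dark background, with
randomized center and radii and additive Gaussian noise. This captures the
cavity/myocardium topology of short-axis slices and nothing else — no
papillary muscles, trabeculation, intensity inhomogeneity, partial-volume
borders or anatomical variability. The calibration the suite runs — 50
training phantoms at 64×64, 20 epochs, batch size 8, mean held-out Dice
required to reach 0.9 — is a scaled-down analogue chosen so a single CPU
trains the network in a few minutes; batch size 8 (rather than the
classifier-side 32) keeps the im2col workspaces small at no cost to the
phantom task.

## Evaluation and the cross-validation harness

Metrics come verbatim from the confusion matrix: accuracy, precision,
recall/TPR, FPR, plus ROC by threshold sweep (ties grouped, curve anchored
at (0,0) and (1,1)) with trapezoidal AUC, Dice and IoU for masks.
Degenerate denominators return 0 with a warning so batch evaluation stays
total. The F1 score deserves a note: the standard harmonic mean
$2PR/(P+R)$ is the default, while a halved variant $0.5\,PR/(P+R)$ —
which some write-ups print, and which is inconsistent with F1 values that
exceed both precision and recall — is available behind
`f1_variant = "printed_half"` for comparison studies, not as a
recommendation. AUC is tested against brute-force Mann–Whitney pair
counting at $10^{-10}$, and the identity $IoU = D/(2-D)$ is asserted on
random fixtures.

Cross-validation defaults to $k = 5$ stratified folds. Fold ids are
assigned per class with a rotating offset so each sample is validated
exactly once and fold sizes differ by at most one overall and per class.
Every fold re-fits the complete pipeline — z-scoring, optional SMOTE,
feature selection, PCSO training — on its training folds only.
`run_pipeline()` executes generate/load → impute → split → fit → metrics →
explanation and attaches a manifest (config echo, R and package versions)
from which `run_from_manifest()` reproduces the identical report; the CLI
script under `inst/cli/` is a thin wrapper over these functions.

## Problem sizes, seeds and what the tests show

The suite fixes every seed, so its stochastic checks are deterministic
re-runs of calibrated experiments: feature-recovery over 10 generator
seeds (9/10 required), optimizer medians over 20 seeds, a classifier run
at $\tau = 30$, $Q_{\max} = 150$ on 400 separable points (held-out
accuracy at least 0.9, label-permutation nulls inside [0.4, 0.6]), and the
phantom calibration above. These sizes are the package's chosen desk-scale
study conditions. Passing them demonstrates that the implementations are
correct and that the method behaves as designed on data with known ground
truth; it demonstrates nothing about clinical data, where feature
correlations, annotation noise and distribution shift dominate.

## Known limitations

* The optimizer treats the objective as a black box; there is no
  constraint handling beyond box clipping and no discrete/combinatorial
  mode.
* PCSO over the full weight vector scales poorly with network size; the
  provided architecture (tens of thousands of weights) is near the
  practical ceiling for a population search on one CPU.
* The U-Net is 2-D and single-channel; no 3-D volumes, no ensembling, no
  automatic ROI detection.
* Permutation importance is correlation-blind: grouped or duplicated
  predictors share importance mass.
* The synthetic generators are deliberately simple; see the caveats above
  before reading any test pass as a clinical claim.
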