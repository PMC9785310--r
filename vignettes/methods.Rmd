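---
title: "Methods: surrogate-optimized CNN classification of expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-optimized CNN classification of expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical conventions, and the
choices made where the design was genuinely open. The running application
is leukemia-subtype classification from microarray expression matrices —
a p ≫ n problem with thousands of genes and a few dozen samples — but
every component is generic over any labelled sample × gene matrix.

## The pipeline at a glance

For each train/test experiment (70-30, 80-20, and a non-stratified random
split), the pipeline runs: normalize → impute → split → BPSO gene
selection on the training partition → HORD hyper-parameter search with its
objective evaluated inside the training partition → final CNN training on
the full training partition → test-set evaluation. Feature selection and
hyper-parameter search never see the test partition; this leak-free order
is a deliberate choice (a `select_on = "all"` flag exists to mimic
whole-dataset selection for comparison, with the caveat that it
optimistically biases the test metrics).

## Digit-scaling normalization

For a positive integer $X$ with $n$ decimal digits and leading digit $F$,

$$\mathrm{ND} = \frac{X - F\cdot 10^{\,n-1}}{10^{\,n-1}},$$

i.e. strip the leading digit and rescale by its place value; the result
lies in $[0,1)$. We adopt this parse because it is the only reading of the
rule that actually lands in the unit interval; 0 maps to 0 by convention,
negative integers are transformed on their absolute value with the sign
restored, and non-integer data are rejected (use min-max instead). Note
the transform is *non-monotonic* (7129 → 0.129 but 999 → 0.99): it
compresses magnitudes but scrambles order across digit boundaries. That
matters downstream: distance-based gene selection assumes a
signal-preserving scaling, so the pipeline's comparison experiments use
min-max normalization, while digit scaling remains available as the
stateless alternative it is. Min-max statistics are always computed on
training data only and replayed onto test data via a stored record — the
pipeline therefore normalizes after splitting when min-max is selected.

## BPSO gene selection

Standard global-best binary PSO. Velocities update as
$v \leftarrow w v + c_1 r_1 (\mathrm{pbest} - x) + c_2 r_2 (\mathrm{gbest} - x)$
with $r_1, r_2 \sim U(0,1)$ per dimension ("random integers" would make
the update degenerate, so uniform draws are the only sensible reading),
clamped to $\pm v_\mathrm{max}$; positions pass through a sigmoid to
per-gene inclusion probabilities (the canonical binary-PSO transfer — the
continuous equations alone do not define a selection mechanism), and an
all-zero mask is rescued by forcing one random bit. Defaults
($m = 30$ particles, 50 iterations, $c_1 = c_2 = 2$, inertia decaying
0.9 → 0.4, $v_\mathrm{max} = 4$) are the textbook BPSO settings; none are
prescribed by the application, all are exposed in `pso_config()`.

The wrapper fitness is
$\alpha \cdot \mathrm{acc}_{CV} + (1-\alpha)(1 - |mask|/D)$ with
$\alpha = 0.9$. The accuracy term is the *repeated* stratified $k$-fold CV
accuracy of a fast nearest-centroid classifier (default 3 folds × 5
repeats, fold assignments fixed by the seed so every mask is scored
against the same folds). Repetition matters: a single 3-fold pass on
$n = 40$ samples quantizes accuracy in steps of $1/40 = 0.025$, which is
coarser than the marginal accuracy contribution of a partially redundant
informative gene; the sparsity bonus then strips genuinely informative
genes. Averaging 5 repeats refines the granularity to $1/200$ and lets the
swarm resolve those margins. The CNN is deliberately *not* used inside the
swarm — at thousands of fitness evaluations per run it would be orders of
magnitude too slow, and wrapper selection with a cheap reference
classifier is standard practice.

## The cubic RBF surrogate

$S_t(h) = \sum_{d=1}^{t} \lambda_d \lVert h - h_d \rVert^3 + p(h)$ with an
affine tail $p$, fitted by the standard augmented symmetric system with
orthogonality side conditions $\sum_d \lambda_d [1, h_d] = 0$. The solve
is exact: $S_t$ interpolates every evaluated point, and any affine target
is reproduced with $\lambda \to 0$. Numerical conventions: a singular
system (e.g. duplicate centers) falls back to a ridge of $10^{-8}$ on the
RBF block, recorded on the model and warned about so callers can assert
the path; updates refit from scratch ($t$ stays in the hundreds here, so
the $O(t^3)$ refit is negligible and much easier to verify than an
incremental factorization).

## The HORD loop

The optimizer *maximizes* a black-box objective $G(h)$ over the unit cube
(losses are wrapped by negation). It starts from a Latin hypercube of
$t_0$ points — each column a permutation of jittered strata
$(\mathrm{perm}(0..t_0-1) + U(0,1))/t_0$ — then repeats until the budget
$N_\mathrm{max}$ is spent: fit the surrogate to all evaluated points, take
the incumbent $h_\mathrm{test} = \arg\max G$, generate $c$ candidates by
perturbing each incumbent coordinate independently with probability

$$\varphi_t = \varphi_0\left(1 - \frac{\ln(t - t_0 + 1)}{\ln(N_\mathrm{max} - t_0)}\right),
\qquad \varphi_0 = \min(20/D, 1),$$

by $N(0, \sigma^2)$ noise reflected into $[0,1]$ (a candidate with no
perturbed coordinate gets one forced), score candidates by
$W = \epsilon W_{cv} + (1-\epsilon) W_{dm}$ — $W_{cv}$ rescales surrogate
predictions so the best-predicted candidate scores 0, $W_{dm}$ rescales
minimum distances to evaluated points so the farthest scores 0, each
degenerating to all-ones when constant — and evaluate the true objective
at $\arg\min W$ (ties to the lowest index, everywhere, for
reproducibility).

Choices the method statement leaves open, fixed here as package defaults
(all in `hord_config()`):

* $t_0 = 2(D+1)$ initial points (at least $D+1$ is required to fit the
  tail) and $c = 100 D$ candidates per iteration — conventional sizes for
  this family of optimizers.
* $\epsilon$ cycles through ⟨0.3, 0.5, 0.8, 0.95⟩, alternating
  exploration-leaning and exploitation-leaning scoring; any fixed value
  can be configured instead.
* $\sigma$ starts at 0.2 in encoded units, halves after 3 consecutive
  non-improving evaluations (floor 0.005) and doubles after 3 consecutive
  improvements (cap 0.2) — the usual dynamic-coordinate-search radius
  adaptation.
* Mixed discrete spaces enter the continuous surrogate through level
  encoding: a $k$-level dimension maps level $i$ to the stratum center
  $(i - 0.5)/k$ and decodes by rounding to the nearest center, so
  encode/decode is an exact bijection on configurations. Candidates that
  decode to an already-evaluated configuration are re-sampled up to 10
  times, then accepted as archive duplicates with the stored value copied
  — late in a run on a small discrete space collisions are unavoidable,
  and re-training on an identical configuration would waste budget.
* A failed objective evaluation (an error, a diverged training) is
  recorded in the archive with value `NA` and skipped by the surrogate
  and the incumbent; more than 10% failures aborts the run. Keeping
  failures in the archive preserves the budget-exactness invariant
  (archive length = $N_\mathrm{max}$).

## The 1-D CNN

`layer_depth` blocks of [valid 1-D convolution (`kernel_count` filters,
`kernel_size`, `stride`, activation) → batch normalization → width-2
max-pool (skipped once the sequence is shorter than 2) → dropout], the
final block projecting through `neuron_count` channels via a pointwise
convolution, then flatten → dense head: a single sigmoid unit for 2-class
problems under binary cross-entropy, otherwise softmax. The "L2" loss is
mean squared error on one-hot targets through the softmax; binary
cross-entropy generalizes to categorical cross-entropy beyond 2 classes.
Configurations whose sequence length collapses before the dense layer
(kernel wider than the input, aggressive stride/depth on short inputs)
raise a dedicated infeasibility condition which the tuning objective
converts to $G = 0$ with a failure flag.

Training is plain backpropagation with Adam at the configured learning
rate — the method statement tunes a learning rate but never names a
weight-update rule, and an adaptive-moment optimizer is the default choice
a practitioner would reach for. Dropout rate 0.25 (not specified;
configurable), pool width 2, early stopping on validation loss with
patience 10 restoring the best weights. The convolution, batch-norm and
pooling kernels are compiled C++ (Armadillo views over R memory, no
copies); weight initialization, batch shuffling and dropout masks all draw
from R's RNG, so `(config, data, seed)` fully determines the weights and
history. The hyper-parameter objective $G$ is the stratified 80/20 holdout
validation accuracy *within the training partition* (single repeat by
default, configurable) — the evaluation protocol is the method's largest
silence, so it is explicit and configurable here.

## Evaluation

One-vs-rest confusion counts per class; accuracy, recall, specificity,
precision as the usual ratios × 100; F1 as the harmonic mean
$2PR/(P+R)$ (the factor 2 restored — the printed formula omits it while
calling itself a harmonic mean, which only the factor-2 form is). A 0/0
ratio reports 0 with a degeneracy flag instead of raising, so optimizers
keep running on degenerate folds. ROC by sweeping all score thresholds
and AUC by the trapezoidal rule, which equals the Mann-Whitney
concordance statistic with ties counted ½; multiclass scores are handled
one-vs-rest with macro-averaged AUC. Report tables round half-up to one
decimal and append an arithmetic-mean row per arm. For multiclass (and
2-class) test sets the pipeline reports macro-averaged one-vs-rest
metrics, which for 2 classes makes recall/specificity symmetric in the
class roles.

## The synthetic generator

The generator emulates the statistical shape of the classic acute-leukemia
microarray: 72 samples × 7129 genes, two classes at 25/47 (up to four
classes supported via explicit proportions, since the real k > 2 partition
is not recoverable from the published description), non-negative integer
intensities, and a small informative-gene subset. Mechanism: each gene
gets a baseline log-mean; the first `n_informative` genes shift their
class-conditional log-means apart by `effect_size` within-class standard
deviations (within-class SD 0.5 on the log scale, classes spread evenly
across the shift range, random sign per gene); log-normal draws are
exponentiated, rounded, and clamped to `[0, value_scale]`. Class counts
use largest-remainder apportionment, so the dataset shape is exactly
deterministic; missing values are an explicit `NA` mask (empty CSV
fields), never conflated with zero expression.

What it does *not* emulate: batch effects, gene-gene correlation beyond
the shared class structure, heavy-tailed outliers, probe saturation, or
array-specific background. Passing tests on this generator therefore
demonstrate the pipeline's mechanics — selection recovers planted signal,
tuning finds feasible high-accuracy configurations, metrics and reports
are arithmetically right — not clinical performance on real arrays.

## Problem sizes in the test suite

The suite exercises the full pipeline at deliberately small scale, chosen
so the complete comparison experiment (three experiments × three arms ×
ten seeds) remains a routine run on a single CPU: 60 samples × 300 genes
with 10 informative genes at effect size 4, BPSO with 10 particles × 10
iterations, HORD with $t_0 = 11$ and a budget of 20 CNN trainings, and
20-epoch default CNNs. The optimizer benchmarks use budget 60 in 3
dimensions against a paired random-search baseline; selection recovery
uses 40 samples × 50 genes with 5 planted genes. These sizes are the
package's chosen reference conditions for its own properties, not
estimates of real-data requirements.

## Known limitations

* The CNN convolves along the gene axis, whose order is arbitrary in a
  microarray matrix; locality is therefore not meaningful prior
  structure, and the architecture's value on real data rests on the
  selection and tuning stages, not on translation invariance.
* The surrogate models a stochastic objective (holdout accuracy of a
  stochastically trained network) as deterministic; with a single holdout
  repeat, $G$ is noisy and the archive can enshrine lucky evaluations.
  Increase `repeats` in `objective_accuracy()` to trade budget for
  stability.
* Digit scaling is kept faithful to its definition, including its
  non-monotonicity; treat it as a historical preprocessing choice rather
  than a recommended one.
* BPSO wrapper selection inherits the granularity of CV accuracy;
  the repeated-CV default mitigates but does not remove it.
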