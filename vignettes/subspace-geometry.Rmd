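---
title: "Demixed subspace geometry and manifold reuse: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixed subspace geometry and manifold reuse: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demixgeom)
```

## The scientific question

When a subject learns a series of visuomotor mapping tasks — each task
pairing new visual stimuli with the same two motor decisions (up/down) —
premotor population activity can in principle solve the
stability–plasticity dilemma by factorizing its representation: a
*decision subspace* whose low-dimensional dynamics are preserved and
reused across tasks (a neural schema), and a *stimulus-related subspace*
that is free to re-represent novel sensory input, kept nearly orthogonal
to the decision subspace so the two do not interfere.

`demixgeom` implements the population-level analyses that test this
account on trials × units × time spike-count tensors:

1. a factorial **marginalization** of condition-averaged activity into
   condition-independent, stimulus, decision and interaction parts;
2. **demixed components** per marginalization, defining the stimulus- and
   decision-related subspaces;
3. the **manifold-reuse correlation**: for two tasks, the Pearson
   correlation over time between their per-decision trajectories on the
   reference task's top decision component, averaged over the two
   decision classes;
4. the **principal angle** between the two subspaces,
   $\theta = \arccos(\sigma_{\max}(U_d^\top U_s))$, compared against a
   label-shuffle null;
5. **decoder generalization**: a small temporal-convolution classifier
   trained on one task and evaluated with frozen parameters on later
   tasks;
6. **behavioral statistics**: trials to a sliding-window accuracy
   criterion, reaction times, effect sizes, and the Watson–Williams test
   for circular means.

Because comparable raw recordings are generally restricted-access, the
package treats its synthetic-session generator as a first-class module:
every analysis is validated by recovery against the generator's known
ground truth.

## Preprocessing

Counts are binned at 10 ms (100 bins covering the 1 s cue epoch before
the go cue; bin 0 at stimulus onset) and smoothed with a unit-area
Gaussian kernel of σ = 50 ms. Smoothing uses symmetric (reflective)
boundary handling, chosen so that a constant series stays constant and
total spike mass per series is conserved — in a fixed 1 s epoch,
zero-padding would attenuate the ends of every trace. Condition averages
are taken over the trials available in each (stimulus, decision) cell
with the counts recorded; no padding to a common trial count is done, so
unbalanced sessions are averaged cell by cell. An empty cell is an error
that names the missing condition.

## Marginalization and demixed components

For the condition-averaged tensor $X \in \mathbb{R}^{N\times S\times
D\times T}$ (after centering each unit by its grand mean), the factorial
decomposition is

$$X = x_t + x_{ts} + x_{td} + x_{tsd},$$

where $x_t$ is the mean over stimuli and decisions, $x_{ts}$ and
$x_{td}$ are the per-factor means minus $x_t$, and $x_{tsd}$ is the
remainder. The terms reconstruct $X$ exactly, each term is zero-mean over
the factors it was marginalized against, and in balanced designs the
per-term variances add to the total.

Demixed axes are the principal axes (eigenvectors) of each marginalized
term's covariance $C_m$. Components from all factors are pooled, ranked
by the fraction of total variance each captures from its own
marginalization, and truncated to `p = 20` by default. The decision-factor
axes are sign-fixed so that the "up" condition projects positively,
making cross-session trajectory comparisons well defined.

**Why not a variance-ratio (whitened) objective?** A classic demixing
solver maximizes $w^\top C_m w / w^\top (C_{tot}+\lambda I) w$. We
evaluated that formulation and rejected it for this pipeline, for two
reasons observed directly in simulation. First, at small ridge values the
ratio is maximized by pure sampling-noise directions (whose variance is
entirely "own-marginalization"), and the estimated axes lose the true
stimulus span almost completely. Second, and more fundamentally, the
pipeline must behave sensibly when the stimulus and decision subspaces
are *not* orthogonal — including the collinear extreme, where the first
stimulus axis coincides with the decision axis. A ratio objective
structurally discards a factor axis that is shared with a stronger
factor, so the estimated angle is biased toward 90° exactly where the
question is most interesting. Principal axes of $C_m$ have no such bias,
and they are also the literal construction behind the subspace bases the
angle analysis needs (an orthonormal basis of activity aligned to one
task factor). The `ridge` argument (default 0.01, as a fraction of total
variance) is kept as a positive-definiteness guard on
$C_{tot}+\lambda I$: with `ridge = 0` and rank-deficient data, fitting
stops with a request for a positive ridge rather than producing an
ill-conditioned fit.

How the original total of 20 components should be divided among the four
marginalizations is not specified anywhere; we rank globally by captured
variance, which allocates components adaptively.

## Subspace selection and the principal angle

Within the demixing result, the **stimulus** subspace takes components in
descending variance order as long as each explains more than 1% of the
total variance, stopping once the cumulative share within the stimulus
subspace reaches 70%; the **decision** subspace takes every component
above 1% with no cumulative cutoff (it is low-dimensional to begin
with). Selected columns are re-orthonormalized.

The reported angle is the *smallest* principal angle,
$\arccos$ of the largest singular value of $U_d^\top U_s$; the full
principal-angle spectrum is returned as well, since conventions differ on
whether the smallest or largest principal angle is "the" subspace angle,
and the spectrum lets a user reproduce either.

The null distribution permutes the stimulus labels and the decision
labels independently across trials (within each task) and reruns the full
demix → select → angle pipeline, 10 times by default, deterministically
given a seed. Two small policies make the null well defined on finite
data: a permutation that empties a condition cell is resampled (logged),
and if shuffling leaves no component of a factor above the 1% rule —
expected, since shuffling destroys that factor's genuine variance — the
null run falls back to the factor's single top component. The observed
angle is always computed with the strict rules.

Whether angles confined to [0°, 90°] should be rescaled before a
circular-statistics comparison is an open convention; following the
stated choice of test, `watson_williams()` treats the angles as circular
data directly, without doubling.

## Manifold reuse

Reuse of task $i$'s decision manifold in task $j$ is measured on the top
decision component of a demixing result fit on task $i$ alone: both
tasks' condition averages are projected through the same axis (no
refitting), averaged over stimuli to one trajectory per decision class,
and correlated over time per class,

$$\rho(S_i^c, S_j^c) = \frac{\mathrm{cov}(S_i^c, S_j^c)}
{\sqrt{\sigma_{i,c}^2\,\sigma_{j,c}^2}},$$

with the mean over the two classes reported. The statistic is invariant
to common positive affine rescaling, +1 for identical dynamics, and −1
when the mapping is reversed (the trajectory keyed to "up" behaves like
the reference task's "down").

## Decoding

The latent step projects smoothed single trials onto the top 16
principal axes of the trial-concatenated population activity. This is a
deliberate linear stand-in with the same `M × 16 × T` output contract as
a sequential-autoencoder latent extraction: downstream analyses depend
only on that contract, and a linear projection keeps the pipeline
CPU-scale and exactly reproducible. The projection fit on one task is
reused, frozen, for held-out tasks of the same session.

The classifier is a two-layer temporal CNN: two 1-D convolution layers
along time (8 filters each, kernel 3, stride 1, zero padding 1), each
followed by a rectifier and max-pooling, then dropout (probability 0.5)
and a softmax head. Choices the architecture description leaves open are
fixed as: pool width 2 (the smallest nontrivial pooling, keeping 100
bins divisible), plain minibatch gradient descent (learning rate 0.05,
batch 32, up to 200 epochs) with early stopping when the training loss
plateaus, inverted dropout during training only (evaluation is
deterministic). Gradients are verified against numerical differentiation
in the test suite. Training uses a stratified 80/20 split; k-fold
accuracy uses stratified folds dealt round-robin across classes so that
leave-one-out (k = M) is well defined. Cross-task evaluation is a pure
forward pass: parameters are bitwise unchanged.

## Behavioral statistics

Task acquisition is the earliest trial at which a trailing window of 15
trials reaches ≥ 90% accuracy, read strictly as ≥ 14/15 correct
(⌈13.5⌉). Window alignment (trailing, evaluated from trial 15 onward) is
a declared choice. Unacquired tasks fall back to the full session
length, i.e. a normalized trials-to-criterion of 1. Reaction time is
touch minus go cue, with malformed trials excluded and logged. Effect
sizes follow the standard closed forms: Hedges'
$g = J\,(\bar x_1-\bar x_2)/s_{pool}$ with $J = 1 - 3/(4\,\mathrm{df}-1)$,
$\eta^2 = SS_{between}/SS_{total}$, Cohen's $f = \sqrt{\eta^2/(1-\eta^2)}$;
t-tests and the one-way ANOVA are delegated to `stats`. The
Watson–Williams test uses the standard concentration correction
$K = 1 + 3/(8\hat\kappa)$ with $\hat\kappa$ from the usual piecewise
resultant-length approximation, warning when the pooled resultant length
is below 0.45.

## The synthetic-session generator

The generator (`make_session()`) emulates the recording design: 10 ms
bins over a 1 s epoch, 40–160 units, a task sequence A – B – (C) –
Revisit-A – Reverse-A, two decisions, and 2–6 stimuli per task. Its
latent construction makes the quantities the pipeline estimates *exact*
by construction:

* **One shared decision axis.** All tasks drive the same latent decision
  direction; the trial's decision sets the sign. The decision time course
  of task A is a half-cosine ramp (a smooth pre-movement build-up; the
  simplest shape consistent with preparatory dynamics without committing
  to unobserved detail).
* **Reuse as a temporal mixture.** A same-mapping task's decision time
  course is $u_\tau = \rho\, s + \sqrt{1-\rho^2}\, h_\tau$ with $h_\tau$
  exactly orthogonal to $s$ on the time grid and SD-matched, so the
  reuse correlation of the projected trajectories equals `reuse_rho`
  exactly before noise. (Rotating the decision *axis* instead cannot
  control this statistic: a Pearson correlation over time is invariant to
  the positive rescaling that a pure axis rotation induces on the
  projected trajectory.)
* **Reversed mapping.** The reversed task flips the sign of its decision
  dynamics relative to the executed decision, emulating activity that
  follows the original stimulus→decision rule; keyed by decision class,
  its reuse is $-\rho$, and a frozen decision decoder's accuracy inverts.
* **Controlled angle.** Each task owns private stimulus axes, one per
  stimulus, each stimulus with its own orthogonal waveform so that the
  stimulus marginalization spans all stimulus axes; the first stimulus
  axis is tilted toward the decision axis by exactly `target_angle_deg`.
  The ground-truth angle is therefore defined against the span the
  pipeline can actually observe, and is exact by construction (verified
  by SVD to 1e−6 in the tests). Per-task redrawing of stimulus axes (also
  for Revisit-A, which reuses task A's stimulus *identities*) is what
  makes stimulus decoders fail to transfer while decision decoders
  generalize.
* **Observation model.** Latents map to units through a random
  orthogonal-column loading (scaled so single-unit modulations are a few
  spikes/s), pass through a softplus to keep rates nonnegative, and
  counts are Poisson per bin. Defaults: 10 spikes/s baseline, task
  modulations of ~2–4 spikes/s SD per unit (decision and stimulus at 4,
  condition-independent at 2, times `signal_gain`) — typical premotor
  task-modulation depths. `signal_gain = 0` yields exact baseline
  Poisson activity.
* **Balanced design.** Every (task, stimulus, decision) cell receives
  `trials_per_condition` trials (default 50), emulating a subject that
  samples both decisions per stimulus while learning; the `outcome`
  column marks whether the decision matched the task's mapping.

What the generator does **not** emulate — and hence what passing
recovery tests cannot certify about real data: non-Poisson count
dispersion, correlated noise across units, non-stationarities within a
session, temporal structure richer than a fixed per-condition waveform,
unbalanced and error-correlated designs, and any single-neuron tuning
structure. The generator is a controlled testbed for the estimators, not
a biophysical model.

Behavioral sequences are Bernoulli with a saturating-exponential success
probability from `start_accuracy` to `asymptote_accuracy`, the standard
minimal learning-curve model for criterion-based measures.

## Numerical choices and degenerate inputs

* Smoothing matrices are built once per (T, σ) and applied as a single
  matrix product; symmetric kernels plus symmetric reflection conserve
  mass to 1e−9.
* Marginalization is exact arithmetic on means; reconstruction is tested
  to 1e−10.
* Singular values are clamped to [0, 1] before `acos`; non-orthonormal
  bases passed to `subspace_angle()` are re-orthonormalized with a
  warning.
* Component sign conventions: decision axes by positive "up" projection;
  other axes by positive largest-magnitude loading.
* Zero-variance trajectories, empty condition cells, constant
  regressors, zero pooled variance and undefined circular concentration
  all raise errors naming the problem rather than returning NaN.

## Problem sizes used by the tests and the acceptance script

Recovery checks run at the design scale the analyses target: 50 trials
per condition, 40–60 units, 100 bins, 5 tasks; angle recovery uses 4
target angles × 5 seeds with 10-shuffle nulls at 90°; reuse recovery uses
ρ ∈ {1, 0.5, 0}; the Watson–Williams decision check uses 100 replicates
of 30 + 30 von Mises angles against a 10,000-draw permutation oracle.
These sizes are the package's chosen study conditions; all complete on a
single CPU in a few minutes.

## Known limitations

* The demixing solver is the per-marginalization principal-axes variant;
  the reduced-rank-regression demixed-PCA solver (and cross-validated
  ridge selection) is out of scope.
* The latent extraction is linear; nonlinear trial-to-trial denoising is
  explicitly not reproduced.
* The decoder trains by plain SGD without a learning-rate schedule or
  hyperparameter search; accuracy claims in the tests use separability
  regimes insensitive to these settings.
* Angles are compared by Watson–Williams on [0°, 90°] data directly; the
  small-sample behavior of that choice for bounded (non-circular) data
  is inherited, mitigated by also exposing the permutation-style null.
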