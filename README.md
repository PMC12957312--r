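# demixgeom

Population-geometry analysis of multi-task visuomotor learning for R.

When a subject learns a series of visuomotor mapping tasks — each task
pairing novel visual stimuli with the same two motor decisions (up /
down) — premotor population activity can balance stability against
plasticity by factorizing its representation: decision dynamics that are
preserved and *reused* across tasks, and stimulus representations that
are re-drawn per task and kept nearly *orthogonal* to the decision
subspace. `demixgeom` implements the analyses that quantify this account
on trials × units × time spike-count tensors, for systems/computational
neuroscientists working with multi-task population recordings:

* **Preprocessing** — Gaussian-kernel rate smoothing (σ = 50 ms on 10 ms
  bins, reflective edges) and condition averaging
  (`smooth_rates()`, `condition_average()`).
* **Demixing** — factorial marginalization of condition-averaged
  activity, `X = x_t + x_ts + x_td + x_tsd` (condition-independent,
  stimulus, decision, interaction), with exact reconstruction; demixed
  components per factor from the principal axes of each marginalized
  covariance (`marginalize()`, `fit_demix()`, `project_demixed()`).
* **Manifold reuse** — the mean over decision classes of the Pearson
  correlation over time between two tasks' trajectories on the reference
  task's top decision component
  (`decision_trajectories()`, `manifold_reuse()`, `reuse_between_tasks()`).
* **Subspace geometry** — variance-rule selection of the stimulus and
  decision subspaces (> 1% per component; ≥ 70% cumulative for the
  stimulus subspace), the smallest principal angle
  θ = arccos(σ_max(U_dᵀ U_s)) with the full principal-angle spectrum, and
  a 10-repeat label-shuffle null
  (`select_components()`, `subspace_angle()`, `shuffle_null()`).
* **Decoding** — 16-dimensional latent trajectories (linear projection
  with a frozen, reusable basis) and a two-layer temporal-convolution
  classifier (8 filters, kernel 3, ReLU + max-pool, dropout 0.5, softmax)
  trained on an 80/20 split, with frozen-parameter cross-task evaluation
  and stratified k-fold accuracy
  (`extract_latent()`, `train_decoder()`, `cross_task_eval()`,
  `kfold_accuracy()`).
* **Behavioral statistics** — trials to a ≥ 90%-in-15-trials criterion,
  reaction times, learning-vs-reuse regression, Hedges' g / Cohen's f /
  η², and the Watson–Williams circular test
  (`trials_to_criterion()`, `reaction_time()`,
  `regress_reuse_vs_learning()`, `effect_size_suite()`,
  `watson_williams()`).
* **Synthetic sessions** — a Poisson spiking-population simulator with
  fully known latent geometry: a controllable angle between stimulus and
  decision subspaces, controllable cross-task reuse, and a reversed
  mapping (`sim_config()`, `make_session()`), plus a saturating-
  exponential behavioral simulator (`make_behavior_sequence()`).
* **IO / CLI** — a plain-text session container with lossless round
  trips, YAML/JSON run configuration, and a subcommand driver
  (`write_session()`, `read_session()`, `run_cli()`, and the
  `inst/cli/demixgeom` script).

## Worked example

Simulate a five-task session (A, B, C, Revisit-A, Reverse-A; 60 units,
50 trials per condition) whose ground truth sets an 80° angle between the
stimulus and decision subspaces and a cross-task reuse of 0.9, then run
the full pipeline:

```r
library(demixgeom)

cfg <- sim_config(seed = 42, target_angle_deg = 80, reuse_rho = 0.9)
out <- make_session(cfg)
out$session
#> <session_data> 1000 trials x 60 units x 100 bins (10 ms)
#> tasks: A, B, C, Revisit-A, Reverse-A

res <- fit_demix(out$session, tasks = "A")   # demix task A only
res
#> <demix_result> 20 components over 60 units
#>         factor explained_variance
#> 1     decision             0.6506
#> 2         time             0.0777
#> 3     stimulus             0.0753
#> 4         time             0.0550
#> 5     stimulus             0.0513
#> ...

for (tk in c("B", "Revisit-A", "Reverse-A"))
  cat(sprintf("reuse A -> %-10s %+.3f\n", tk,
              reuse_between_tasks(out$session, res, "A", tk)))
#> reuse A -> B          +0.910
#> reuse A -> Revisit-A  +0.933
#> reuse A -> Reverse-A  -0.934

shuffle_null(out$session, tasks = "A", seed = 1)
#> <angle_null> observed 80.13 deg; null 67.25 +/- 11.56 deg (n=10)
```

Reading the numbers: the top demixed component is decision-related and
carries 65% of the variance; projecting the other tasks through task A's
top decision axis recovers the generated reuse (0.91–0.93 against a
ground truth of 0.9), with the reversed mapping flipping its sign; and
the observed stimulus–decision angle (80.1° against a ground truth of
80°) exceeds the label-shuffle null (67.3° ± 11.6°). Decoder
generalization shows the same dissociation: a decision decoder trained on
task A transfers to Revisit-A at its training accuracy while a stimulus
decoder falls to chance, because stimulus axes are re-drawn per task.

The same pipeline runs from the shell on session containers:

```sh
Rscript inst/cli/demixgeom simulate --seed 5 --out runs/s1
Rscript inst/cli/demixgeom geometry --in runs/s1/session --out runs/s1/results
Rscript inst/cli/demixgeom decode   --in runs/s1/session --out runs/s1/results
Rscript inst/cli/demixgeom behavior --in runs/s1/session --out runs/s1/results
Rscript inst/cli/demixgeom report   --in runs/s1/results --out runs/s1
```

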