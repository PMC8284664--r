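---
title: "Methods: sequential Bayesian learning and transfer across shared subspaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential Bayesian learning and transfer across shared subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbltransfer)
```

## The scientific question

When people learn two tasks in a row, learning the second is sometimes
helped and sometimes hurt by the first. One candidate account is that both
tasks share a low-dimensional *subspace* of the stimulus — an intermediate
feature that, once extracted, makes each task simple. This package
implements a computational model of that account: a small multitask value
network whose first hidden layer *is* the subspace, trained by sequential
Bayesian learning (the elastic-weight-consolidation family), together with
the synthetic task environment and the statistics used to quantify
positive and negative transfer.

## The task environment

Stimuli are two "pies" showing `u1` and `u2` slices (1–5 each, 25
configurations). The agent predicts a binary outcome (sun/rain in task 1,
heads/tails in task 2) and receives correct/incorrect feedback. Inputs are
augmented with a constant third component `u3 = 6` (slices in a full pie),
so both relevant features are linear in the input: `u1 - u2` (Sub) and
`u1 + u2 - 6` (Add).

Four reward maps define `p(outcome 1 | u)`:

* **Sub1 / Add1** (log-quadratic): the log-odds are a quadratic form
  `(u - mu)' W (u - mu) + w0` with `mu = (3, 3)`, `w0 = 4` and
  `|W| entries = 2.4 * 0.71`. The sign of the off-diagonal entry collapses
  the form onto one feature: `4 - 1.704 (u1 - u2)^2` (probability peaks at
  equal slices, the Sub rule) or `4 - 1.704 (u1 + u2 - 6)^2` (peak at a
  full pie, the Add rule). We attach the `+0.71` sign to Sub1 because that
  is the sign that realises the stated Sub rule; the tests assert the rules
  rather than the sign label. The argmax policy scores 95% on these maps
  (exact enumeration over the 25 cells).
* **Sub2 / Add2** (log-linear): log-odds `beta * (x - 0.5)` in the same
  features. The `0.5` offset makes the strict rules ("more slices on the
  left", "sum greater than six") optimal, with the boundary cases leaning
  to the opposite response. Only the family, the rule and a 93% ceiling
  are specified for these maps, so `beta` is the one calibrated
  parameter: it is solved numerically (once, at load time) so that the
  ceiling is exactly 93%. The same `beta` (about 2.96) calibrates both
  maps because the two features have identical value distributions over
  the grid.

Rewards are sampled by realising the outcome once per trial
(`y ~ Bernoulli(p)`) and scoring the decision against it, which matches
trial-wise correct/incorrect feedback. A consequence worth noting: the
pair (decision, reward) is a recoding of the realised outcome, so learning
from feedback is exactly logistic regression of the outcome on the
network's pre-sigmoid output.

Trials for model simulations draw stimuli from the *continuous* uniform
distribution over the cue space `[1, 5]^2` (`stimuli = "continuous"`, the
default in `run_config()`); the discrete 25-cell grid shown to human
subjects is available as `stimuli = "grid"`. The continuous choice follows
the modelling protocol's description of inputs drawn uniformly over input
space, and it matters quantitatively: with grid stimuli the MAP optimiser
falls into the trivial constant-output solution noticeably more often,
depressing task-1 accuracy below the reported operating point.

## The value network

The network (see `network_spec()`) has

* a shared linear first hidden layer of `H1` units (`H1 = 1` minimal,
  `H1 = 2` increased capacity) with biases — `W1` defines the learned
  subspace;
* one subnetwork of 4 second-layer units per task, GELU
  (`x * pnorm(x)`, exact, no tanh approximation) for task 1 whose map is
  log-quadratic, linear for task 2 whose map is log-linear in the
  features;
* a sigmoid output per task: `v1 = sigmoid(atilde)`, `v2 = 1 - v1`, the
  values of the two decisions. `atilde` is a single scalar per trial; with
  binary decisions nothing more is needed.

Parameters pack into a single vector `theta` (`pack_params()`), with the
field families kept contiguous (`[vec(W1); vec(W2, per task); output
weights; biases]`). Growing the network for task 2 inserts the new task's
segments; prior statistics are carried across growth by segment name, so
the re-indexing is transparent. Task-2 subnetworks read the shared
first-layer units only; there are no second-layer cross-links between
task subnetworks.

Gradients are computed by backward accumulation. The central quantity is
the *output sensitivity* `eta(i) = d atilde / d theta_i`
(`output_sensitivity()`); the per-trial likelihood gradient is
`(r - v_k) * (+/-) eta` and the diagonal outer-product (Gauss–Newton)
curvature is `sum_t v(1-v) eta^2`. Unit tests pin all of these to central
finite differences at 1e-6 relative error, and the diagonal update to a
dense outer-product Hessian oracle.

## Sequential Bayesian learning

Beliefs over `theta` are a factorised Gaussian (mean `m`, precision
`lambda` per parameter). Learning on a block `R_j` of trials is:

1. **MAP estimation** (`map_estimate()`): ascend the log joint
   `J = log p(R_j | theta) + log p(theta | prior)`.
2. **Laplace precision update** (`laplace_precision_update()`):
   `lambda_j = lambda_{j-1} + sum_t v(1-v) eta^2`, evaluated at the MAP
   estimate on the current block only. Precisions never decrease.
3. The posterior becomes the prior for the next block or task.

In the conjugate linear-Gaussian case this recursion is exactly equivalent
to single-batch learning; `sbl_linear_gaussian()` implements that solvable
case and the test suite verifies sequential-equals-batch to 1e-8, which
pins down the chaining logic. For the nonlinear network the factorised
Laplace step is an approximation and its adequacy is an empirical matter —
that is what the simulation batteries assess.

### Initial prior

Means are zero. Weight precisions follow the fan-in heuristic — units
with more inputs get smaller weights: precision 3 for first-layer weights
(three inputs), `H1` for second-layer weights, 4 for output weights, and 1
for all biases. The heuristic realises the stated qualitative rule with no
free parameters. The exact numbers are not reported in the original study and
absolute accuracies and the size of the posterior contraction are somewhat
sensitive to them; a sensitivity sweep over these precisions (factor-4
range) moved task-1 accuracy by at most a few points, so we fixed the
zero-parameter rule.

### The optimiser

`map_estimate()` implements bounded-line-search gradient ascent with
multistart:

* Each iteration steps along the **normalised** gradient direction; the
  step length is chosen by single-variable bounded minimisation of `-J`
  over `(0, 1]` (`stats::optimize`, the same Brent-style search as
  Matlab's `fminbnd`). Normalising makes the documented `(0, 1]` step bound
  meaningful in parameter units; with raw-gradient steps the same bound
  admits steps of norm 30 or more early in learning, and in our
  experiments that reading visibly depressed the multistart operating
  curve relative to the reported one.
* If no improving step exists within the bound, the bound is halved, up to
  three times (bounds 1, 1/2, 1/4, 1/8); if still no improvement, the run
  stops.
* Convergence is declared when the log joint improves by less than
  `tol = 0.001` (absolute — the simplest reading of a scalar "convergence
  tolerance"; a relative criterion of the same nominal value stops runs
  mid-ascent on joints of magnitude ~80), with at most 64 iterations.
* Initial `theta` is sampled from the prior. If the solution's *average
  trial likelihood* `exp(logL / n)` is below `pc_T = 0.60`, the
  optimisation restarts from a fresh prior sample, up to
  `maxstarts = 3` starts; if none succeeds the start with the highest log
  joint is returned and the run is flagged (kept, not discarded).
* Values are clamped to `[1e-12, 1 - 1e-12]` before logs so the joint
  stays finite.

The posterior landscape genuinely contains a dominant trivial local
maximum (first-layer weights collapse to zero, output constant at 0.5,
accuracy 0.5); roughly three quarters of single starts end there under the
study conditions, which is why the multistart budget controls mean task-1
accuracy and why the batteries show a bimodal run distribution.

## Simulation protocols

* **Over tasks** (`run_over_tasks()`): one 100-trial dataset per task
  mapping (decisions sampled from a prior-initialised network, i.e.
  near-random), MAP + Laplace on task 1 from the initial prior, network
  growth, transfer of the task-1 posterior as the task-2 prior, MAP on
  task 2. Accuracy is the average trial likelihood of each task's own
  training data at its MAP estimate. Datasets are regenerated per
  simulation run; the 40-run averages absorb this extra variance.
* **Over blocks** (`run_over_blocks()`): 250 trials per task in 25-trial
  blocks. Each block is generated on-policy (decisions sampled from the
  network at the current posterior mean) and scored *before* training on
  it (test-then-train), then learned from. The posterior chains across
  blocks and across the task boundary, where the network grows exactly as
  in the over-tasks protocol. Pairs of 25-trial scores are averaged into
  ten 50-trial learning-curve points. The first block of each task is
  scored by a network whose (new) task parameters sit at the prior mean,
  so it scores exactly 0.5 — the model predicts a sharp drop at the task
  boundary.
* **Variants**: minimal capacity (`H1 = 1`), increased capacity
  (`H1 = 2`), and reduced precision (minimal capacity, but carried
  precisions are reset to their initial-prior values at the task
  boundary while the carried means are kept; applied to all task-1
  parameters).
* **Batches** (`run_batch()`): 40 simulations per condition, each on a
  seed derived deterministically from one master seed, so every table is
  reproducible end to end.

Per-task accuracies and the mean posterior/prior precision ratio of the
first-layer weights after task 1 are recorded per run; `transfer_summary()`
computes the full contrast set (means by subspace relation, paired and
independent t tests, per-relation Pearson correlations and their Fisher
r-to-z comparison, all two-sided).

## Problem sizes and runtime

The study conditions are 40 simulations per condition, 100 trials per task
(over tasks) or 250 (over blocks). The acceptance script and the
acceptance test battery run these sizes in full — a few minutes per
battery on one CPU; the unit test suite uses miniature configurations
(tens of trials, 2-run batches) chosen to exercise every code path in
seconds. `analysis/` scripts default to the full sizes and accept
`--n-sims` for quick looks.

## What the generator does and does not emulate

The synthetic environment reproduces the stimulus space, reward structure,
trial counts, block structure and condition pairings of the behavioural
experiment. It does not model reaction times, missed trials, block breaks,
declarative strategy knowledge, or individual differences beyond decision
noise — so agreement between model batteries and reported behavioural
effects speaks to the learning mechanism, not to any of those processes.
Human performance summaries themselves are not recomputable here because
the behavioural dataset is not included; the statistics layer accepts any
table in the same format.

## Known limitations and open choices

* The multistart return rule when no start reaches `pc_T` ("best
  solution") is interpreted as highest log joint, the optimisation
  objective; highest accuracy is the other defensible reading and differs
  only for flagged runs.
* Whether multistart re-samples all parameters or only first-layer weights
  is unspecified; we re-sample all of `theta`.
* Task-2 second-layer activations are linear from the start in over-blocks
  mode (activation is fixed per task identity, not per phase).
* With one hidden unit the two second-layer subnetworks could in principle
  share units; we keep them disjoint per the architecture diagram.
* The mean task-1 accuracy of the minimal network sits a few points below
  the published operating point (~0.59–0.62 versus 0.66 across master
  seeds): within the specified 64-iteration budget our line-search ascent
  rescues slightly fewer starts from the trivial maximum, and successful
  starts plateau slightly lower, than the original study's implementation.
  Sensitivity sweeps over the prior precisions, the line-search tolerance,
  the convergence-test form and the restart scope move this by less than a
  point, so we report it as a known quantitative gap rather than absorb it
  into any parameter.
* The increased-capacity ablation reproduces the direction of the
  published effect (the task-2 same/different gap shrinks markedly
  relative to the minimal network) but not always its full abolition: in
  our batteries the idle first-layer unit retains some posterior
  precision after task 1 — its weights are not driven fully to zero
  within the 64-iteration budget — so a residual negative-transfer
  correlation can survive. Deeper optimisation (256 iterations) does not
  remove it. The reduced-precision ablation abolishes the effect cleanly.
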