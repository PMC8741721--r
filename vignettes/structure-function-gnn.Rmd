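---
title: "Predicting functional connectomes from structural connectomes with message-passing graph networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional connectomes from structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sc2fc)
```

## The problem

Resting-state functional connectivity (FC) — the region-by-region matrix
of Pearson correlations between BOLD timeseries — is constrained but not
determined by structural connectivity (SC), the matrix of white-matter
streamline counts estimated from diffusion tractography.  SC is sparse
and non-negative; FC is dense, signed and bounded in $[-1, 1]$.  `sc2fc`
implements a learned mapping from SC to FC (and from structural to
functional *centrality*) using a message-passing graph network, together
with the full surrounding pipeline: FC preprocessing, statistical
thresholding, graph centrality, training, evaluation and virtual-lesion
analysis.  Because real multi-subject connectome cohorts are
access-gated, the package ships a synthetic cohort generator with a
known ground-truth SC$\to$FC mapping, and every claim the package makes
about itself is validated end-to-end on those cohorts.

## From BOLD timeseries to a functional network

Each session's regional timeseries are z-scored per region (sample SD,
denominator $n-1$), band-pass filtered to 0.01–0.1 Hz, and all sessions
are concatenated before computing Pearson correlations.  Choices the
procedure leaves open, fixed here:

* **Filter family.** A 2nd-order Butterworth band-pass applied
  forward–backward (zero phase; effective order 4), the standard
  resting-state choice.  Edge transients are suppressed by odd
  reflection of the series plus steady-state initial conditions, so a
  constant series filters to numerically zero instead of ringing.
* **Repetition time.** Filtering is undefined without the sampling
  interval; `tr_seconds` defaults to 0.72 s (the common multiband
  protocol value) and is a required property of every timeseries.
* **Order of operations.** z-score, then filter, each session
  separately; then concatenate; then correlate.

Functional graphs are built by a *lower threshold* at the critical
correlation $r^\* = t^\*/\sqrt{\mathrm{df} + t^{\*2}}$, where $t^\*$ is
the two-tailed Student-$t$ critical value at $p = 10^{-4}$ with
$\mathrm{df} = n - 2$; for $n = 4800$ timepoints $r^\* \approx 0.056$.
Entries below $r^\*$ are zeroed, so negative correlations are dropped —
the literal reading of a lower threshold; an `absolute` flag retains
strong negative edges instead.

## Centrality measures

Degree (count of nonzero connections), eigenvector centrality
(principal eigenvector of the adjacency, unit Euclidean norm) and
PageRank (damping 0.85, weight-proportional transitions, dangling mass
redistributed uniformly, values summing to 1).  Defaults mirror the
common graph-library conventions: degree and eigenvector binary,
PageRank weighted; each exposes a `weighted` flag.  Structural
centralities are computed on the raw count matrix (only functional
matrices are thresholded).  Power iteration for eigenvector centrality
runs on $A + I$: the principal eigenvector is unchanged, but the
dominant eigenvalue becomes strictly dominant even on bipartite graphs
(a star graph oscillates forever under plain power iteration).
Centralities are z-scored across regions and affinely rescaled so the
post-z minimum maps to $-1$ and the maximum to $+1$; the four constants
are stored so the map inverts exactly.  Standardization is per subject
(a cohort-level alternative was considered; per-subject keeps subjects
exchangeable and inversion local to each record).

## The network

The model is the encode–process–decode message-passing architecture:
independent edge and node encoders, a recurrent core applied for 10
steps, and a decoder applied to every step's latents.  All update
functions are MLPs with two hidden layers of 16 rectified-linear units;
encoder and core outputs are layer-normalized; decoders are linear.
One message-passing step computes, for every directed edge $k$ from
sender $s_k$ to receiver $r_k$,

$$e'_k = \phi^e([e^0_k, e_k, v^0_{s_k}, v_{s_k}, v^0_{r_k}, v_{r_k}])$$

(the $\cdot^0$ terms are the encoder outputs — a skip connection the
core sees at every step), then aggregates incoming edges per node by
summation, $\rho^{e\to v}_i = \sum_{k:\,r_k = i} e'_k$, and updates

$$v'_i = \phi^v([v^0_i, v_i, \rho^{e\to v}_i]).$$

Graphs carry one directed edge per ordered pair with nonzero SC (an
`all_pairs` mode exists for ablation).  Raw streamline counts are
heavy-tailed, so edge inputs default to $\log(1+c)$ followed by min–max
rescaling to $[0,1]$ per subject.

Two supervised tasks share this trunk:

* **Edge prediction.** Edge inputs = transformed SC; node inputs = 1.0;
  edge targets = the subject's FC values aligned to the directed edge
  list, z-scored and rescaled to $[-1,1]$ across the subject's edge set
  (the stored constants let predictions be *unstandardized* back to
  correlation units before thresholding and derived-centrality
  computation, which reuses the identical empirical code path).
* **Centrality prediction.** Same edges; node inputs = the standardized
  structural centrality of one measure (or all three stacked); node
  targets = the standardized functional centrality.

The loss is the mean over all 10 steps of the MSE against the target —
penalizing every step pushes the network toward solutions reachable in
few steps.  Prediction uses the final step's decoded output.

## Training

Adam with learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-7}$; batch size 32.  Cohorts split 70/10/20 into
train/validation/test by floor-rounding train and validation and giving
the remainder to test (998 subjects $\to$ 698/99/201); an epoch is
$\lfloor n_\text{train}/32 \rfloor$ batches sampled without replacement
(698 $\to$ 21).  The batch gradient is the *mean of per-subject losses*,
implemented exactly via per-row weights on a block-diagonal batched
graph, so gradient scale is batch-size invariant.  Validation loss is
monitored each epoch with the same formula; it influences nothing
(no early stopping).  Every random draw — initialization, split, epoch
shuffles, generator noise — derives from one root seed through a
per-purpose stream scheme, and the epoch streams are indexed by
absolute epoch number, so training can be paused for evaluation and
resumed bit-identically.

Gradients are computed by hand-derived backpropagation through the
recurrent core.  Two numerical details of the *verification* deserve
note.  The loss is piecewise smooth in the parameters (ReLU), so the
finite-difference check skips any coordinate whose $\pm h$ perturbation
flips a hidden unit's activation state — a centered quotient across a
kink estimates neither one-sided derivative.  And the default step is
$h = 10^{-7}$: layer normalization contributes curvature of order
$1/s^3$ with $s = \sqrt{\text{var} + 10^{-6}}$, which makes the
$O(h^2)$ truncation term of central differences visible at
$h = 10^{-5}$.  Hidden biases are initialized with small random offsets
($\sigma = 0.01$) rather than zeros so that no unit sits exactly on its
kink at the starting point.  The forward/backward pass exists twice —
a pure-R reference and a compiled Armadillo fast path — asserted equal
to machine precision in the tests; training and evaluation use the fast
path.

## Evaluation and virtual lesions

Accuracy is reported as $R^2$, the squared Pearson correlation of
predicted versus empirical values (the convention of plotting one
against the other; a coefficient-of-determination option is exposed —
note the squared-correlation form is sign-blind).  *Mean-level* $R^2$
compares element-wise test-set means; *individual-level* $R^2$ pools
all per-subject pairs.  For lesion analysis, each region in turn has
its SC row and column zeroed in every test subject, the task graphs
are rebuilt, and the trained model's multi-step loss (no retraining) is
averaged over test subjects; per-region lesioned loss is then
correlated with group-mean structural degree centrality (Pearson $r$,
$\mathrm{df} = n_\text{regions} - 2$, two-tailed $p$) to ask whether
hubs matter more.

## The synthetic cohorts

The generator emulates what the pipeline needs from a real cohort and
nothing more:

* **Template SC** — nodes uniform in the unit square, a Euclidean MST
  for guaranteed connectivity plus the shortest remaining pairs up to a
  target density of 0.30 (tractography networks are distance-penalized
  and sparse), lognormal weights (median ~30 streamlines,
  $\sigma = 1$), and 3 *planted hubs* wired to ~75% of regions.
* **Subjects** — multiplicative lognormal weight noise
  ($\sigma = 0.1$), edge drop at rate $\sigma/5$ with density-balancing
  additions; dropped bridges are restored so every subject stays
  connected.
* **Ground-truth FC** — with $\hat S$ the strength-normalized SC
  ($D^{-1/2} S D^{-1/2}$): `linear` ($\propto \hat S$),
  `direct_plus_indirect` ($\tanh(4\hat S + 2\hat S^2)$; the default —
  direct connections plus one step of indirect paths, learnable by a
  local message passer and analytically checkable), or
  `communicability_tanh` ($\tanh(2\,e^{\hat S})$ off-diagonal, all
  walks down-weighted by length).  Additive symmetric Gaussian noise
  (SD 0.02), clipped to $[-1,1]$.

What the synthetic cohorts do **not** emulate: hemodynamics, indirect
functional coupling beyond the chosen algebraic maps, heteroscedastic
measurement noise, site/motion artefacts, or realistic atlas geometry.
Passing the recovery benchmarks therefore demonstrates that the
pipeline and learner work as specified — not that any particular $R^2$
will transfer to empirical cohorts.

The standard validation (`edge_recovery_benchmark()`) trains the edge
model on the default cohort (30 regions, 200 subjects) and stops once
mean-level test $R^2 \ge 0.8$, within a 300-epoch budget; it also
reports a *subject-blind baseline* — the individual-level $R^2$ of
predicting every test subject with the training-mean FC.  Because
subjects share most of their structure, that baseline is high
(~0.93–0.95); a model only earns its keep by beating it with
subject-specific structure, and it does.  `hub_lesion_benchmark()`
(20 regions, 3 hubs, 50 subjects, 60 epochs at batch 16) checks that
lesion importance correlates positively with structural degree and
that the planted hubs rank in the top half of importance.

## Numerical choices and degenerate inputs

* Matrix symmetry tolerance $10^{-8}$ with averaging repair below it
  (absorbs text round-trips, refuses real asymmetry); diagonals forced
  to zero; full-precision (17 significant digits) text serialization so
  write–read is the identity.
* Eigenvector centrality errors on edgeless graphs and on
  non-convergence; PageRank handles dangling nodes by uniform
  redistribution; the lesion correlation is reported as `NA` when fewer
  than 3 regions are lesioned.
* Standardization refuses constant vectors; FC computation refuses
  zero-variance regions; Adam fails fast on non-finite gradients.
* Problem sizes used in the shipped validation: recovery at 30
  regions / 200 subjects, hub-lesion at 20 regions / 50 subjects, both
  chosen as the smallest cohorts that still separate signal from noise
  cleanly at the generator's default noise level.

## Limitations

The model treats each subject's graph independently and learns a
population mapping; it does not model session-to-session variability
within subject.  The sparse edge set means structurally absent pairs
are predicted as zero FC; the `all_pairs` mode lifts this at quadratic
cost.  Sign-blind $R^2$ overstates agreement if a model anticorrelates
with the target (the `cod` option guards against this).  Training is
CPU-only by design; cohort sizes in the hundreds and atlases up to
~100 regions are comfortable, voxel-level graphs are out of scope.
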