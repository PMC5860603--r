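---
title: "Gaussian-mixture HMM genome segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-mixture HMM genome segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Semi-automated genome annotation partitions a genome into segments, each
carrying one of $K$ unsupervised labels, from one or more real-valued
signal tracks (ChIP-seq or DNase-seq fold enrichment and the like).
Labels are interpreted biologically afterwards — one may behave like
"enhancer", another like "facultative heterochromatin". `sagahmm`
implements the full workflow: signal input and binning, model fitting,
Viterbi annotation, and two evaluation procedures (per-label
Kolmogorov–Smirnov goodness of fit, and TSS active/inactive
discrimination), plus a synthetic-genome generator so everything is
testable without downloads.

## The model

Observations are binned signal values $x_{it}$ for bin $i$ and track
$t$ at a working resolution of $r$ base pairs per bin (default 1).
Hidden labels $z_i \in \{1..K\}$ follow a Markov chain; given
$z_i = l$, tracks are conditionally independent with Gaussian-mixture
emissions

$$p(x_{it} \mid z_i = l) = \sum_{c=1}^{C} w_{ltc}\,
  \mathcal{N}(x_{it};\, \mu_{ltc},\, \sigma^2_{tc}).$$

There are $C$ means per (label, track) pair but only $C$ variances per
track: variances are **tied across labels** per (track, component).
With $C = 1$ this reduces to the classic single-Gaussian emission with
one variance per track, which may additionally be frozen
(`fixed_variance`). Missing cells (`NA`) marginalize out: a missing
track simply contributes nothing to the bin's emission density, and a
fully missing bin contributes only transition structure.

Segment lengths are geometric (the Markov chain's native law) shaped by
two constraints:

* a **hard minimum length** $m$ (bins), realized by expanding each
  label into $m$ duration-phase states — phases $1..m{-}1$ advance
  deterministically, phase $m$ carries the label-level transition row;
* a **soft expected length** $L$ (bins), entering through the
  initial/simulated self-transition probability $1 - 1/L$ and, if
  `transition_prior > 0`, through a pseudocount prior on the
  transition rows.

The hard constraint is relaxed at chunk boundaries (initial mass enters
at phase $m$; any phase may end a chunk), so a segment may be truncated
by a chunk edge and chunked inference composes over the genome. The
phase expansion is our realization of "geometric plus hard and soft
constraints"; other mechanizations of the same idea exist and are not
guaranteed to be parameter-for-parameter identical.

Inference on a chunk is exact: log-domain forward–backward for the
marginal likelihood and E-step statistics, log-domain Viterbi for
decoding, both over the phase-expanded state space, implemented in
C++ with log-sum-exp throughout so underflow is structurally
impossible. Viterbi ties break deterministically towards the lowest
state index.

## Training

The genome is binned, cut into fixed-size chunks (`chunk_size` bins,
never spanning a chromosome boundary), and split into a training pool
and a held-out validation set of whole chunks drawn at random until
they first reach the requested fraction of genome bins (default 1.5%).
Whole chunks keep the training and validation likelihoods on the same
inference unit.

Two EM regimes:

* **fixed**: one region set sampled per instance at round 0; training
  likelihood is then monotone non-decreasing and the instance may stop
  early (relative change < `tol` for two consecutive rounds);
* **minibatch**: a *fresh* random region set every round (default 1% of
  genome bins per round), re-drawn independently across rounds, never
  touching validation. There is no convergence guarantee, so after
  every round the validation likelihood of the updated parameters is
  recorded, and the final parameters are those of the (instance, round)
  pair with the maximal validation likelihood — not necessarily the
  last round.

Likelihoods are reported in nats per bin (bins with at least one
observed track), so rounds with different region sizes and the
validation set are directly comparable; a plot of per-round totals
would differ from ours only by these normalizations.

M-step updates are closed-form: responsibility-weighted means per
(label, track, component); variances pooled across labels per (track,
component) and floored at $10^{-4}$ times the global per-track data
variance; weights from responsibilities; transition rows and the
initial distribution from expected counts (for $m > 1$, only genuine
label-level transition events at phase $m$ are counted, not forced
phase advances).

Two regularizers are available but **off by default**:
`weight_pseudocount` (symmetric Dirichlet on mixture weights) and
`transition_prior` (soft-length pseudocounts on transition rows). We
keep the default M-step pure maximum likelihood because MAP-EM with
pseudocounts does not guarantee monotone raw-likelihood ascent near
convergence, and monotone fixed-regime training is a property we test
to 1e-9; component death — the failure mode pseudocounts guard
against — is handled instead by re-seeding any label whose total
responsibility reaches zero (jittered data quantiles, with a message).

Randomness is organized as named child streams of one master seed
(validation split, per-instance initialization, per-round minibatch),
so a fixed seed gives bit-identical parameters, traces and BED output,
and adding instances does not perturb existing ones. Initialization
draws component means from jittered per-track data quantiles, sets
variances to the per-track data variance, uniform weights, and
self-transition $1 - 1/L$.

## Annotation and evaluation

`annotate_genome()` (or `predict()` on the fit) Viterbi-decodes every
chunk and stitches per-bin paths into maximal same-label segments,
merging equal labels across chunk joins; the merge is cosmetic —
inference stays per-chunk, so boundaries exactly at chunk joins are
approximate.

Goodness of fit per label: the empirical distribution of all datapoints
assigned to a label is compared with the label's theoretical mixture
CDF by the one-sample KS statistic
$D = \max_i \max(i/n - F(x_{(i)}),\, F(x_{(i)}) - (i-1)/n)$; smaller is
better. We compute $D$ on the same values the model was trained on
(the statistic is invariant under monotone transforms applied
consistently, so any prior signal transform cancels). `qq_points()`
exports paired quantiles for QQ plots. All of a label's datapoints are
used by default, with an optional seeded cap for very large genomes.

TSS discrimination: given single-base positive (activity-supported) and
negative TSS positions — reduced to one most-upstream TSS per gene,
strand-aware, by `most_upstream_tss()` — each label's segments are
treated as predictions: TP/FP are positives/negatives overlapped by the
label, FN positives overlapped by *other* labels; TSSs covered by no
segment are counted and reported separately. The best-precision label
is reported with its recall (ties: higher recall, then lower index).

## The synthetic generator

`simulation_spec()` + `random_params()` + `simulate_genome()` generate
a ground-truth model and genome with exactly the structure the model
assumes: Markov label paths with run lengths $m - 1 +$ Geometric$(1/L)$,
mixture emissions with label-tied variances, and i.i.d. missing cells.
Component means sit on a jittered grid guaranteeing pairwise separation
of at least `mean_separation` standard deviations, so scenarios are
identifiable by construction. `bimodal_params()` is a named preset —
one track, two well-separated modes per label — exercising the case
where single-Gaussian emissions must fail. Default conditions follow
the tool's conventions (1% minibatch fraction, 1.5% validation, 100
rounds, 10 labels) and, for the recovery scenario, a 10^5-bin
chromosome at 10 bp with 3 labels, 2 tracks, 2 components, 3-sd
separation, expected length 50 bins and 5% missing cells.

What the generator does **not** emulate: spatially correlated coverage
artifacts, mappability and copy-number structure, heavy-tailed or
discrete count noise, replicate structure, and any dependence between
tracks beyond the shared label. Passing tests therefore demonstrate
correctness of the method under its own assumptions, not performance on
real chromatin data.

## Numerical and design choices

* 0-based half-open coordinates everywhere (BED convention); bins are
  $[ir, (i+1)r)$; a chromosome's last bin may be partial and is
  averaged over the bases it covers.
* Overlapping bedGraph intervals are a hard error — malformed input
  must not silently change results.
* Bins covered by a single interval take its value verbatim, so
  simulated bedGraph round-trips bit-exactly; multi-interval bins take
  the coverage-weighted mean.
* Parameters serialize to versioned structured text at `%.17g`
  precision (bit-exact round trips); the observation store persists as
  a versioned binary container keyed by chunk id.
* Validation-region placement is random whole chunks (the alternative —
  one contiguous block — would confound the held-out estimate with
  regional composition).
* The held-out criterion is the data log-likelihood of the learned
  parameters on validation chunks (the natural reading of evaluating
  parameters on held-out data).
* The winner is the global argmax over all instances and rounds, ties
  going to the earliest (instance, round).
* Mixture weights are learned per (label, track) pair; whether weights
  should be shared across tracks is a modelling interpretation, and
  per-pair is the more expressive choice.
* Test problem sizes (10^5-bin recovery genome, 8×10^4 bp bimodal
  genome, 6-block heterogeneous genome, 200-model enumeration sweeps)
  were chosen so the full suite documents the method's properties in
  under a minute on one core.

## Known limitations

* Winner parameters in minibatch mode come from a single round's
  M-step, so they carry that minibatch's sampling noise (roughly
  $\sigma/\sqrt{n_c}$ per component mean, with $n_c$ the component's
  effective bin count in the round); on marginal scenarios this
  dominates recovery error. Averaging over final rounds would reduce
  it but would no longer be winner selection, so we do not.
* For $m > 1$ the state space grows as $K m$; inference cost is
  $O(n K^2 m^2)$ per chunk worst case.
* Exhaustive label matching in `best_label_matching()` is factorial in
  $K$ and capped at $K \le 8$; it is an evaluation aid, not part of the
  method.
* Posterior (soft) decoding, sub-label hierarchies and semi-supervised
  seeding are out of scope.
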