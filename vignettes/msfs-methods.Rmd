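---
title: "Silhouette-guided feature separability regularization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-guided feature separability regularization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfs)
```

## The problem

Motor-imagery EEG decoders are usually adapted to a new user by pretraining
on pooled recordings from other subjects and fine-tuning on the user's own
calibration trials. With only a handful of labeled target trials, CE-only
fine-tuning over-adapts: feature dimensions of the penultimate layer that
carried class structure after pretraining drift, and dimensions that carry
none begin to influence the classifier. This package implements a
feature-level auxiliary objective (MSFS, maximizing single-feature
separability) that counteracts that drift during fine-tuning, together with
the full transfer protocol needed to measure its effect.

## The regularizer

For a mini-batch with feature matrix $Z \in \mathbb{R}^{N \times F}$ (the
input of the final dense layer) and labels $y_i \in \{1..K\}$, each feature
dimension $f$ is treated as a one-dimensional embedding with absolute
distance $d_f(i, k) = |z_{i,f} - z_{k,f}|$. The silhouette score of sample
$i$ in dimension $f$ is

$$ s_i = \frac{b_i - a_i}{\max(a_i, b_i)}, $$

with $a_i$ the mean distance to own-class members (excluding $i$) and $b_i$
the minimum over other classes of the mean distance to that class. For every
$(i, f)$ the search `optPosSil()` considers relocating $z_{i,f}$ to each
existing batch value $z_{j,f}$, with all other samples fixed, and selects
the candidate that maximizes the relocation silhouette. The selected values
form a target matrix $t$, and the auxiliary loss is the mean squared
deviation

$$ L_{pos} = \frac{1}{NF} \sum_{i,f} (z_{i,f} - t_{i,f})^2 , $$

added to the cross-entropy behind a hard gate:

$$ L = L_{CE} + \omega \cdot \mathbf{1}[L_{CE} < Loss_{min}] \cdot L_{pos}. $$

The search is vectorized per feature through the pairwise distance tensor
$D[f, j, k]$, giving $O(FN^2)$ time and memory per batch
(`pairwiseAbsDistance()`, `relocatedSilhouette()`). Because the targets
depend on batch composition and batches are reshuffled each epoch, the
auxiliary objective is stochastic across iterations; this is a feature, not
an artifact — a fixed target configuration would invite convergence to it.

Key semantics, and why:

* **Gate** — strict inequality; a batch whose cross-entropy equals the
  threshold keeps the gate closed, so `lossMin = 0` is an exact off-switch.
  The gate is evaluated per batch on that batch's detached CE value, with no
  running average, matching the per-batch structure of the training loop.
* **Skip rule** — batches with fewer than two classes, or any present class
  with fewer than two samples, make $a_i$ or $b_i$ ill-defined; such batches
  optimize cross-entropy only and never raise.
* **Zero denominator** — when $\max(a_i, b_i) = 0$ (all relevant values
  coincide) the silhouette is defined as 0, the standard convention.
* **Candidate set** — all $N$ batch values, including the sample's own
  position; consequently the selected silhouette never falls below the
  current one, and a batch already at an optimum has $t = Z$ and
  $L_{pos} = 0$ exactly.
* **Tie-breaking** — among candidates within $10^{-9}$ of the maximal
  silhouette, the value closest to the current value wins, then the lowest
  candidate index. The tolerance absorbs floating-point summation-order
  differences between the vectorized path (BLAS matrix products) and the
  brute-force oracle (`optPosBrute()`, plain loops over the definitional
  formulas); both paths apply the same convention, and the suite checks
  elementwise equality of the two searches on batches with deliberately
  induced duplicate values.
* **Detached targets** — $t$ is a constant for gradient purposes. The
  argmax that produced it is not differentiated through; features are pulled
  toward fixed positions, a regression-style constraint.
* **Class means in the relocation silhouette** — the between-class mean for
  a candidate position includes the candidate's own coincident batch member
  at distance zero. This follows the vectorized formulation used throughout
  (class sums of rows of $D$); the brute-force oracle makes the same choice,
  so the two are comparable. Deduplicating candidates would change the
  reported argmax index but never the returned target value, given the
  tie-break above.

Two approximations extend the search to larger batches or wider feature
layers: `optPosSilSubsampled()` evaluates at most `m` candidate values per
class (plus the sample's own position; exact whenever `m` covers the largest
class), and `topkFeatureMask()` restricts the position loss to the `k`
feature dimensions with the highest mean current silhouette — the ranking
statistic is the mean per-sample 1D silhouette at current positions, chosen
because it is the same quantity the search maximizes.

## The model contract and the reference backbone

All training code sees models only through a small contract: a `forward`
map from an `N x C x T` batch to `(logits, features)` plus an analytic
`backward`. Any backbone honoring the contract can be plugged in unchanged
(the suite demonstrates this with a trivial linear model). Multi-branch
architectures are supported by `branchAverage()` (elementwise mean of branch
logits — the final class score) and `branchPositionLoss()` (targets computed
independently per branch on its own feature layer, losses averaged; the
symmetric treatment mirrors the logit averaging). The gate uses the CE of
the averaged logits, since that is the quantity the classifier is judged by.

`referenceBackbone()` is a compact trainable network for desk-scale
experiments: a bank of temporal convolution filters shared across channels
(initialized as Hann-windowed sinusoids at random frequencies — a learnable
band-pass bank, which conditions the power path far better than white-noise
filters), a linear spatial projection, squaring, mean pooling over
`nSegments = 4` contiguous time windows, and a log transform, followed by a
linear feature layer and a dense classifier head. Segment-wise (rather than
whole-trial) pooling is essential: the class signal of motor imagery is a
*change* of band power after the cue, which global pooling averages away.
The `1e-4` floor inside the log guards the zero-power corner. Optimization
is Adam (lr 0.001, weight decay 0.009 folded into the gradient, batch size
from the plan), the settings fixed throughout the protocol. The backbone is
deliberately small (about 1.5k parameters) and is a reference
implementation of the contract, not a re-implementation of any published
EEG architecture.

## The transfer protocol

For each target subject, `pretrain()` trains on the pooled training trials
of all other subjects with cross-entropy only; `finetuneMsfs()` then adapts
on the target's training split with the gated objective. Strategies:
`tl` (CE-only fine-tuning), `tl_msfs` (gated silhouette targets),
`rand_pos` (targets drawn uniformly within each feature's batch range —
keeps the loss form, removes the separability criterion), `msfs_nogate`
(silhouette targets applied throughout fine-tuning), and `original` (no
pretraining; a fresh model trained CE-only on the target fit set for
`ep + ef` epochs, so it receives the same total epoch budget as the
pretrain-plus-fine-tune path). Few-shot budgets subsample the target
training split per class (`stratifiedSubsample()`: floor of the fraction,
at least one trial per class). Hyperparameters are selected by
`selectHyperparameters()` on a class-balanced half split of the target
training trials (odd counts give the extra trial to the fit side),
maximizing mean validation accuracy across subjects with ties resolved in
grid order. Test trials never enter any fit or validation path.

Randomness is structured: every user-facing seed derives per-purpose
streams (model initialization, per-epoch shuffling, random targets, splits,
subsampling). Shuffling and random-target draws use independent streams, so
ablation arms see identical batch sequences and a run with `omega = 0`,
`lossMin = 0` or strategy `none` reproduces CE-only fine-tuning bit for
bit. Three independent runs per configuration is the reporting default;
the benchmark below uses ten.

## The synthetic population

`generateSyntheticSubjects()` emulates the statistical skeleton of a
multi-subject motor-imagery study: each trial is 1/f-shaped background
noise (10 uV) plus a 10 Hz rhythm (20 uV) on all channels; after the cue
(0.5 s into the trial) the rhythm's amplitude on the channel subset
assigned to the trial's class is attenuated by `effectSize` — an
event-related-desynchronization-like, lateralized power drop. Each subject
applies its own per-channel log-normal gain and DC offset (scale
`subjectShift`), emulating inter-subject variability. Under the defaults
(`effectSize = 0.4`, `subjectShift = 0.15`) the task is decodable well
above chance within subject while naive cross-subject transfer is
measurably worse — the regime in which transfer learning and its
regularization matter. With `effectSize = 0` the class signal vanishes and
band-power classifiers perform at chance (a property the suite checks).

What the generator does *not* emulate: realistic channel covariance and
volume conduction, artifacts (ocular, muscular), non-stationarity within a
session, multi-band structure, and the trial counts of real benchmarks.
Passing the package's tests therefore demonstrates the correctness of the
machinery and the direction of the transfer and regularization effects
under controlled conditions — not effect sizes on real EEG.

## Reference study conditions

The fixed desk-scale benchmark (`benchmarkConfig()`): 4 subjects, 2
classes, 6 channels, 100 Hz, 1.5 s trials (T = 150), 16 trials per class
per subject. Each subject is half-split into train/test; the main arms
fine-tune on the full training half (8 trials per class), few-shot arms on
25% and 50% of it. The plan is 60 pretraining epochs, 200 fine-tuning
epochs, batch size 8, Adam at lr 0.001 / weight decay 0.009; the gate is
$\omega = 1$, $Loss_{min} = 0.2$. Ten run seeds, each redrawing the
population and all training randomness; one seed covers a full
leave-one-subject-out rotation with the pretraining shared across arms.
These sizes keep a full benchmark under ten minutes on one CPU core while
leaving the gate's dynamics intact: fine-tuning crosses the gate threshold
partway through, so the regularizer acts exactly where intended. Epoching
fidelity is checked separately at the canonical 250 Hz / 4.5 s geometry
(T = 1125).

## Known limitations

* The reference backbone is linear after the log-power stage; tasks whose
  class structure lives in feature interactions will understate what larger
  backbones can do — and the regularizer itself is expected to be less
  helpful when discrimination arises primarily from such interactions.
* The exact search is $O(FN^2)$ per batch; for wide feature layers or large
  batches use the subsampled search or the top-k mask.
* The epoched-trial container uses R's native serialization; it is
  lossless and keyed (X, y, fs, subject, channels) but not
  language-neutral. Continuous recordings read by any means can be epoched
  with `epochTrials()`.
* Gate behavior depends on the scale of the cross-entropy and hence on K;
  thresholds tuned for one class count do not transfer automatically.
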