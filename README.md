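# msfs — silhouette-guided feature separability for EEG transfer learning

Adapting a motor-imagery EEG decoder to a new user usually means
pretraining on pooled recordings of other subjects and fine-tuning on the
user's few calibration trials. CE-only fine-tuning over-adapts: feature
dimensions of the penultimate layer that separated the classes after
pretraining drift away. `msfs` implements **maximizing single-feature
separability (MSFS)** — a plug-in auxiliary loss that, for every feature
dimension, pulls each sample toward the batch feature value maximizing its
one-dimensional silhouette score

s_i = (b_i − a_i) / max(a_i, b_i),

where a_i is the mean intra-class distance and b_i the minimum mean
inter-class distance under the absolute distance |z_if − z_kf|. The
selected values form a batch-dependent target matrix t, and the objective is
the hard-gated composite

L = L_CE + ω · 1[L_CE < Loss_min] · L_pos,  L_pos = (1/NF) Σ (z_if − t_if)².

The target search is vectorized through the per-feature pairwise distance
tensor (O(FN²) per batch) and verified elementwise against a brute-force
oracle. The package ships the full protocol around the loss: a compact
trainable reference backbone with analytic gradients, pretrain /
fine-tune / leave-one-subject-out evaluation, few-shot subsampling,
random-target and no-gating ablations, paired Wilcoxon reporting, trial
epoching, an epoched-trial container, and a synthetic multi-subject EEG
generator so everything runs without downloads.

## Worked example

```r
library(msfs)

# a 4-subject synthetic population with ERD-like class structure
subjects <- generateSyntheticSubjects(SynthSpec(seed = 1))

# leave-one-subject-out: pretrain on the others, fine-tune on the target
plan <- TransferPlan()            # ep 60, ef 200, batch 8, Adam 1e-3 / wd 9e-3
gate <- GateConfig(omega = 1, lossMin = 0.2)
res  <- losoTransfer(subjects, plan, gate,
                     strategies = c("tl", "tl_msfs"), seed = 1)
aggregate(accuracy ~ strategy, res, mean)
#>   strategy accuracy
#> 1       tl 0.687500
#> 2  tl_msfs 0.734375
```

Each row of `res` is one target subject's held-out test accuracy (mean
shown). `tl` is CE-only fine-tuning of the pretrained backbone; `tl_msfs`
adds the gated silhouette regularizer during fine-tuning. On this seed the
regularizer lifts mean accuracy by about five points; single seeds are
noisy, so the benchmark below averages such runs over ten seeds.

The silhouette machinery is usable on its own:

```r
fb <- FeatureBatch(matrix(c(0, 0.1, 5, 0.9), 4, 1), c(1, 1, 2, 2))
optPosSil(fb)       # sample 4 (value 0.9) is pulled to its classmate at 5
silhouette1d(c(0, 2, 1, 3), c(1, 1, 2, 2))
#> [1]  0.0 -0.5 -0.5  0.0
```

A thin command-line front end over the same functions lives in
`inst/scripts/msfs-cli.R` (verbs `synth`, `pretrain`, `finetune`, `loso`,
`fewshot`, `ablate`, `report`).

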