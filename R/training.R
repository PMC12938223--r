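# Mini-batch training engine shared by pretraining and fine-tuning.
#
# Per epoch the trial order is reshuffled (its own random stream), then per
# batch: forward, cross-entropy, and — only during fine-tuning with an
# active strategy — the gated position loss. Random target positions draw
# from a second, independent stream so ablation arms see identical shuffles.
trainEngine <- function(model, X, y, epochs, batchSize, lr, weightDecay,
                        gate = NULL, targetFn = "none",
                        gating = c("gated", "always_on"), seed = 1L,
                        recordTargets = FALSE) {
  gating <- match.arg(gating)
  if (!targetFn %in% c("none", "opt_pos_sil", "rand_pos"))
    stop("unknown target strategy '", targetFn,
         "'; valid: none, opt_pos_sil, rand_pos", call. = FALSE)
  n <- dim(X)[1]
  if (n < 1L) stop("empty training set", call. = FALSE)
  y <- as.integer(y)
  shuffleStream <- rngStream(seed, 1L)
  randStream <- rngStream(seed, 2L)
  opt <- adamInit(model$params)
  hist <- list()
  targetsSeen <- list()
  om <- if (is.null(gate)) 0 else omega(gate)
  lm <- if (is.null(gate)) 0 else lossMin(gate)
  step <- 0L
  for (e in seq_len(epochs)) {
    perm <- streamEval(shuffleStream, sample.int(n))
    chunks <- split(perm, ceiling(seq_along(perm) / batchSize))
    for (ch in chunks) {
      Xb <- X[ch, , , drop = FALSE]
      yb <- y[ch]
      fwd <- model$forward(model$params, Xb)
      ce <- ceLoss(fwd$logits, yb)
      dLogits <- ceGrad(fwd$logits, yb)
      dFeatures <- fwd$features * 0
      lpos <- 0; applied <- FALSE
      wantMsfs <- targetFn != "none" &&
        (gating == "always_on" || ce < lm) &&
        batchIsMsfsEligible(yb)
      if (wantMsfs) {
        fb <- FeatureBatch(fwd$features, yb)
        tg <- if (targetFn == "opt_pos_sil") optPosSil(fb)
              else randPos(fb, randStream)
        lpos <- positionLoss(fwd$features, tg)
        # targets are constants; only the features receive gradient
        dFeatures <- (2 * om / length(fwd$features)) * (fwd$features - tg)
        applied <- om > 0
        if (recordTargets) targetsSeen[[length(targetsSeen) + 1L]] <- tg
      }
      total <- ce + if (wantMsfs) om * lpos else 0
      grads <- model$backward(model$params, Xb, fwd$cache, dLogits, dFeatures)
      upd <- adamStep(model$params, grads, opt, lr, weightDecay)
      model$params <- upd$params
      opt <- upd$state
      step <- step + 1L
      hist[[step]] <- data.frame(epoch = e, step = step, ce = ce,
                                 lpos = lpos, gate_open = wantMsfs,
                                 applied = applied, total = total)
    }
  }
  model$history <- if (length(hist)) do.call(rbind, hist) else NULL
  if (recordTargets) attr(model, "targets") <- targetsSeen
  model
}

datasetXY <- function(data) {
  if (is(data, "EpochedDataset"))
    list(X = trialArray(data), y = trialLabels(data))
  else if (is.list(data) && !is.null(data$X) && !is.null(data$y))
    list(X = data$X, y = as.integer(data$y))
  else stop("data must be an EpochedDataset or a list(X, y)", call. = FALSE)
}

#' Pretrain a model on pooled source subjects
#'
#' Cross-entropy-only training for `ep` epochs with per-epoch shuffling and
#' the plan's fixed optimizer settings. With `ep = 0` the model is returned
#' unchanged. Deterministic for a fixed seed.
#'
#' @param model a `featureModel`.
#' @param data pooled source data: an [EpochedDataset-class] (see
#'   [poolDatasets()]) or a `list(X, y)`.
#' @param plan a [TransferPlan-class].
#' @param seed training seed (shuffling).
#' @return the trained `featureModel`; `model$history` holds the per-step
#'   loss log.
#' @export
pretrain <- function(model, data, plan, seed = 1L) {
  d <- datasetXY(data)
  if (dim(d$X)[1] < 1L) stop("empty source set", call. = FALSE)
  trainEngine(model, d$X, d$y, epochs = plan@ep, batchSize = plan@batchSize,
              lr = plan@lr, weightDecay = plan@weightDecay, seed = seed)
}

#' Fine-tune with the gated feature-separability regularizer
#'
#' Runs `ef` epochs of mini-batch training on the target subject's data.
#' Per batch, the cross-entropy is computed first; if the strategy is active
#' (`gated`: batch cross-entropy strictly below the gate threshold;
#' `always_on`: unconditionally) and the batch is eligible (at least two
#' classes, each with at least two samples), targets are computed by the
#' selected strategy and `omega` times the position loss is added before
#' backpropagation. Ineligible batches, and batches with the gate closed,
#' optimize cross-entropy only. Targets are batch-dependent, so the
#' per-epoch reshuffle makes the auxiliary objective stochastic.
#'
#' @param model a `featureModel` (typically pretrained).
#' @param data target-subject training data: [EpochedDataset-class] or
#'   `list(X, y)`.
#' @param plan a [TransferPlan-class] (uses `ef`, `batchSize`, `lr`,
#'   `weightDecay`).
#' @param gate a [GateConfig-class].
#' @param targetFn target strategy: `"opt_pos_sil"` (silhouette-optimized),
#'   `"rand_pos"` (uniform within batch range), or `"none"` (cross-entropy
#'   only).
#' @param gating `"gated"` (default) or `"always_on"` (no-gating ablation).
#' @param seed training seed.
#' @param recordTargets record the per-batch target matrices in
#'   `attr(model, "targets")` (diagnostics).
#' @return the fine-tuned `featureModel` with per-step history.
#' @export
finetuneMsfs <- function(model, data, plan, gate = GateConfig(),
                         targetFn = c("opt_pos_sil", "rand_pos", "none"),
                         gating = c("gated", "always_on"), seed = 1L,
                         recordTargets = FALSE) {
  targetFn <- match.arg(targetFn)
  gating <- match.arg(gating)
  d <- datasetXY(data)
  trainEngine(model, d$X, d$y, epochs = plan@ef, batchSize = plan@batchSize,
              lr = plan@lr, weightDecay = plan@weightDecay, gate = gate,
              targetFn = targetFn, gating = gating, seed = seed,
              recordTargets = recordTargets)
}

#' Class-balanced half split
#'
#' Splits trial indices within each class into two near-equal parts by a
#' seeded random permutation; odd class counts give the extra trial to the
#' fit set. Used for hyperparameter selection on the target training set.
#'
#' @param y integer class labels.
#' @param seed split seed.
#' @return list with integer index vectors `fit` and `validation`; together
#'   they partition `seq_along(y)`.
#' @export
balancedHalfSplit <- function(y, seed = 1L) {
  y <- as.integer(y)
  if (any(tabulate(y)[unique(y)] < 2L))
    stop("every class needs >= 2 trials to split", call. = FALSE)
  fit <- integer(0); val <- integer(0)
  withSeed(seed, {
    for (q in sort(unique(y))) {
      idx <- which(y == q)
      idx <- idx[sample.int(length(idx))]
      nFit <- ceiling(length(idx) / 2)
      fit <- c(fit, idx[seq_len(nFit)])
      val <- c(val, idx[-seq_len(nFit)])
    }
  })
  list(fit = sort(fit), validation = sort(val))
}

#' Stratified few-shot subsampling
#'
#' Selects `floor(fraction * n_q)` trials per class (at least one) uniformly
#' without replacement, preserving class balance in proportion. Models the
#' limited-calibration regime where only a fraction of the target subject's
#' labeled trials is available.
#'
#' @param y integer class labels.
#' @param fraction labeled-data budget in `(0, 1]`.
#' @param seed sampling seed.
#' @return sorted integer vector of selected trial indices.
#' @export
stratifiedSubsample <- function(y, fraction, seed = 1L) {
  y <- as.integer(y)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  keep <- integer(0)
  withSeed(seed, {
    for (q in sort(unique(y))) {
      idx <- which(y == q)
      k <- max(1L, floor(fraction * length(idx)))
      keep <- c(keep, if (k >= length(idx)) idx else sample(idx, k))
    }
  })
  sort(keep)
}

#' Half split of an EpochedDataset into train and test trials
#'
#' Stratified per class with the half-split convention (odd counts: extra
#' trial to the training side).
#'
#' @param ds an [EpochedDataset-class].
#' @param seed split seed.
#' @return list with [EpochedDataset-class] elements `train` and `test`.
#' @export
splitDataset <- function(ds, seed = 1L) {
  sp <- balancedHalfSplit(trialLabels(ds), seed)
  list(train = ds[sp$fit], test = ds[sp$validation])
}

#' Pool several EpochedDatasets into one
#'
#' Concatenates trials along the first axis; sampling rates and channel
#' counts must agree.
#'
#' @param dss list of [EpochedDataset-class] objects.
#' @param subject identifier for the pooled object.
#' @return an [EpochedDataset-class].
#' @export
poolDatasets <- function(dss, subject = "pool") {
  stopifnot(length(dss) >= 1L)
  fs <- unique(vapply(dss, samplingRate, numeric(1)))
  dims <- unique(lapply(dss, function(d) dim(trialArray(d))[2:3]))
  if (length(fs) != 1L || length(dims) != 1L)
    stop("datasets must share fs, channel count and trial length",
         call. = FALSE)
  n <- sum(vapply(dss, nTrials, numeric(1)))
  X <- array(0, c(n, dims[[1]][1], dims[[1]][2]))
  y <- integer(n)
  at <- 0L
  for (d in dss) {
    k <- nTrials(d)
    X[at + seq_len(k), , ] <- trialArray(d)
    y[at + seq_len(k)] <- trialLabels(d)
    at <- at + k
  }
  EpochedDataset(X, y, fs, subject = subject,
                 channels = channelNames(dss[[1]]))
}

freshModel <- function(template, seed) {
  builders <- backboneBuilders()
  args <- template$meta$args
  args$seed <- seed
  do.call(builders[[template$meta$builder]], args)
}

predictLabels <- function(model, X) {
  out <- modelForward(model, X)
  max.col(out$logits, ties.method = "first")
}

# One fine-tuning arm starting from a pretrained model (or fresh weights for
# the no-pretraining reference) and its test accuracy.
runArm <- function(strategy, pretrained, template, fitData, testData, plan,
                   gate, seed) {
  model <- switch(strategy,
    original = {
      # no source pretraining: fresh weights, CE only, same total epoch
      # budget as the pretrain + fine-tune path
      m <- freshModel(template, deriveSeed(seed, 11))
      planCE <- plan; planCE@ef <- plan@ep + plan@ef
      finetuneMsfs(m, fitData, planCE, gate, targetFn = "none", seed = seed)
    },
    tl = finetuneMsfs(pretrained, fitData, plan, gate, targetFn = "none",
                      seed = seed),
    tl_msfs = finetuneMsfs(pretrained, fitData, plan, gate,
                           targetFn = "opt_pos_sil", seed = seed),
    rand_pos = finetuneMsfs(pretrained, fitData, plan, gate,
                            targetFn = "rand_pos", seed = seed),
    msfs_nogate = finetuneMsfs(pretrained, fitData, plan, gate,
                               targetFn = "opt_pos_sil",
                               gating = "always_on", seed = seed),
    stop("unknown strategy '", strategy, "'; valid: original, tl, tl_msfs, ",
         "rand_pos, msfs_nogate", call. = FALSE))
  pred <- predictLabels(model, trialArray(testData))
  evaluateAccuracy(pred, trialLabels(testData))
}

#' Leave-one-subject-out transfer evaluation
#'
#' For each subject in turn: the remaining subjects' training trials are
#' pooled for cross-entropy pretraining, the target's training split is
#' (optionally subsampled and) used for fine-tuning under each requested
#' strategy, and accuracy is measured on the target's held-out test split.
#'
#' @param subjects list of [EpochedDataset-class] objects, one per subject
#'   (`>= 2`); each is half-split into train/test internally.
#' @param plan a [TransferPlan-class].
#' @param gate a [GateConfig-class].
#' @param strategies character vector from `original`, `tl`, `tl_msfs`,
#'   `rand_pos`, `msfs_nogate`.
#' @param budget labeled-data fraction of the target training split used
#'   for fine-tuning (stratified; default 1).
#' @param seed run seed; all internal seeds derive from it.
#' @return `data.frame` with columns `subject`, `strategy`, `seed`,
#'   `budget`, `split`, `accuracy`.
#' @export
losoTransfer <- function(subjects, plan, gate = GateConfig(),
                         strategies = c("tl", "tl_msfs"), budget = 1,
                         seed = 1L) {
  stopifnot(length(subjects) >= 2L)
  rows <- list()
  splits <- lapply(seq_along(subjects), function(i)
    splitDataset(subjects[[i]], deriveSeed(seed, 3, i)))
  for (i in seq_along(subjects)) {
    if (nTrials(splits[[i]]$test) < 1L)
      stop("subject ", i, " has an empty test split", call. = FALSE)
    pool <- poolDatasets(lapply(splits[-i], `[[`, "train"))
    template <- freshModel0 <- freshModel(listTemplate(subjects[[i]], plan),
                                          deriveSeed(seed, 5, i))
    pre <- pretrain(freshModel0, pool, plan, seed = deriveSeed(seed, 7, i))
    train <- splits[[i]]$train
    keep <- stratifiedSubsample(trialLabels(train), budget,
                                deriveSeed(seed, 9, i))
    fit <- train[keep]
    for (st in strategies) {
      acc <- runArm(st, pre, template, fit, splits[[i]]$test, plan, gate,
                    seed = deriveSeed(seed, 13, i))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjectId(subjects[[i]]), strategy = st, seed = seed,
        budget = budget, split = "test", accuracy = acc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Default backbone template sized to the data.
listTemplate <- function(ds, plan) {
  d <- dim(trialArray(ds))
  referenceBackbone(channels = d[2], samples = d[3],
                    classes = length(unique(trialLabels(ds))))
}

#' Grid search over regularizer hyperparameters
#'
#' For each grid point `(omega, lossMin, ef)`, fine-tunes on each target
#' subject's fit half (after source pretraining) and evaluates on its
#' validation half; returns the grid point maximizing the mean validation
#' accuracy across subjects (ties: first in grid order). Pretraining per
#' subject is shared across grid points.
#'
#' @param grid `data.frame` with columns `omega`, `lossMin`, `ef`.
#' @param subjects list of [EpochedDataset-class] objects (their training
#'   halves are used; test trials are never touched).
#' @param plan a [TransferPlan-class].
#' @param seed run seed.
#' @return list with `best` (the selected grid row), `meanAccuracy`
#'   (per grid point), and `table` (per subject x grid point).
#' @export
selectHyperparameters <- function(grid, subjects, plan, seed = 1L) {
  stopifnot(nrow(grid) >= 1L,
            all(c("omega", "lossMin", "ef") %in% names(grid)))
  splits <- lapply(seq_along(subjects), function(i)
    splitDataset(subjects[[i]], deriveSeed(seed, 3, i)))
  rows <- list()
  for (i in seq_along(subjects)) {
    train <- splits[[i]]$train
    half <- balancedHalfSplit(trialLabels(train), deriveSeed(seed, 17, i))
    fit <- train[half$fit]; val <- train[half$validation]
    pool <- poolDatasets(lapply(splits[-i], `[[`, "train"))
    base <- freshModel(listTemplate(subjects[[i]], plan),
                       deriveSeed(seed, 5, i))
    pre <- pretrain(base, pool, plan, seed = deriveSeed(seed, 7, i))
    for (g in seq_len(nrow(grid))) {
      planG <- plan; planG@ef <- as.integer(grid$ef[g])
      gateG <- GateConfig(grid$omega[g], grid$lossMin[g])
      m <- finetuneMsfs(pre, fit, planG, gateG, targetFn = "opt_pos_sil",
                        seed = deriveSeed(seed, 13, i))
      acc <- evaluateAccuracy(predictLabels(m, trialArray(val)),
                              trialLabels(val))
      rows[[length(rows) + 1L]] <- data.frame(subject = i, gridPoint = g,
                                              accuracy = acc)
    }
  }
  tab <- do.call(rbind, rows)
  meanAcc <- vapply(seq_len(nrow(grid)),
                    function(g) mean(tab$accuracy[tab$gridPoint == g]),
                    numeric(1))
  best <- which(meanAcc == max(meanAcc))[1L]   # ties: first in grid order
  list(best = cbind(grid[best, , drop = FALSE],
                    meanAccuracy = meanAcc[best]),
       meanAccuracy = meanAcc, table = tab)
}
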