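test_that("epoching reproduces the cue-aligned window conventions", {
  fs <- 250
  # 0.5 s before + 4 s after the cue at 250 Hz: exactly 1125 samples
  cont <- matrix(rnorm(2 * 3000), 2, 3000)
  ds <- epochTrials(cont, cueSamples = 1500, fs = fs, preS = 0.5, postS = 4)
  expect_equal(dim(trialArray(ds))[3], 1125L)

  # pre = 0: the first sample of the trial is the cue sample
  cont2 <- matrix(seq_len(400), 1, 400)
  ds2 <- epochTrials(cont2, cueSamples = 150, fs = 100, preS = 0, postS = 1)
  expect_equal(dim(trialArray(ds2))[3], 100L)
  expect_equal(trialArray(ds2)[1, 1, 1], 150)

  # ramp content check: x[i] = i - 1, cue at index 501, 0.5 s at 250 Hz
  ramp <- matrix(0:2999, 1, 3000)
  ds3 <- epochTrials(ramp, cueSamples = 501, fs = 250, preS = 0.5, postS = 4)
  expect_equal(trialArray(ds3)[1, 1, 1], 375)
})

test_that("epoching is translation-equivariant and rejects bad windows", {
  set.seed(2)
  cont <- matrix(rnorm(3 * 500), 3, 500)
  cues <- c(120, 260)
  a <- epochTrials(cont, cues, fs = 100, preS = 0.2, postS = 0.8,
                   y = c(1, 2))
  shift <- 40
  cont2 <- cbind(matrix(0, 3, shift), cont)
  b <- epochTrials(cont2[, seq_len(500 + shift)], cues + shift, fs = 100,
                   preS = 0.2, postS = 0.8, y = c(1, 2))
  expect_equal(trialArray(a), trialArray(b))

  # out-of-bounds cues are dropped with a warning, labels stay aligned
  expect_warning(
    c3 <- epochTrials(cont, c(5, 260, 499), fs = 100, preS = 0.2,
                      postS = 0.8, y = c(1, 2, 1)),
    "rejected")
  expect_equal(nTrials(c3), 1L)
  expect_equal(trialLabels(c3), 2L)
  expect_error(
    suppressWarnings(epochTrials(cont, c(5, 499), fs = 100, preS = 0.2,
                                 postS = 0.8)),
    "all trial windows")
})

test_that("the epoched container round-trips losslessly and names missing keys", {
  spec <- SynthSpec(nSubjects = 1L, trialsPerClass = 3L, nTimes = 50L,
                    seed = 6L)
  ds <- generateSyntheticSubjects(spec)[[1]]
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path), add = TRUE)
  saveEpoched(ds, path)
  back <- loadEpoched(path)
  expect_identical(trialArray(back), trialArray(ds))
  expect_identical(trialLabels(back), trialLabels(ds))
  expect_identical(samplingRate(back), samplingRate(ds))
  expect_identical(subjectId(back), subjectId(ds))
  expect_identical(channelNames(back), channelNames(ds))

  broken <- readRDS(path)
  broken$y <- NULL
  path2 <- tempfile(fileext = ".rds")
  on.exit(unlink(path2), add = TRUE)
  saveRDS(broken, path2)
  expect_error(loadEpoched(path2), "missing key.*y")

  # two subjects saved, reloaded, pooled: trial counts add up
  spec2 <- spec; spec2@seed <- 7L
  ds2 <- generateSyntheticSubjects(spec2)[[1]]
  pool <- poolDatasets(list(back, ds2))
  expect_equal(nTrials(pool), nTrials(ds) + nTrials(ds2))
  expect_equal(trialLabels(pool), c(trialLabels(ds), trialLabels(ds2)))
})

test_that("feature-batch fixtures respect seed, balance and separation", {
  fb <- generateFeatureBatch(10, K = 2, F = 4, informative = 2,
                             separation = 4, seed = 5)
  expect_identical(featureMatrix(fb),
                   featureMatrix(generateFeatureBatch(10, 2, 4, 2, 4, 5)))
  expect_equal(as.vector(table(classLabels(fb))), c(10, 10))

  # informative columns carry class structure, noise columns do not
  s <- vapply(1:4, function(f)
    mean(silhouette1d(featureMatrix(fb)[, f], classLabels(fb))), numeric(1))
  expect_true(all(s[1:2] > 0.4))
  expect_true(all(abs(s[3:4]) < 0.3))

  # zero separation: mean silhouette of every feature near zero
  fb0 <- generateFeatureBatch(200, K = 2, F = 3, informative = 3,
                              separation = 0, seed = 8)
  s0 <- vapply(1:3, function(f)
    mean(silhouette1d(featureMatrix(fb0)[, f], classLabels(fb0))),
    numeric(1))
  expect_true(all(abs(s0) < 0.15))
})

test_that("the synthetic population carries an ERD-like class signal", {
  # band-power-style features: log variance of the post-cue window
  logPower <- function(ds) {
    cueIdx <- 50
    t(apply(trialArray(ds), 1, function(tr)
      log(apply(tr[, (cueIdx + 1):ncol(tr), drop = FALSE], 1, var))))
  }
  ldaAcc <- function(train, test) {
    fit <- MASS::lda(logPower(train), grouping = trialLabels(train))
    mean(predict(fit, logPower(test))$class == trialLabels(test))
  }
  withinAcc <- crossAcc <- nullAcc <- numeric(6)
  for (k in 1:6) {
    spec <- SynthSpec(nSubjects = 2L, seed = 100L + k)
    subs <- generateSyntheticSubjects(spec)
    sp1 <- splitDataset(subs[[1]], seed = k)
    withinAcc[k] <- ldaAcc(sp1$train, sp1$test)
    crossAcc[k] <- ldaAcc(subs[[2]], sp1$test)
    # no effect: class signal vanishes
    spec0 <- SynthSpec(nSubjects = 1L, effectSize = 0, seed = 200L + k)
    sub0 <- generateSyntheticSubjects(spec0)[[1]]
    sp0 <- splitDataset(sub0, seed = k)
    nullAcc[k] <- ldaAcc(sp0$train, sp0$test)
  }
  # null generator performs at chance
  expect_lt(abs(mean(nullAcc) - 0.5), 0.12)
  # default conditions are decodable well above chance ...
  expect_gt(mean(withinAcc), 0.6)
  # ... while subject shifts keep naive cross-subject transfer off the
  # ceiling, opening the gap the fine-tuning protocol is meant to close
  expect_lt(mean(crossAcc), mean(withinAcc))
  expect_lt(mean(crossAcc), 0.995)
})
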