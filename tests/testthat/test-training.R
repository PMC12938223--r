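test_that("pretraining is a seeded no-op at zero epochs and reproducible", {
  d <- tinyTrialData(n = 12, seed = 1)
  m <- tinyLinearModel(seed = 4)
  plan0 <- TransferPlan(ep = 0, ef = 0, batchSize = 4)
  expect_identical(pretrain(m, d, plan0, seed = 1)$params, m$params)

  plan <- TransferPlan(ep = 6, ef = 0, batchSize = 4)
  m1 <- pretrain(m, d, plan, seed = 9)
  m2 <- pretrain(m, d, plan, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$ce, m2$history$ce)
  m3 <- pretrain(m, d, plan, seed = 10)
  expect_false(identical(m3$history$ce, m1$history$ce))
  # loss decreases in trend on a separable task
  expect_lt(tail(m1$history$ce, 1), m1$history$ce[1])
})

test_that("disabled regularization reproduces CE-only fine-tuning bit for bit", {
  d <- tinyTrialData(n = 12, seed = 5)
  m <- tinyLinearModel(seed = 2)
  plan <- TransferPlan(ep = 0, ef = 8, batchSize = 4)
  ceOnly <- finetuneMsfs(m, d, plan, GateConfig(1, 0.2), targetFn = "none",
                         seed = 7)
  # lossMin = 0: the gate never opens (strict inequality)
  g0 <- finetuneMsfs(m, d, plan, GateConfig(1, 0), targetFn = "opt_pos_sil",
                     seed = 7)
  expect_identical(g0$params, ceOnly$params)
  # omega = 0: the term contributes nothing even when the gate opens
  w0 <- finetuneMsfs(m, d, plan, GateConfig(0, 10), targetFn = "opt_pos_sil",
                     seed = 7)
  expect_identical(w0$params, ceOnly$params)
  # rand_pos draws from its own stream, so disabling it changes nothing
  r0 <- finetuneMsfs(m, d, plan, GateConfig(0, 10), targetFn = "rand_pos",
                     seed = 7)
  expect_identical(r0$params, ceOnly$params)
  expect_error(
    msfs:::trainEngine(m, d$X, d$y, 1, 4, 0.001, 0, targetFn = "bogus"),
    "unknown target strategy")
})

test_that("an active gate changes the optimization path", {
  d <- tinyTrialData(n = 12, seed = 5)
  m <- tinyLinearModel(seed = 2)
  plan <- TransferPlan(ep = 0, ef = 12, batchSize = 4)
  ceOnly <- finetuneMsfs(m, d, plan, GateConfig(1, 0.2), targetFn = "none",
                         seed = 7)
  # always-on regularization must alter the parameters
  on <- finetuneMsfs(m, d, plan, GateConfig(1, 0.2),
                     targetFn = "opt_pos_sil", gating = "always_on",
                     seed = 7)
  expect_false(identical(on$params, ceOnly$params))
  expect_true(any(on$history$lpos > 0))
  # gated runs log gate openings only below the threshold
  gated <- finetuneMsfs(m, d, plan, GateConfig(1, 0.2),
                        targetFn = "opt_pos_sil", seed = 7)
  expect_true(all(gated$history$ce[gated$history$gate_open] < 0.2))
})

test_that("ineligible batches fall back to CE without raising", {
  # batch size 3 on alternating labels guarantees singleton classes
  set.seed(8)
  X <- array(rnorm(6 * 2 * 10), c(6, 2, 10))
  y <- c(1L, 2L, 1L, 2L, 1L, 2L)
  m <- tinyLinearModel(seed = 3)
  plan <- TransferPlan(ep = 0, ef = 4, batchSize = 3)
  expect_no_error({
    ft <- finetuneMsfs(m, list(X = X, y = y), plan, GateConfig(1, 10),
                       targetFn = "opt_pos_sil", gating = "always_on",
                       seed = 1)
  })
  # eligibility never held for any 3-sample batch: every step was CE-only
  expect_true(all(ft$history$lpos == 0))
  # a single-class stream is equally safe
  expect_no_error(
    finetuneMsfs(m, list(X = X, y = rep(1L, 6)), plan, GateConfig(1, 10),
                 targetFn = "opt_pos_sil", gating = "always_on", seed = 1))
})

test_that("epoch reshuffling makes the computed targets stochastic", {
  set.seed(21)
  # non-separable features: targets depend strongly on batch composition
  X <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
  y <- rep(1:2, 6)
  m <- tinyLinearModel(seed = 6)
  plan <- TransferPlan(ep = 0, ef = 2, batchSize = 6)
  ft <- finetuneMsfs(m, list(X = X, y = y), plan, GateConfig(1, 100),
                     targetFn = "opt_pos_sil", gating = "always_on",
                     seed = 3, recordTargets = TRUE)
  tg <- attr(ft, "targets")
  # two epochs x two batches; across epochs the batch compositions differ,
  # so the per-batch target matrices differ too
  expect_equal(length(tg), 4L)
  expect_false(identical(tg[[1]], tg[[3]]))
})

test_that("balanced half split partitions every class evenly", {
  y <- rep(1:2, each = 10)
  sp <- balancedHalfSplit(y, seed = 4)
  expect_length(intersect(sp$fit, sp$validation), 0)
  expect_setequal(c(sp$fit, sp$validation), seq_along(y))
  expect_equal(as.vector(table(y[sp$fit])), c(5, 5))

  # odd class counts: the fit side gets the extra trial
  y2 <- c(rep(1, 7), rep(2, 4))
  sp2 <- balancedHalfSplit(y2, seed = 4)
  expect_equal(sum(y2[sp2$fit] == 1), 4)
  expect_equal(sum(y2[sp2$validation] == 1), 3)

  expect_identical(balancedHalfSplit(y, seed = 11),
                   balancedHalfSplit(y, seed = 11))
  expect_false(identical(balancedHalfSplit(y, seed = 11),
                         balancedHalfSplit(y, seed = 12)))
  expect_error(balancedHalfSplit(c(1, 1, 2), seed = 1), ">= 2 trials")
})

test_that("stratified subsampling keeps class proportions", {
  y <- rep(1:4, each = 72)
  idx <- stratifiedSubsample(y, 0.25, seed = 2)
  expect_equal(as.vector(table(y[idx])), rep(18, 4))
  expect_identical(stratifiedSubsample(y, 0.25, seed = 2), idx)

  # full budget returns everything
  expect_identical(stratifiedSubsample(y, 1, seed = 2), seq_along(y))
  # floor with a minimum of one per class
  y3 <- rep(1:2, each = 15)
  idx3 <- stratifiedSubsample(y3, 0.1, seed = 3)
  expect_equal(as.vector(table(y3[idx3])), c(1, 1))
  expect_error(stratifiedSubsample(y, 0, seed = 1), "fraction")
})

test_that("leave-one-subject-out returns one row per subject and strategy", {
  spec <- SynthSpec(nSubjects = 2L, trialsPerClass = 8L, nTimes = 60L,
                    effectSize = 0.7, subjectShift = 0.05, seed = 3L)
  subs <- generateSyntheticSubjects(spec)
  plan <- TransferPlan(ep = 2, ef = 2, batchSize = 4)
  res <- losoTransfer(subs, plan, GateConfig(), strategies = c("tl"),
                      seed = 5)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$subject, c("synth1", "synth2"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_identical(res, losoTransfer(subs, plan, GateConfig(),
                                     strategies = c("tl"), seed = 5))
})

test_that("hyperparameter selection maximizes mean validation accuracy", {
  spec <- SynthSpec(nSubjects = 2L, trialsPerClass = 8L, nTimes = 60L,
                    effectSize = 0.7, subjectShift = 0.05, seed = 4L)
  subs <- generateSyntheticSubjects(spec)
  plan <- TransferPlan(ep = 2, ef = 2, batchSize = 4)
  # single-point grid returns that point
  g1 <- data.frame(omega = 1, lossMin = 0.2, ef = 2)
  sel1 <- selectHyperparameters(g1, subs, plan, seed = 2)
  expect_equal(sel1$best$omega, 1)
  # a degenerate all-tie grid returns the first row
  g2 <- data.frame(omega = c(0.4, 0.4), lossMin = c(0, 0), ef = c(2, 2))
  sel2 <- selectHyperparameters(g2, subs, plan, seed = 2)
  expect_equal(sel2$meanAccuracy[1], sel2$meanAccuracy[2])
  expect_equal(rownames(sel2$best), "1")
})
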