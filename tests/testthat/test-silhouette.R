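test_that("pairwise absolute distances match direct evaluation", {
  fb <- interleavedBatch()
  D <- pairwiseAbsDistance(fb)
  expect_equal(dim(D), c(1L, 4L, 4L))
  expect_equal(D[1, , ], rbind(c(0, 2, 1, 3), c(2, 0, 1, 1),
                               c(1, 1, 0, 2), c(3, 1, 2, 0)))

  zeros <- FeatureBatch(matrix(0, 3, 2), c(1L, 1L, 2L))
  expect_equal(pairwiseAbsDistance(zeros), array(0, c(2, 3, 3)))

  fb2 <- randomEligibleBatch(11)
  D2 <- pairwiseAbsDistance(fb2)
  for (f in seq_len(dim(D2)[1])) {
    expect_equal(D2[f, , ], t(D2[f, , ]))
    expect_equal(diag(D2[f, , ]), rep(0, dim(D2)[2]))
  }

  bad <- twoClusterBatch()
  bad@Z[1, 1] <- NA_real_
  expect_error(pairwiseAbsDistance(bad), "finite")
})

test_that("1D silhouette reproduces hand-computed vectors", {
  expect_equal(silhouette1d(c(0, 0, 1, 1), c(1, 1, 2, 2)), rep(1, 4))
  expect_equal(silhouette1d(c(0, 2, 1, 3), c(1, 1, 2, 2)),
               c(0, -0.5, -0.5, 0))
  # all-equal values: zero-denominator convention gives 0
  expect_equal(silhouette1d(rep(2, 6), rep(1:2, each = 3)), rep(0, 6))
  # ineligible labelings are rejected
  expect_error(silhouette1d(1:3, c(1, 1, 2)), "eligible")
  expect_error(silhouette1d(1:4, rep(1, 4)), "eligible")
})

test_that("batch eligibility follows the skip rule", {
  expect_true(batchIsMsfsEligible(c(1, 1, 2, 2)))
  expect_false(batchIsMsfsEligible(c(1, 1, 2)))   # singleton class
  expect_false(batchIsMsfsEligible(c(1, 1, 1, 1)))  # one class
  expect_true(batchIsMsfsEligible(rep(1:3, each = 2)))
  expect_false(batchIsMsfsEligible(c(1, 2)))
})

test_that("relocation silhouettes match the hand oracle and stay in range", {
  fb <- lonelyClassmateBatch()
  rs <- relocatedSilhouette(fb)
  # sample 4 moved next to its lone classmate at 5
  expect_equal(rs$a[4, 1, 3], 0)
  expect_equal(rs$b[4, 1, 3], 4.95)
  expect_equal(rs$s[4, 1, 3], 1)
  # sample 4 moved into the other cluster at 0
  expect_equal(rs$a[4, 1, 1], 5)
  expect_equal(rs$b[4, 1, 1], 0.05)
  expect_equal(rs$s[4, 1, 1], (0.05 - 5) / 5)

  for (seed in c(1, 2, 3)) {
    rs2 <- relocatedSilhouette(randomEligibleBatch(seed))
    expect_true(all(rs2$s >= -1 - 1e-12 & rs2$s <= 1 + 1e-12))
    expect_true(all(rs2$a >= 0))
    expect_true(all(rs2$b >= 0))
  }
})

test_that("optimal positions pick the silhouette argmax with stable ties", {
  fb <- lonelyClassmateBatch()
  t1 <- optPosSil(fb)
  expect_equal(t1[4, 1], 5)  # pulled to the lone same-class position

  # already-optimal duplicates stay put, position loss is exactly 0
  fb2 <- twoClusterBatch()
  expect_equal(optPosSil(fb2), featureMatrix(fb2))
  expect_identical(positionLoss(featureMatrix(fb2), optPosSil(fb2)), 0)

  # constant feature: all silhouettes 0, own position wins the tie-break
  fb3 <- FeatureBatch(matrix(2, 4, 1), c(1L, 1L, 2L, 2L))
  expect_equal(optPosSil(fb3), featureMatrix(fb3))

  # own position is always a candidate: selected silhouette never degrades
  for (seed in 4:6) {
    fb4 <- randomEligibleBatch(seed)
    rs <- relocatedSilhouette(fb4)
    t4 <- optPosSil(fb4)
    N <- nSamples(fb4)
    for (f in seq_len(nFeatures(fb4))) {
      best <- vapply(seq_len(N), function(i) max(rs$s[i, f, ]), numeric(1))
      own <- vapply(seq_len(N), function(i) rs$s[i, f, i], numeric(1))
      expect_true(all(best >= own - 1e-12))
      # candidate membership: targets are existing batch values
      expect_true(all(t4[, f] %in% featureMatrix(fb4)[, f]))
    }
  }
})

test_that("vectorized search agrees with the brute-force oracle", {
  for (seed in 1:30) {
    fb <- randomEligibleBatch(seed)
    expect_identical(optPosSil(fb), optPosBrute(fb))
  }
})

test_that("random targets respect the batch range and the seed", {
  fb <- randomEligibleBatch(7)
  Z <- featureMatrix(fb)
  t1 <- randPos(fb, seed = 42)
  t2 <- randPos(fb, seed = 42)
  expect_identical(t1, t2)
  for (f in seq_len(ncol(Z))) {
    expect_true(all(t1[, f] >= min(Z[, f]) & t1[, f] <= max(Z[, f])))
  }
  expect_false(identical(t1, randPos(fb, seed = 43)))

  cst <- FeatureBatch(matrix(3, 4, 2), c(1L, 1L, 2L, 2L))
  expect_equal(randPos(cst, seed = 1), matrix(3, 4, 2))
})

test_that("candidate subsampling is exact once the class is covered", {
  for (seed in 8:12) {
    fb <- randomEligibleBatch(seed)
    maxClass <- max(table(classLabels(fb)))
    expect_identical(optPosSilSubsampled(fb, m = maxClass, seed = 5),
                     optPosSil(fb))
    # any m: targets remain batch values of their feature
    t2 <- optPosSilSubsampled(fb, m = 2L, seed = 5)
    Z <- featureMatrix(fb)
    for (f in seq_len(ncol(Z)))
      expect_true(all(t2[, f] %in% Z[, f]))
  }
  cst <- FeatureBatch(matrix(1, 4, 1), c(1L, 1L, 2L, 2L))
  expect_equal(optPosSilSubsampled(cst, m = 1L, seed = 1),
               featureMatrix(cst))
})

test_that("top-k feature ranking uses mean current silhouette", {
  Z <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  fb <- FeatureBatch(Z, c(1L, 1L, 2L, 2L))
  expect_identical(topkFeatureMask(fb, 1L), 1L)
  expect_identical(topkFeatureMask(fb, 2L), c(1L, 2L))
  # exact ties: lowest feature index wins
  fbTie <- FeatureBatch(cbind(c(0, 0, 1, 1), c(5, 5, 6, 6)),
                        c(1L, 1L, 2L, 2L))
  expect_identical(topkFeatureMask(fbTie, 1L), 1L)
})

test_that("silhouette profile export writes a readable table", {
  fb <- twoClusterBatch()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  prof <- exportSilhouetteProfile(fb, path)
  back <- read.delim(path)
  expect_equal(back$mean_silhouette, prof$mean_silhouette)
  expect_equal(back$feature, 1L)
  expect_equal(prof$mean_silhouette, 1)
})
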