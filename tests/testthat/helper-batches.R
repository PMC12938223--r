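# Shared fixtures: small feature batches and a seeded random-batch factory.

twoClusterBatch <- function() {
  FeatureBatch(matrix(c(0, 0, 1, 1), 4, 1), c(1L, 1L, 2L, 2L))
}

interleavedBatch <- function() {
  FeatureBatch(matrix(c(0, 2, 1, 3), 4, 1), c(1L, 1L, 2L, 2L))
}

lonelyClassmateBatch <- function() {
  FeatureBatch(matrix(c(0, 0.1, 5, 0.9), 4, 1), c(1L, 1L, 2L, 2L))
}

# Random eligible batch; values rounded to 2 decimals so exact duplicates
# (and thus argmax ties) occur regularly.
randomEligibleBatch <- function(seed, maxN = 12L, maxF = 4L, maxK = 3L) {
  set.seed(seed)
  K <- sample(2:maxK, 1L)
  npc <- sample(2:max(2L, floor(maxN / K)), 1L)
  F <- sample(seq_len(maxF), 1L)
  y <- rep(seq_len(K), each = npc)
  Z <- matrix(round(rnorm(length(y) * F), 2), length(y), F)
  FeatureBatch(Z, y)
}

tinyLinearModel <- function(seed = 1L) {
  linearFeatureModel(channels = 2L, samples = 10L, classes = 2L,
                     featureDim = 3L, seed = seed)
}

tinyTrialData <- function(n = 12L, seed = 1L) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  X <- array(rnorm(n * 2 * 10), c(n, 2, 10))
  # separable structure: class shifts the mean of channel 1
  X[, 1, ] <- X[, 1, ] + (y - 1.5) * 2
  list(X = X, y = y)
}
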