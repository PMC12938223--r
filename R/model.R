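# Feature-model contract
#
# Any trainable model usable with the training protocol is a list of class
# "featureModel" with:
#   params   named list of numeric arrays
#   forward  function(params, X) -> list(logits = N x K, features = N x F,
#            cache = anything backward needs)
#   backward function(params, X, cache, dLogits, dFeatures) -> named list of
#            gradients matching params
#   meta     list(builder = <registry name>, args = <constructor args>,
#            classes = K, featureDim = F)
# Everything downstream (losses, optimizer, transfer protocol) sees only
# this surface, so backbones are swappable.

backboneBuilders <- function() {
  list(reference = referenceBackbone, linear = linearFeatureModel)
}

newFeatureModel <- function(params, forward, backward, meta) {
  structure(list(params = params, forward = forward, backward = backward,
                 meta = meta, history = NULL),
            class = "featureModel")
}

#' @export
print.featureModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("featureModel '%s': %d parameters, %d classes, %d features\n",
              x$meta$builder, np, x$meta$classes, x$meta$featureDim))
  invisible(x)
}

#' Forward pass of a feature model
#'
#' @param model a `featureModel`.
#' @param X `N x C x T` input array (a single trial may be passed as
#'   `C x T`).
#' @return list with `logits` (`N x K`) and `features` (`N x F`).
#' @export
modelForward <- function(model, X) {
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  out <- model$forward(model$params, X)
  list(logits = out$logits, features = out$features)
}

#' Compact reference backbone for epoched EEG
#'
#' A small trainable network in the spirit of shallow band-power
#' architectures: a bank of temporal convolution filters shared across
#' channels, a linear spatial projection mixing channels, squaring, mean
#' pooling over `nSegments` contiguous time windows and a log transform
#' (yielding segment-wise log band-power maps, so task-related power changes
#' relative to the pre-cue window stay visible), followed by a linear
#' feature layer of width `featureDim` and a dense classifier head. All
#' gradients are analytic; initialization is deterministic for a fixed seed.
#' The design keeps the parameter count in the low thousands so desk-scale
#' experiments run quickly on one CPU; it is a reference implementation of
#' the feature-layer contract, not a re-implementation of any published EEG
#' architecture.
#'
#' @param channels number of channels C.
#' @param samples trial length T (`>= 16`).
#' @param classes number of classes K.
#' @param featureDim width F of the feature layer.
#' @param nTemporalFilters temporal filters in the first bank.
#' @param filterLength temporal filter length (samples).
#' @param nSpatialFilters spatial projections per temporal filter.
#' @param nSegments pooling windows along the trial.
#' @param seed initialization seed.
#' @return a `featureModel` (see package documentation for the contract).
#' @export
referenceBackbone <- function(channels, samples, classes, featureDim = 8L,
                              nTemporalFilters = 4L, filterLength = 21L,
                              nSpatialFilters = 2L, nSegments = 4L,
                              seed = 1L) {
  stopifnot(channels >= 1L, samples >= 16L, filterLength < samples)
  C <- as.integer(channels); T <- as.integer(samples)
  K <- as.integer(classes); F <- as.integer(featureDim)
  m <- as.integer(nTemporalFilters); Lt <- as.integer(filterLength)
  S <- as.integer(nSpatialFilters); G <- as.integer(nSegments)
  Tp0 <- T - Lt + 1L
  stopifnot(G >= 1L, G <= Tp0)
  # contiguous near-equal pooling windows over the conv output
  segId <- as.integer(cut(seq_len(Tp0), G, labels = FALSE))
  segLen <- tabulate(segId, G)
  d <- S * m * G
  eps <- 1e-4
  # temporal filters start as Hann-windowed sinusoids at random normalized
  # frequencies (learnable band-pass init), which conditions the log-power
  # path far better than white-noise filters
  initWt <- function() {
    tIdx <- 0:(Lt - 1)
    hann <- 0.5 - 0.5 * cos(2 * pi * (tIdx + 0.5) / Lt)
    Wt <- matrix(0, m, Lt)
    for (j in seq_len(m)) {
      fj <- runif(1, 0.05, 0.25)           # cycles per sample
      w <- hann * sin(2 * pi * fj * tIdx + runif(1, 0, 2 * pi))
      Wt[j, ] <- w / sqrt(sum(w^2))
    }
    Wt
  }
  params <- withSeed(seed, list(
    Wt = initWt(),
    Ws = matrix(rnorm(S * C, sd = 1 / sqrt(C)), S, C),
    W1 = matrix(rnorm(F * d, sd = 1 / sqrt(d)), F, d),
    b1 = numeric(F),
    W2 = matrix(rnorm(K * F, sd = 1 / sqrt(F)), K, F),
    b2 = numeric(K)))

  # The temporal convolution is a banded T x (m*Tp) matrix applied by one
  # BLAS multiply; these index tables scatter Wt into the band (forward) and
  # gather the band sums of crossprod(X, dU) back into dWt (backward).
  Tp <- Tp0
  colOf <- rep(seq_len(m * Tp), each = Lt)         # band layout: (j, t')
  tOf <- rep(rep(seq_len(Tp), each = Lt), times = m) +
    rep(seq_len(Lt) - 1L, times = m * Tp)          # input sample index
  bandIdx <- (colOf - 1L) * T + tOf                # linear index into B
  wtIdx <- rep(rep(seq_len(Lt), times = Tp), times = m) +
    rep((seq_len(m) - 1L) * Lt, each = Lt * Tp)    # Wt entry per band slot
  segW <- vapply(seq_len(G), function(g) (segId == g) / segLen[g],
                 numeric(Tp))                       # Tp x G pooling weights

  forward <- function(params, X) {
    stopifnot(length(dim(X)) == 3L)
    N <- dim(X)[1]
    if (dim(X)[2] != C || dim(X)[3] != T)
      stop(sprintf("input must be N x %d x %d", C, T), call. = FALSE)
    Xmat <- matrix(X, N * C, T)        # rows ordered (n fastest, then c)
    B <- numeric(T * m * Tp)
    B[bandIdx] <- t(params$Wt)[wtIdx]
    dim(B) <- c(T, m * Tp)
    Uall <- Xmat %*% B                 # (N*C) x (m*Tp), columns (j, t')
    Ujp <- vector("list", m); Vj <- vector("list", m)
    Q <- array(0, c(N, S, G, m))
    for (j in seq_len(m)) {
      Uj <- Uall[, (j - 1L) * Tp + seq_len(Tp), drop = FALSE]
      # reorder to rows (n, t'), cols c for the spatial projection
      Up <- matrix(aperm(array(Uj, c(N, C, Tp)), c(1L, 3L, 2L)), N * Tp, C)
      V <- Up %*% t(params$Ws)         # (N*Tp) x S
      Ujp[[j]] <- Up; Vj[[j]] <- V
      V2 <- V * V
      for (s in seq_len(S))
        Q[, s, , j] <- matrix(V2[, s], N, Tp) %*% segW
    }
    P <- log(Q + eps)
    Pmat <- matrix(P, N, d)            # columns ordered (s, g, j)
    Zf <- Pmat %*% t(params$W1) + rep(params$b1, each = N)
    logits <- Zf %*% t(params$W2) + rep(params$b2, each = N)
    list(logits = logits, features = Zf,
         cache = list(Xmat = Xmat, Ujp = Ujp, Vj = Vj, Q = Q,
                      Pmat = Pmat, Zf = Zf, N = N))
  }

  backward <- function(params, X, cache, dLogits, dFeatures) {
    N <- cache$N
    dZf <- dLogits %*% params$W2 + dFeatures
    g <- list(
      Wt = matrix(0, m, Lt),
      Ws = matrix(0, S, C),
      W1 = t(dZf) %*% cache$Pmat,
      b1 = colSums(dZf),
      W2 = t(dLogits) %*% cache$Zf,
      b2 = colSums(dLogits))
    dP <- dZf %*% params$W1            # N x d
    dQhat <- array(dP, c(N, S, G, m)) / (cache$Q + eps)
    dUall <- matrix(0, N * C, m * Tp)
    for (j in seq_len(m)) {
      dV <- cache$Vj[[j]]
      for (s in seq_len(S)) {
        Eseg <- dQhat[, s, , j, drop = FALSE]
        dim(Eseg) <- c(N, G)
        # expand segment weights back over time: d(mean V^2)/dV = 2V/len
        Em <- 2 * (Eseg %*% t(segW))   # N x Tp
        dV[, s] <- cache$Vj[[j]][, s] * as.vector(Em)
      }
      g$Ws <- g$Ws + t(dV) %*% cache$Ujp[[j]]
      dUp <- dV %*% params$Ws          # (N*Tp) x C
      dUall[, (j - 1L) * Tp + seq_len(Tp)] <-
        matrix(aperm(array(dUp, c(N, Tp, C)), c(1L, 3L, 2L)), N * C, Tp)
    }
    M <- crossprod(cache$Xmat, dUall)  # T x (m*Tp)
    vals <- M[bandIdx]
    dim(vals) <- c(Lt, Tp, m)
    g$Wt <- t(colSums(aperm(vals, c(2L, 1L, 3L))))  # sum over t' -> (m, Lt)
    g
  }

  newFeatureModel(params, forward, backward,
                  meta = list(builder = "reference",
                              args = list(channels = C, samples = T,
                                          classes = K, featureDim = F,
                                          nTemporalFilters = m,
                                          filterLength = Lt,
                                          nSpatialFilters = S,
                                          nSegments = G, seed = seed),
                              classes = K, featureDim = F))
}

#' Trivial linear feature model
#'
#' A minimal model satisfying the feature-layer contract: features are a
#' linear map of the flattened trial, logits a linear map of the features.
#' Used to demonstrate that the training protocol is backbone-agnostic and
#' as a fast stand-in in unit tests.
#'
#' @inheritParams referenceBackbone
#' @return a `featureModel`.
#' @export
linearFeatureModel <- function(channels, samples, classes, featureDim = 4L,
                               seed = 1L) {
  C <- as.integer(channels); T <- as.integer(samples)
  K <- as.integer(classes); F <- as.integer(featureDim)
  d <- C * T
  params <- withSeed(seed, list(
    W1 = matrix(rnorm(F * d, sd = 1 / sqrt(d)), F, d),
    b1 = numeric(F),
    W2 = matrix(rnorm(K * F, sd = 1 / sqrt(F)), K, F),
    b2 = numeric(K)))
  forward <- function(params, X) {
    N <- dim(X)[1]
    if (dim(X)[2] != C || dim(X)[3] != T)
      stop(sprintf("input must be N x %d x %d", C, T), call. = FALSE)
    Xf <- matrix(X, N, d)
    Zf <- Xf %*% t(params$W1) + rep(params$b1, each = N)
    logits <- Zf %*% t(params$W2) + rep(params$b2, each = N)
    list(logits = logits, features = Zf, cache = list(Xf = Xf, Zf = Zf))
  }
  backward <- function(params, X, cache, dLogits, dFeatures) {
    dZf <- dLogits %*% params$W2 + dFeatures
    list(W1 = t(dZf) %*% cache$Xf,
         b1 = colSums(dZf),
         W2 = t(dLogits) %*% cache$Zf,
         b2 = colSums(dLogits))
  }
  newFeatureModel(params, forward, backward,
                  meta = list(builder = "linear",
                              args = list(channels = C, samples = T,
                                          classes = K, featureDim = F,
                                          seed = seed),
                              classes = K, featureDim = F))
}

#' Save / load a feature model checkpoint
#'
#' Checkpoints store the registry name of the builder, its construction
#' arguments and the current parameters in R's native serialized form; the
#' model is rebuilt from the registry on load so function environments are
#' never serialized.
#'
#' @param model a `featureModel`.
#' @param path checkpoint file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   restored `featureModel`.
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "featureModel"))
  saveRDS(list(builder = model$meta$builder, args = model$meta$args,
               params = model$params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  builders <- backboneBuilders()
  if (is.null(builders[[ck$builder]]))
    stop("unknown backbone '", ck$builder, "' in checkpoint", call. = FALSE)
  model <- do.call(builders[[ck$builder]], ck$args)
  model$params <- ck$params
  model
}

#' Average logits across parallel branches
#'
#' For multi-branch backbones the final class score is the elementwise mean
#' of the per-branch logits.
#'
#' @param branches list of branch outputs, each a list with `logits`
#'   (`N x K`) and optionally `features`.
#' @return numeric `N x K` matrix of averaged logits.
#' @export
branchAverage <- function(branches) {
  if (!length(branches)) stop("empty branch list", call. = FALSE)
  logits <- lapply(branches, function(b) as.matrix(b$logits))
  dims <- unique(lapply(logits, dim))
  if (length(dims) != 1L)
    stop("branches must share N and K", call. = FALSE)
  Reduce(`+`, logits) / length(logits)
}

#' Position loss aggregated over branches
#'
#' Each branch has its own feature layer; targets are computed independently
#' per branch with the shared labels and the per-branch position losses are
#' averaged.
#'
#' @param branches list of branch outputs, each a list with `features`
#'   (`N x F_b`).
#' @param y shared integer labels.
#' @param targetFn function mapping a [FeatureBatch-class] to an `N x F_b`
#'   target matrix (default [optPosSil()]).
#' @return a single nonnegative number.
#' @export
branchPositionLoss <- function(branches, y, targetFn = optPosSil) {
  if (!length(branches)) stop("empty branch list", call. = FALSE)
  losses <- vapply(branches, function(b) {
    fb <- FeatureBatch(b$features, y)
    positionLoss(b$features, targetFn(fb))
  }, numeric(1))
  mean(losses)
}

# Adam with L2 weight decay folded into the gradient (the convention of the
# optimizer settings the protocol fixes: lr 0.001, weight decay 0.009).
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
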