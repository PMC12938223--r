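# 1/f-shaped background noise via spectral shaping: white Gaussian spectrum
# scaled by 1/sqrt(f), inverse FFT, normalized to unit standard deviation.
pinkNoise <- function(n) {
  nf <- floor(n / 2)
  amp <- 1 / sqrt(seq_len(nf))
  phase <- runif(nf, 0, 2 * pi)
  mag <- amp * abs(rnorm(nf))
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE))
  s <- sd(x)
  if (s == 0) x else (x - mean(x)) / s
}

#' Gaussian feature-batch fixture
#'
#' Generates a balanced `FeatureBatch` for exercising the feature-level
#' machinery: `informative` feature dimensions are Gaussian per class with
#' class means spaced `separation` apart (unit variance); the remaining
#' dimensions are class-independent standard Gaussians.
#'
#' @param nPerClass samples per class.
#' @param K number of classes.
#' @param F number of feature dimensions.
#' @param informative number of class-dependent dimensions (`<= F`).
#' @param separation distance between adjacent class means.
#' @param seed generator seed.
#' @return a [FeatureBatch-class].
#' @export
generateFeatureBatch <- function(nPerClass, K = 2L, F = 4L, informative = 2L,
                                 separation = 1, seed = 1L) {
  stopifnot(informative <= F, nPerClass >= 1L, K >= 1L)
  N <- nPerClass * K
  y <- rep(seq_len(K), each = nPerClass)
  withSeed(seed, {
    Z <- matrix(rnorm(N * F), N, F)
    if (informative >= 1L)
      for (f in seq_len(informative))
        Z[, f] <- Z[, f] + (y - 1) * separation
    FeatureBatch(Z, y)
  })
}

#' Simulate a multi-subject motor-imagery-like EEG population
#'
#' Each trial is 1/f-shaped background noise plus a 10 Hz oscillation on all
#' channels; after the cue, the oscillation amplitude on the channel subset
#' assigned to the trial's class is attenuated by `effectSize` (an
#' event-related-desynchronization-like lateralized power drop, the spatial
#' signature motor-imagery decoders exploit). Each subject applies its own
#' random per-channel gain (log-normal, scale `subjectShift`) and DC offset,
#' emulating inter-subject variability in anatomy and electrode placement.
#' Fully reproducible for a fixed spec seed.
#'
#' @param spec a [SynthSpec-class].
#' @return list of [EpochedDataset-class] objects, one per subject, each
#'   with `nClasses * trialsPerClass` trials in balanced class order.
#' @export
generateSyntheticSubjects <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  K <- spec@nClasses; C <- spec@nChannels; Tn <- spec@nTimes
  cueIdx <- round(spec@cueS * spec@fs)
  post <- seq_len(Tn) > cueIdx
  # contiguous channel groups per class (lateralized sites)
  grp <- sort(rep_len(seq_len(K), C))
  classCh <- split(seq_len(C), grp)
  tt <- (seq_len(Tn) - 1) / spec@fs
  withSeed(spec@seed, {
    lapply(seq_len(spec@nSubjects), function(sub) {
      gain <- exp(rnorm(C, 0, spec@subjectShift))
      offset <- rnorm(C, 0, spec@subjectShift * spec@noiseLevel)
      n <- K * spec@trialsPerClass
      y <- rep(seq_len(K), each = spec@trialsPerClass)
      X <- array(0, c(n, C, Tn))
      for (i in seq_len(n)) {
        attChans <- classCh[[y[i]]]
        for (c in seq_len(C)) {
          amp <- rep(spec@oscAmplitude, Tn)
          if (c %in% attChans) amp[post] <- amp[post] * (1 - spec@effectSize)
          phase <- runif(1, 0, 2 * pi)
          osc <- amp * sin(2 * pi * 10 * tt + phase)
          X[i, c, ] <- offset[c] +
            gain[c] * (pinkNoise(Tn) * spec@noiseLevel + osc)
        }
      }
      EpochedDataset(X, y, spec@fs, subject = paste0("synth", sub))
    })
  })
}
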