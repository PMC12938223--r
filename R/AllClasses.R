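#' FeatureBatch: a batch feature matrix with class labels
#'
#' The object all silhouette machinery operates on: an `N x F` matrix `Z` of
#' feature-layer activations (one row per sample, one column per feature
#' dimension) together with integer class labels `y` in `1..K`.
#'
#' @slot Z numeric matrix, `N x F`, all entries finite.
#' @slot y integer vector of length `N`, values in `1..K`.
#'
#' @examples
#' fb <- FeatureBatch(matrix(rnorm(8), 4, 2), c(1L, 1L, 2L, 2L))
#' nSamples(fb); nFeatures(fb); nClasses(fb)
#' @export
setClass("FeatureBatch",
  representation(Z = "matrix", y = "integer"))

setValidity("FeatureBatch", function(object) {
  msg <- character()
  if (!is.numeric(object@Z)) msg <- c(msg, "Z must be numeric")
  if (nrow(object@Z) < 2L) msg <- c(msg, "need N >= 2 samples")
  if (ncol(object@Z) < 1L) msg <- c(msg, "need F >= 1 features")
  if (length(object@y) != nrow(object@Z))
    msg <- c(msg, "length(y) must equal nrow(Z)")
  if (!all(is.finite(object@Z))) msg <- c(msg, "Z must be finite")
  if (anyNA(object@y) || any(object@y < 1L))
    msg <- c(msg, "labels must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureBatch
#'
#' @param Z numeric matrix `N x F` of feature activations.
#' @param y class labels, coerced to integer, values in `1..K`.
#' @return a [FeatureBatch-class] object.
#' @export
FeatureBatch <- function(Z, y) {
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1L)
  new("FeatureBatch", Z = unname(as.matrix(Z)), y = as.integer(y))
}

#' GateConfig: weight and activation threshold of the gated objective
#'
#' Holds the MSFS loss weight `omega` and the gating threshold `lossMin`.
#' The position loss is added to the objective only when the batch
#' cross-entropy is strictly below `lossMin`; `lossMin = 0` therefore keeps
#' the gate permanently closed and `omega = 0` silences the term.
#'
#' @slot omega nonnegative loss weight.
#' @slot lossMin nonnegative gating threshold (nats of cross-entropy).
#' @export
setClass("GateConfig",
  representation(omega = "numeric", lossMin = "numeric"))

setValidity("GateConfig", function(object) {
  msg <- character()
  if (length(object@omega) != 1L || !is.finite(object@omega) || object@omega < 0)
    msg <- c(msg, "omega must be a single nonnegative number")
  if (length(object@lossMin) != 1L || !is.finite(object@lossMin) || object@lossMin < 0)
    msg <- c(msg, "lossMin must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Construct a GateConfig
#' @param omega nonnegative MSFS loss weight.
#' @param lossMin nonnegative gating threshold on the batch cross-entropy.
#' @return a [GateConfig-class] object.
#' @export
GateConfig <- function(omega = 1, lossMin = 0.2) {
  new("GateConfig", omega = as.numeric(omega), lossMin = as.numeric(lossMin))
}

#' EpochedDataset: cue-aligned EEG trials of one subject
#'
#' Trials are stored as an `n x C x T` array in microvolts, with integer
#' class labels, the sampling rate in Hz, a subject identifier, and channel
#' names. This is the unit of the transfer protocol: one object per subject.
#'
#' @slot X numeric array, `n_trials x C x T`.
#' @slot y integer labels of length `n_trials`, values in `1..K`.
#' @slot fs sampling rate in Hz.
#' @slot subject subject identifier.
#' @slot channels channel names, length `C`.
#' @export
setClass("EpochedDataset",
  representation(X = "array", y = "integer", fs = "numeric",
                 subject = "character", channels = "character"))

setValidity("EpochedDataset", function(object) {
  msg <- character()
  if (length(dim(object@X)) != 3L) msg <- c(msg, "X must be n x C x T")
  else {
    if (dim(object@X)[1] != length(object@y))
      msg <- c(msg, "dim(X)[1] must equal length(y)")
    if (length(object@channels) &&
        length(object@channels) != dim(object@X)[2])
      msg <- c(msg, "length(channels) must equal dim(X)[2]")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (any(object@y < 1L)) msg <- c(msg, "labels must be in 1..K")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochedDataset
#'
#' @param X `n_trials x C x T` numeric array of trials (microvolts).
#' @param y class labels, coerced to integer.
#' @param fs sampling rate in Hz.
#' @param subject subject identifier.
#' @param channels channel names (default `"ch1".."chC"`).
#' @return an [EpochedDataset-class] object.
#' @export
EpochedDataset <- function(X, y, fs, subject = "s1", channels = NULL) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(X)[2]))
  new("EpochedDataset", X = X, y = as.integer(y), fs = as.numeric(fs),
      subject = as.character(subject), channels = as.character(channels))
}

#' SynthSpec: study conditions of the synthetic multi-subject generator
#'
#' Describes the simulated population: number of subjects, trials per class,
#' class/channel/sample counts, sampling rate, the cue time within the trial,
#' the ERD effect size (fractional post-cue attenuation of the 10 Hz rhythm
#' on class-assigned channels), the scale of subject-specific gain/offset
#' shifts, the background noise level, and the oscillation amplitude.
#'
#' @slot nSubjects number of simulated subjects.
#' @slot trialsPerClass trials per class per subject.
#' @slot nClasses number of classes K.
#' @slot nChannels number of channels C.
#' @slot nTimes samples per trial T.
#' @slot fs sampling rate in Hz.
#' @slot cueS cue time within the trial, seconds from trial onset.
#' @slot effectSize fractional post-cue amplitude attenuation, in [0, 1).
#' @slot subjectShift scale of per-subject log-gain and offset shifts.
#' @slot noiseLevel background 1/f noise standard deviation, microvolts.
#' @slot oscAmplitude amplitude of the 10 Hz rhythm, microvolts.
#' @slot seed base seed of the generator.
#' @export
setClass("SynthSpec",
  representation(nSubjects = "integer", trialsPerClass = "integer",
                 nClasses = "integer", nChannels = "integer",
                 nTimes = "integer", fs = "numeric", cueS = "numeric",
                 effectSize = "numeric", subjectShift = "numeric",
                 noiseLevel = "numeric", oscAmplitude = "numeric",
                 seed = "integer"))

setValidity("SynthSpec", function(object) {
  msg <- character()
  counts <- c(object@nSubjects, object@trialsPerClass, object@nClasses,
              object@nChannels, object@nTimes)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@effectSize < 0 || object@effectSize >= 1)
    msg <- c(msg, "effectSize must lie in [0, 1)")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@cueS < 0 || round(object@cueS * object@fs) > object@nTimes)
    msg <- c(msg, "cue must fall inside the trial")
  if (length(msg)) msg else TRUE
})

#' Construct a SynthSpec
#'
#' Defaults are the package's reference study conditions: a 4-subject,
#' two-class population with 6 channels at 100 Hz, 1.5 s trials (cue at
#' 0.5 s, 16 trials per class so a half split leaves 8 target training
#' trials per class),
#' a 40% post-cue attenuation, moderate subject shifts, 10 uV background
#' noise and a 20 uV rhythm, giving class separability strictly between
#' chance and ceiling so transfer gains are measurable.
#'
#' @param nSubjects,trialsPerClass,nClasses,nChannels,nTimes counts.
#' @param fs sampling rate (Hz).
#' @param cueS cue time within the trial (s).
#' @param effectSize fractional post-cue attenuation in [0, 1).
#' @param subjectShift scale of subject gain/offset shifts.
#' @param noiseLevel background noise sd (uV).
#' @param oscAmplitude rhythm amplitude (uV).
#' @param seed base seed.
#' @return a [SynthSpec-class] object.
#' @export
SynthSpec <- function(nSubjects = 4L, trialsPerClass = 16L, nClasses = 2L,
                      nChannels = 6L, nTimes = 150L, fs = 100, cueS = 0.5,
                      effectSize = 0.4, subjectShift = 0.15,
                      noiseLevel = 10, oscAmplitude = 20, seed = 1L) {
  new("SynthSpec", nSubjects = as.integer(nSubjects),
      trialsPerClass = as.integer(trialsPerClass),
      nClasses = as.integer(nClasses), nChannels = as.integer(nChannels),
      nTimes = as.integer(nTimes), fs = as.numeric(fs),
      cueS = as.numeric(cueS), effectSize = as.numeric(effectSize),
      subjectShift = as.numeric(subjectShift),
      noiseLevel = as.numeric(noiseLevel),
      oscAmplitude = as.numeric(oscAmplitude), seed = as.integer(seed))
}

#' TransferPlan: schedule and optimizer settings of the transfer protocol
#'
#' @slot ep pretraining epochs.
#' @slot ef fine-tuning epochs.
#' @slot batchSize mini-batch size (>= 2; the regularizer needs at least two
#'   samples per class in a batch to ever fire).
#' @slot lr Adam learning rate.
#' @slot weightDecay L2 weight decay added to the gradient.
#' @slot seeds run seeds for repeated independent runs.
#' @export
setClass("TransferPlan",
  representation(ep = "integer", ef = "integer", batchSize = "integer",
                 lr = "numeric", weightDecay = "numeric", seeds = "integer"))

setValidity("TransferPlan", function(object) {
  msg <- character()
  if (object@ep < 0L || object@ef < 0L) msg <- c(msg, "ep, ef must be >= 0")
  if (object@batchSize < 2L) msg <- c(msg, "batchSize must be >= 2")
  if (object@lr <= 0) msg <- c(msg, "lr must be positive")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TransferPlan
#' @param ep pretraining epochs.
#' @param ef fine-tuning epochs.
#' @param batchSize mini-batch size.
#' @param lr Adam learning rate (default 0.001).
#' @param weightDecay L2 weight decay (default 0.009).
#' @param seeds run seeds (default `1:3`, three independent runs).
#' @return a [TransferPlan-class] object.
#' @export
TransferPlan <- function(ep = 60L, ef = 200L, batchSize = 8L, lr = 0.001,
                         weightDecay = 0.009, seeds = 1:3) {
  new("TransferPlan", ep = as.integer(ep), ef = as.integer(ef),
      batchSize = as.integer(batchSize), lr = as.numeric(lr),
      weightDecay = as.numeric(weightDecay), seeds = as.integer(seeds))
}
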