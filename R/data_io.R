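#' Epoch a continuous recording around cue onsets
#'
#' Cuts one trial per cue from a continuous multichannel recording using the
#' half-open sample window `[cue - round(pre_s * fs), cue - round(pre_s *
#' fs) + round((pre_s + post_s) * fs))`. Cue indices are 1-based sample
#' numbers. At 250 Hz with 0.5 s before and 4 s after the cue this yields
#' exactly 1125 samples per trial. Windows falling outside the recording are
#' rejected per trial with a warning; if every window is rejected an error
#' is raised.
#'
#' @param continuous numeric `C x S` matrix (channels x samples).
#' @param cueSamples integer vector of 1-based cue sample indices.
#' @param fs sampling rate in Hz.
#' @param preS seconds retained before the cue.
#' @param postS seconds retained after the cue.
#' @param y optional labels per cue (default all 1).
#' @param subject subject identifier.
#' @param channels channel names.
#' @return an [EpochedDataset-class]; rejected cues are dropped from both
#'   trials and labels.
#' @export
epochTrials <- function(continuous, cueSamples, fs, preS = 0.5, postS = 4.0,
                        y = NULL, subject = "s1", channels = NULL) {
  continuous <- as.matrix(continuous)
  C <- nrow(continuous); S <- ncol(continuous)
  pre <- round(preS * fs)
  len <- round((preS + postS) * fs)
  if (len < 1L) stop("window length must be >= 1 sample", call. = FALSE)
  if (is.null(y)) y <- rep(1L, length(cueSamples))
  starts <- as.integer(cueSamples) - pre
  ok <- starts >= 1L & (starts + len - 1L) <= S
  if (any(!ok))
    warning(sum(!ok), " trial(s) rejected: window outside the recording",
            call. = FALSE)
  if (!any(ok)) stop("all trial windows fall outside the recording",
                     call. = FALSE)
  starts <- starts[ok]
  X <- array(0, c(length(starts), C, len))
  for (i in seq_along(starts))
    X[i, , ] <- continuous[, starts[i]:(starts[i] + len - 1L), drop = FALSE]
  EpochedDataset(X, y[ok], fs, subject = subject, channels = channels)
}

#' Save / load an epoched-trial container
#'
#' Single-file keyed container (R native serialization) holding the trial
#' array `X`, labels `y`, and the attributes `fs`, `subject` and `channels`.
#' Loading validates the layout and names any missing key; the round trip is
#' lossless at 64-bit precision.
#'
#' @param ds an [EpochedDataset-class].
#' @param path container file path.
#' @return `saveEpoched` returns `path` invisibly; `loadEpoched` returns the
#'   restored [EpochedDataset-class].
#' @export
saveEpoched <- function(ds, path) {
  stopifnot(is(ds, "EpochedDataset"))
  saveRDS(list(X = trialArray(ds), y = trialLabels(ds),
               fs = samplingRate(ds), subject = subjectId(ds),
               channels = channelNames(ds)), path)
  invisible(path)
}

#' @rdname saveEpoched
#' @export
loadEpoched <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj)) stop("not an epoched-trial container", call. = FALSE)
  need <- c("X", "y", "fs", "subject", "channels")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("container is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  EpochedDataset(obj$X, obj$y, obj$fs, subject = obj$subject,
                 channels = obj$channels)
}
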