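#' @name accessors
#' @title Accessors for msfs S4 containers
#' @description Slot access for [FeatureBatch-class], [GateConfig-class] and
#'   [EpochedDataset-class] objects goes through these accessors.
#' @param x an msfs S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
#' @rdname accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))
#' @rdname accessors
#' @export
setGeneric("lossMin", function(x) standardGeneric("lossMin"))
#' @rdname accessors
#' @export
setGeneric("trialArray", function(x) standardGeneric("trialArray"))
#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureBatch", function(x) x@Z)
#' @rdname accessors
#' @export
setMethod("classLabels", "FeatureBatch", function(x) x@y)
#' @rdname accessors
#' @export
setMethod("nSamples", "FeatureBatch", function(x) nrow(x@Z))
#' @rdname accessors
#' @export
setMethod("nFeatures", "FeatureBatch", function(x) ncol(x@Z))
#' @rdname accessors
#' @export
setMethod("nClasses", "FeatureBatch", function(x) length(unique(x@y)))

#' @rdname accessors
#' @export
setMethod("omega", "GateConfig", function(x) x@omega)
#' @rdname accessors
#' @export
setMethod("lossMin", "GateConfig", function(x) x@lossMin)

#' @rdname accessors
#' @export
setMethod("trialArray", "EpochedDataset", function(x) x@X)
#' @rdname accessors
#' @export
setMethod("trialLabels", "EpochedDataset", function(x) x@y)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedDataset", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("subjectId", "EpochedDataset", function(x) x@subject)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochedDataset", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochedDataset", function(x) dim(x@X)[1])

#' Subset an EpochedDataset by trial index
#' @param x an [EpochedDataset-class].
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @return an [EpochedDataset-class] with the selected trials.
#' @export
setMethod("[", "EpochedDataset", function(x, i, j, ..., drop = FALSE) {
  new("EpochedDataset", X = x@X[i, , , drop = FALSE], y = x@y[i],
      fs = x@fs, subject = x@subject, channels = x@channels)
})

setMethod("show", "FeatureBatch", function(object) {
  cat("FeatureBatch:", nSamples(object), "samples x", nFeatures(object),
      "features,", nClasses(object), "classes\n")
  cat("  class counts:",
      paste(sprintf("%d:%d", sort(unique(object@y)),
                    tabulate(object@y)[sort(unique(object@y))]),
            collapse = " "), "\n")
})

setMethod("show", "GateConfig", function(object) {
  cat(sprintf("GateConfig: omega = %g, lossMin = %g\n",
              object@omega, object@lossMin))
})

setMethod("show", "EpochedDataset", function(object) {
  d <- dim(object@X)
  cat(sprintf("EpochedDataset '%s': %d trials x %d channels x %d samples @ %g Hz\n",
              object@subject, d[1], d[2], d[3], object@fs))
  cat("  classes:", paste(sort(unique(object@y)), collapse = ", "), "\n")
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(paste0("SynthSpec: %d subjects, %d classes x %d trials, ",
                     "%d ch x %d samples @ %g Hz\n"),
              object@nSubjects, object@nClasses, object@trialsPerClass,
              object@nChannels, object@nTimes, object@fs))
  cat(sprintf("  effectSize %.2f, subjectShift %.2f, noise %.1f uV, seed %d\n",
              object@effectSize, object@subjectShift, object@noiseLevel,
              object@seed))
})

setMethod("show", "TransferPlan", function(object) {
  cat(sprintf("TransferPlan: ep %d, ef %d, batch %d, lr %g, wd %g, %d run seed(s)\n",
              object@ep, object@ef, object@batchSize, object@lr,
              object@weightDecay, length(object@seeds)))
})
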