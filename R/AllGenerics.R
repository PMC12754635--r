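#' Accessors for entrainKit objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an entrainKit S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("itcValues", function(object) standardGeneric("itcValues"))

#' @rdname accessors
#' @export
setGeneric("bf10", function(object) standardGeneric("bf10"))

#' @rdname accessors
#' @export
setGeneric("inclusionStats", function(object) standardGeneric("inclusionStats"))

#' @rdname accessors
#' @export
setMethod("events", "EventTimeline", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EEGRecording", function(object) object@sampleRate)

#' @rdname accessors
#' @export
setMethod("sampleRate", "EpochSet", function(object) object@sampleRate)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @rdname accessors
#' @export
setMethod("channelNames", "ITCSpectrum", function(object) object@channelNames)

#' @rdname accessors
#' @export
setMethod("markers", "EEGRecording", function(object) object@markers)

#' @rdname accessors
#' @export
setMethod("signalData", "EEGRecording", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("processingLog", "EEGRecording", function(object) object@log)

#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])

#' @rdname accessors
#' @export
setMethod("nEpochs", "ITCSpectrum", function(object) object@nEpochs)

#' @rdname accessors
#' @export
setMethod("itcValues", "ITCSpectrum", function(object) {
  data.frame(frequency = object@frequencies, itc_avg = object@itcAvg)
})

#' @rdname accessors
#' @export
setMethod("bf10", "KendallBFResult", function(object) object@bf10)

#' @rdname accessors
#' @export
setMethod("inclusionStats", "BMAResult", function(object) object@predictors)

setMethod("show", "EventTimeline", function(object) {
  ev <- object@events
  cat(sprintf("EventTimeline (%s): %d events, %.1f s total\n",
              object@condition, nrow(ev), object@totalDuration))
  if (nrow(ev) > 0L) {
    tab <- table(ev$level)
    cat("  levels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sampleRate,
              ncol(object@data) / object@sampleRate))
  cat(sprintf("  markers: %d; excision seams: %d; log stages: %d\n",
              nrow(object@markers), length(object@seams), nrow(object@log)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet (%s): %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              object@condition, d[1L], d[2L], d[3L],
              object@epochLength, object@sampleRate))
})

setMethod("show", "ITCSpectrum", function(object) {
  cat(sprintf("ITCSpectrum (%s): %d channels, %d bins (%.4g-%.4g Hz, width %.4g Hz), N = %d epochs\n",
              object@condition, nrow(object@itc), length(object@frequencies),
              min(object@frequencies), max(object@frequencies),
              object@binWidth, object@nEpochs))
})

setMethod("show", "StretchedBetaPrior", function(object) {
  cat(sprintf("StretchedBetaPrior: kappa = %g (beta(%g, %g)), side = %s\n",
              object@kappa, 1 / object@kappa, 1 / object@kappa, object@side))
})

setMethod("show", "KendallBFResult", function(object) {
  cat(sprintf("Kendall tau-b Bayes factor (side = %s, kappa = %g)\n",
              object@prior@side, object@prior@kappa))
  cat(sprintf("  tau-b = %.3f, n = %d, BF10 = %.3f, 95%% CI [%.3f, %.3f], robust: %s\n",
              object@tauB, object@n, object@bf10,
              object@ci95[1L], object@ci95[2L],
              ifelse(isTRUE(object@robust), "yes", "no")))
})

setMethod("show", "BMAResult", function(object) {
  cat(sprintf("BMAResult: %d models, best model: %s\n",
              nrow(object@models), object@bestModel))
  print(object@predictors, digits = 3)
})
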