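#' Accessors for decalage classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptWords", function(x) standardGeneric("transcriptWords"))
#' @rdname accessors
#' @export
setMethod("transcriptWords", "Transcript", function(x) x@words)

#' @rdname accessors
#' @export
setGeneric("transcriptRole", function(x) standardGeneric("transcriptRole"))
#' @rdname accessors
#' @export
setMethod("transcriptRole", "Transcript", function(x) x@role)

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setMethod("direction", "Transcript", function(x) x@direction)
#' @rdname accessors
#' @export
setMethod("direction", "LoadSeries", function(x) x@direction)

#' @rdname accessors
#' @export
setGeneric("language", function(x) standardGeneric("language"))
#' @rdname accessors
#' @export
setMethod("language", "Transcript", function(x) x@language)

#' @rdname accessors
#' @export
setGeneric("estimationMethod", function(x) standardGeneric("estimationMethod"))
#' @rdname accessors
#' @export
setMethod("estimationMethod", "LoadSeries", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname accessors
#' @export
setMethod("breakpoints", "LoadSeries", function(x)
  data.frame(time = x@time, load = x@load))

#' @rdname accessors
#' @export
setGeneric("probeOnsets", function(x) standardGeneric("probeOnsets"))
#' @rdname accessors
#' @export
setMethod("probeOnsets", "ProbeTrain", function(x) x@onsets)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "ContinuousEEG", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "ContinuousEEG", function(x) x@srate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@srate)

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setMethod("signalData", "ContinuousEEG", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("signalData", "EpochSet", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("eegEvents", function(x) standardGeneric("eegEvents"))
#' @rdname accessors
#' @export
setMethod("eegEvents", "ContinuousEEG", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))
#' @rdname accessors
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setMethod("frequencies", "FrequencyTable", function(x) x@entries)

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript: %s (%s, %s), %d words",
              object@role, object@language, object@direction,
              nrow(object@words)))
  if (nrow(object@words))
    cat(sprintf(", %.1f-%.1f s", min(object@words$onset), max(object@words$offset)))
  cat("\n")
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable: %d lemmas, F in [%g, %g]\n",
              length(object@entries), object@Fmin, object@Fmax))
})

setMethod("show", "LoadSeries", function(object) {
  cat(sprintf("LoadSeries (%s) for %s/%s: %d breakpoints, load in [%g, %g]\n",
              object@method, object@subject, object@direction,
              length(object@time), min(object@load), max(object@load)))
})

setMethod("show", "ProbeTrain", function(object) {
  n <- length(object@onsets)
  cat(sprintf("ProbeTrain: %d probes", n))
  if (n > 1)
    cat(sprintf(", mean ISI %.1f ms", mean(diff(object@onsets)) * 1000))
  cat(sprintf(" (%g Hz, %g ms tone)\n", object@toneFreq, object@toneDur * 1000))
})

setMethod("show", "ContinuousEEG", function(object) {
  cat(sprintf("ContinuousEEG: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              ncol(object@data), nrow(object@data), object@srate,
              nrow(object@data) / object@srate, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
              d[1], d[2], d[3], object@srate,
              min(object@times), max(object@times)))
  if ("label" %in% names(object@info)) {
    tab <- table(object@info$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
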