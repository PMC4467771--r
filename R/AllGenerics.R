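#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("scheduleTrials", function(x) standardGeneric("scheduleTrials"))
#' @rdname accessors
#' @export
setGeneric("trialStreams", function(x) standardGeneric("trialStreams"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("selectedRegion", function(x) standardGeneric("selectedRegion"))
#' @rdname accessors
#' @export
setGeneric("statMap", function(x) standardGeneric("statMap"))

#' Accessors for the battery's S4 containers
#'
#' Small read-only accessors for \linkS4class{BatterySchedule},
#' \linkS4class{EEGRecording}, \linkS4class{EpochSet} and
#' \linkS4class{CMPTResult} objects.
#'
#' @param x an object of one of the classes above.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "CMPTResult", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("eegData", "EpochSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("eventTable", "EEGRecording", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[3])
#' @rdname accessors
#' @export
setMethod("scheduleTrials", "BatterySchedule", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("trialStreams", "BatterySchedule", function(x) x@streams)
#' @rdname accessors
#' @export
setMethod("vocabulary", "BatterySchedule", function(x) x@vocabulary)
#' @rdname accessors
#' @export
setMethod("clusterTable", "CMPTResult", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("pValue", "CMPTResult", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("selectedRegion", "CMPTResult", function(x) x@selectedRegion)
#' @rdname accessors
#' @export
setMethod("statMap", "CMPTResult", function(x) x@tmap)

setMethod("show", "BatterySchedule", function(object) {
  tr <- object@trials
  cat("BatterySchedule: 72 trials in 6 blocks (AT, WM, AR, AT, WM, AR)\n")
  cat("  vocabulary:", paste(object@vocabulary, collapse = ", "), "\n")
  cat("  stream words total:", sum(lengths(object@streams)),
      "| seed:", object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat(sprintf("  %d stimulus events\n", nrow(object@events)))
  invisible(NULL)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d epochs, %d channels x %d samples (%.0f to %.0f ms)%s\n",
    d[3], d[1], d[2], 1000 * min(object@times), 1000 * max(object@times),
    if (isTRUE(object@baselined)) ", baseline-corrected" else ""))
  invisible(NULL)
})

setMethod("show", "CMPTResult", function(object) {
  cat(sprintf("CMPTResult (%s level): %d cluster(s), overall p = %.4g\n",
              object@level, nrow(object@clusters), object@p))
  if (nrow(object@clusters)) {
    cl <- object@clusters[1, ]
    cat(sprintf("  largest: mass %.1f (%s), %d points, %.0f-%.0f ms, p = %.4g\n",
                cl$mass, ifelse(cl$sign > 0, "+", "-"), cl$size,
                1000 * cl$t_start, 1000 * cl$t_end, cl$p))
  }
  cat(sprintf("  threshold |t| > %.3f, %s permutations\n", object@threshold,
              if (object@nPerm > 0) format(object@nPerm) else "exhaustive"))
  invisible(NULL)
})
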