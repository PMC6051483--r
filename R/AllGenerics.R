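# Accessor generics. Slots are never reached into by user code; these are
# the supported surface.

#' @name accessors
#' @title Accessors for lfpdec containers
#' @param object an lfpdec container object.
#' @description Small accessor family: sampling rate, identifiers, counts,
#'   sample/value matrices and time axes.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("kernels", function(object) standardGeneric("kernels"))
#' @rdname accessors
#' @export
setGeneric("lagGrid", function(object) standardGeneric("lagGrid"))
#' @rdname accessors
#' @export
setGeneric("areaLabels", function(object) standardGeneric("areaLabels"))

#' @rdname accessors
setMethod("samplingRate", "LfpRecording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "ArealVelocitySignal", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "ArealVelocityVector", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "KinematicsTrace", function(object)
  1 / diff(object@times[1:2]))

#' @rdname accessors
setMethod("channelIds", "LfpRecording", function(object) object@channelIds)
#' @rdname accessors
setMethod("channelIds", "SrspModel", function(object) object@channelIds)
#' @rdname accessors
setMethod("channelIds", "RateDecoder", function(object) object@channelIds)

#' @rdname accessors
setMethod("unitIds", "SpikeTrainSet", function(object) object@unitIds)
#' @rdname accessors
setMethod("unitIds", "BinnedRates", function(object) object@unitIds)
#' @rdname accessors
setMethod("unitIds", "SrspModel", function(object) object@unitIds)
#' @rdname accessors
setMethod("unitIds", "SrspBasis", function(object) object@unitIds)
#' @rdname accessors
setMethod("unitIds", "RateDecoder", function(object) object@unitIds)

#' @rdname accessors
setMethod("nChannels", "LfpRecording", function(object) ncol(object@samples))
#' @rdname accessors
setMethod("nChannels", "SrspModel", function(object) length(object@channelIds))
#' @rdname accessors
setMethod("nUnits", "SpikeTrainSet", function(object) length(object@unitIds))
#' @rdname accessors
setMethod("nUnits", "BinnedRates", function(object) ncol(object@values))
#' @rdname accessors
setMethod("nUnits", "SrspModel", function(object) length(object@unitIds))

#' @rdname accessors
setMethod("startTime", "LfpRecording", function(object) object@tStart)
#' @rdname accessors
setMethod("startTime", "BinnedRates", function(object) object@tStart)
#' @rdname accessors
setMethod("startTime", "ArealVelocitySignal", function(object) object@tStart)
#' @rdname accessors
setMethod("startTime", "ArealVelocityVector", function(object) object@tStart)
#' @rdname accessors
setMethod("startTime", "SpikeTrainSet", function(object) object@tStart)
#' @rdname accessors
setMethod("startTime", "KinematicsTrace", function(object) object@times[1])

#' @rdname accessors
setMethod("values", "LfpRecording", function(object) object@samples)
#' @rdname accessors
setMethod("values", "BinnedRates", function(object) object@values)
#' @rdname accessors
setMethod("values", "ArealVelocitySignal", function(object) object@values)
#' @rdname accessors
setMethod("values", "ArealVelocityVector", function(object) object@values)
#' @rdname accessors
setMethod("values", "KinematicsTrace", function(object) object@position)

#' @rdname accessors
setMethod("timeAxis", "LfpRecording", function(object)
  object@tStart + (seq_len(nrow(object@samples)) - 1L) / object@fs)
#' @rdname accessors
setMethod("timeAxis", "BinnedRates", function(object)
  object@tStart + (seq_len(nrow(object@values)) - 1L) * object@binWidth)
#' @rdname accessors
setMethod("timeAxis", "ArealVelocitySignal", function(object)
  object@tStart + (seq_along(object@values) - 1L) / object@fs)
#' @rdname accessors
setMethod("timeAxis", "ArealVelocityVector", function(object)
  object@tStart + (seq_len(nrow(object@values)) - 1L) / object@fs)
#' @rdname accessors
setMethod("timeAxis", "KinematicsTrace", function(object) object@times)

#' @rdname accessors
setMethod("spikeTimes", "SpikeTrainSet", function(object) {
  st <- object@spikeTimes
  names(st) <- object@unitIds
  st
})

#' @rdname accessors
setMethod("kernels", "SrspModel", function(object) {
  k <- object@kernels
  dimnames(k) <- list(object@unitIds, object@channelIds, NULL)
  k
})
#' @rdname accessors
setMethod("lagGrid", "SrspModel", function(object) object@lags)
#' @rdname accessors
setMethod("lagGrid", "RateDecoder", function(object) object@lags)

#' @rdname accessors
setMethod("areaLabels", "LfpRecording", function(object) object@areaLabels)
#' @rdname accessors
setMethod("areaLabels", "SpikeTrainSet", function(object) object@areaLabels)

#' Plane basis vectors
#'
#' @param object a [ProjectionPlane-class].
#' @return 2-column matrix cbind(u, v).
#' @export
setGeneric("planeVectors", function(object) standardGeneric("planeVectors"))
#' @rdname planeVectors
setMethod("planeVectors", "ProjectionPlane", function(object)
  cbind(u = object@u, v = object@v))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SpikeTrainSet", function(object) {
  n <- vapply(object@spikeTimes, length, 1L)
  cat(sprintf("SpikeTrainSet: %d units, %d spikes, span [%.3f, %.3f] s\n",
              length(object@unitIds), sum(n), object@tStart, object@tStop))
})

setMethod("show", "LfpRecording", function(object) {
  cat(sprintf("LfpRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@samples), nrow(object@samples), object@fs,
              nrow(object@samples) / object@fs))
})

setMethod("show", "BinnedRates", function(object) {
  cat(sprintf("BinnedRates: %d bins x %d units, bin %g s (%s)\n",
              nrow(object@values), ncol(object@values), object@binWidth,
              if (object@isCounts) "counts" else "Hz"))
})

setMethod("show", "SrspModel", function(object) {
  d <- dim(object@kernels)
  cat(sprintf(paste0("SrspModel: %d units x %d channels x %d lags ",
                     "[%+.3f, %+.3f] s, ridge %g\n"),
              d[1], d[2], d[3], min(object@lags), max(object@lags),
              object@ridge))
  cat(sprintf("  fitted-span VAF: median %.3f\n",
              stats::median(object@vaf, na.rm = TRUE)))
})

setMethod("show", "SrspBasis", function(object) {
  ks <- vapply(object@waveforms, ncol, 1L)
  cat(sprintf("SrspBasis: %d units, %s sources each\n",
              length(object@unitIds), paste(unique(ks), collapse = "/")))
})

setMethod("show", "RateDecoder", function(object) {
  cat(sprintf(
    "RateDecoder: %d units from %d channels, FIR span [%+.3f, %+.3f] s, nsr %g\n",
    length(object@unitIds), length(object@channelIds),
    min(object@lags), max(object@lags), object@nsr))
})

setMethod("show", "ProjectionPlane", function(object) {
  cat(sprintf("ProjectionPlane (%s): %d channels%s\n", object@provenance,
              length(object@u),
              if (is.finite(object@freqHz))
                sprintf(", rotation ~%.2f Hz", object@freqHz) else ""))
})

setMethod("show", "ArealVelocitySignal", function(object) {
  cat(sprintf("ArealVelocitySignal [%s]: %d samples @ %g Hz, mean %.4g\n",
              object@id, length(object@values), object@fs,
              mean(object@values)))
})

setMethod("show", "ArealVelocityVector", function(object) {
  cat(sprintf("ArealVelocityVector: %d samples @ %g Hz\n",
              nrow(object@values), object@fs))
})

setMethod("show", "SubmovementEvents", function(object) {
  cat(sprintf("SubmovementEvents: %d events", length(object@times)))
  if (length(object@times) > 1)
    cat(sprintf(", rate %.2f /s", (length(object@times) - 1) /
                  diff(range(object@times))))
  cat("\n")
})

setMethod("show", "ModelContainer", function(object) {
  cat(sprintf("ModelContainer <%s>: arrays {%s}\n", object@modelKind,
              paste(names(object@payload), collapse = ", ")))
})

#' Convert submovement events to a data.frame
#'
#' @param x a [SubmovementEvents-class].
#' @param ... unused.
#' @return data.frame with time, speed, direction, window bounds.
#' @export
as.data.frame.SubmovementEvents <- function(x, ...) {
  data.frame(time_s = x@times, speed = x@speeds, direction_rad = x@directions,
             window_start_s = x@windowStart, window_end_s = x@windowEnd)
}
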