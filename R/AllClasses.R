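#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core data containers. Time is always seconds (double); LFP channel order is
# defined by header order and preserved everywhere -- pairwise areal-velocity
# indices refer to this order.
# ---------------------------------------------------------------------------

#' Spike event times for a set of sorted units
#'
#' Container for per-unit sorted spike event times with optional cortical
#' area labels. Spike times are in seconds and must lie within
#' `[tStart, tStop]`; units with no spikes are retained as empty vectors.
#'
#' @slot unitIds character vector of unique unit identifiers.
#' @slot areaLabels character vector, one label per unit (e.g. "M1", "PMv").
#' @slot spikeTimes list of numeric vectors, sorted ascending, seconds.
#' @slot tStart,tStop numeric scalars delimiting the recording span.
#' @export
setClass("SpikeTrainSet",
  representation(unitIds = "character", areaLabels = "character",
                 spikeTimes = "list", tStart = "numeric", tStop = "numeric"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@unitIds))
      msg <- c(msg, "unit ids must be unique")
    if (length(object@spikeTimes) != length(object@unitIds))
      msg <- c(msg, "one spike-time vector per unit required")
    if (length(object@areaLabels) != length(object@unitIds))
      msg <- c(msg, "one area label per unit required")
    if (length(object@tStart) != 1L || length(object@tStop) != 1L ||
        object@tStop <= object@tStart)
      msg <- c(msg, "tStart/tStop must be scalars with tStop > tStart")
    for (i in seq_along(object@spikeTimes)) {
      st <- object@spikeTimes[[i]]
      if (length(st) == 0L) next
      if (is.unsorted(st, strictly = FALSE))
        msg <- c(msg, sprintf("spike times of unit '%s' are not sorted",
                              object@unitIds[i]))
      if (min(st) < object@tStart || max(st) > object@tStop)
        msg <- c(msg, sprintf("spike times of unit '%s' fall outside [tStart, tStop]",
                              object@unitIds[i]))
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn SpikeTrainSet constructor.
#' @param unitIds,areaLabels,spikeTimes,tStart,tStop see slots.
#' @export
SpikeTrainSet <- function(unitIds, spikeTimes, tStart, tStop,
                          areaLabels = rep(NA_character_, length(unitIds))) {
  new("SpikeTrainSet", unitIds = as.character(unitIds),
      areaLabels = as.character(areaLabels),
      spikeTimes = lapply(spikeTimes, as.numeric),
      tStart = as.numeric(tStart), tStop = as.numeric(tStop))
}

#' Multichannel LFP recording
#'
#' A time x channel matrix of potentials sampled uniformly at `fs` Hz.
#' Potential units are arbitrary (microvolt-like); all downstream outputs are
#' scale-covariant and documented as such.
#'
#' @slot samples numeric matrix, rows = samples, columns = channels.
#' @slot fs sampling rate, Hz.
#' @slot channelIds character vector of unique channel identifiers.
#' @slot areaLabels per-channel labels.
#' @slot tStart time of the first sample, seconds.
#' @slot metadata free-form list (filter provenance, edge flags, ...).
#' @export
setClass("LfpRecording",
  representation(samples = "matrix", fs = "numeric", channelIds = "character",
                 areaLabels = "character", tStart = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@samples) || anyNA(object@samples))
      msg <- c(msg, "samples must be numeric with no missing values")
    if (nrow(object@samples) < 2L) msg <- c(msg, "need at least 2 samples")
    if (ncol(object@samples) < 1L) msg <- c(msg, "need at least 1 channel")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar")
    if (length(object@channelIds) != ncol(object@samples))
      msg <- c(msg, "one channel id per column required")
    if (anyDuplicated(object@channelIds))
      msg <- c(msg, "channel ids must be unique")
    if (length(msg)) msg else TRUE
  })

#' @describeIn LfpRecording constructor.
#' @param samples,fs,channelIds,areaLabels,tStart,metadata see slots.
#' @export
LfpRecording <- function(samples, fs,
                         channelIds = paste0("ch", seq_len(ncol(samples))),
                         areaLabels = rep(NA_character_, ncol(samples)),
                         tStart = 0, metadata = list()) {
  new("LfpRecording", samples = as.matrix(samples), fs = as.numeric(fs),
      channelIds = as.character(channelIds),
      areaLabels = as.character(areaLabels), tStart = as.numeric(tStart),
      metadata = metadata)
}

#' 2D cursor kinematics
#'
#' Uniformly sampled cursor position trace (task units).
#'
#' @slot times numeric, seconds, uniformly spaced.
#' @slot position numeric matrix, time x 2 (x, y).
#' @export
setClass("KinematicsTrace",
  representation(times = "numeric", position = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@position) != length(object@times))
      msg <- c(msg, "times and position must have equal length")
    if (ncol(object@position) != 2L)
      msg <- c(msg, "position must have 2 columns (x, y)")
    if (length(object@times) >= 3L) {
      dt <- diff(object@times)
      if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
        msg <- c(msg, "times must be uniformly spaced")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn KinematicsTrace constructor.
#' @param times,position see slots.
#' @export
KinematicsTrace <- function(times, position) {
  new("KinematicsTrace", times = as.numeric(times),
      position = as.matrix(position))
}

#' Binned spike counts or rates
#'
#' Time-bin x unit matrix on half-open bins `[t, t + binWidth)` tiling the
#' recording span. When `isCounts` is TRUE the column sums equal the total
#' number of spikes per unit.
#'
#' @slot values numeric matrix, bins x units.
#' @slot binWidth bin width, seconds.
#' @slot tStart left edge of the first bin, seconds.
#' @slot unitIds unit identifiers (column order).
#' @slot isCounts logical; counts (TRUE) or rates in Hz (FALSE).
#' @export
setClass("BinnedRates",
  representation(values = "matrix", binWidth = "numeric", tStart = "numeric",
                 unitIds = "character", isCounts = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
    if (length(object@unitIds) != ncol(object@values))
      msg <- c(msg, "one unit id per column required")
    if (isTRUE(object@isCounts) && any(object@values < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @describeIn BinnedRates constructor.
#' @param values,binWidth,tStart,unitIds,isCounts see slots.
#' @export
BinnedRates <- function(values, binWidth, tStart = 0,
                        unitIds = paste0("u", seq_len(ncol(values))),
                        isCounts = TRUE) {
  new("BinnedRates", values = as.matrix(values), binWidth = as.numeric(binWidth),
      tStart = as.numeric(tStart), unitIds = as.character(unitIds),
      isCounts = isCounts)
}

#' Principal-component basis in channel space
#'
#' @slot center per-channel mean removed before fitting.
#' @slot components channel x k matrix of orthonormal component vectors.
#' @slot varianceFractions explained variance fractions, descending.
#' @export
setClass("PcaBasis",
  representation(center = "numeric", components = "matrix",
                 varianceFractions = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@components)
    g <- crossprod(object@components)
    if (max(abs(g - diag(k))) > 1e-8)
      msg <- c(msg, "components must be orthonormal")
    vf <- object@varianceFractions
    if (length(vf) != k) msg <- c(msg, "one variance fraction per component")
    if (any(diff(vf) > 1e-12)) msg <- c(msg, "variance fractions must be descending")
    if (sum(vf) > 1 + 1e-10) msg <- c(msg, "variance fractions must sum to <= 1")
    if (length(msg)) msg else TRUE
  })

#' A plane in LFP channel space
#'
#' Pair of orthonormal channel-space vectors (u, v) defining the plane in
#' which an areal-velocity signal is measured. Counter-clockwise rotation in
#' (u, v) coordinates is the positive sign convention.
#'
#' @slot u,v orthonormal numeric vectors of length = channel count.
#' @slot provenance one of "pca", "jpca", "custom".
#' @slot freqHz rotation frequency estimate (Hz; NA when unknown).
#' @export
setClass("ProjectionPlane",
  representation(u = "numeric", v = "numeric", provenance = "character",
                 freqHz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@u) != length(object@v))
      msg <- c(msg, "u and v must have equal length")
    if (abs(sum(object@u^2) - 1) > 1e-10 || abs(sum(object@v^2) - 1) > 1e-10)
      msg <- c(msg, "u and v must have unit norm")
    if (abs(sum(object@u * object@v)) > 1e-10)
      msg <- c(msg, "u and v must be orthogonal")
    if (!object@provenance %in% c("pca", "jpca", "custom"))
      msg <- c(msg, "provenance must be pca, jpca or custom")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ProjectionPlane constructor.
#' @param u,v,provenance,freqHz see slots.
#' @export
ProjectionPlane <- function(u, v, provenance = "custom", freqHz = NA_real_) {
  new("ProjectionPlane", u = as.numeric(u), v = as.numeric(v),
      provenance = provenance, freqHz = as.numeric(freqHz))
}

#' Areal-velocity time series
#'
#' Area swept per unit time by the LFP trajectory in a plane or channel
#' pair; units are (LFP units)^2 per second. Pairwise signals are
#' antisymmetric under index swap and only the i < j member is stored.
#'
#' @slot values numeric vector.
#' @slot fs sampling rate, Hz.
#' @slot tStart seconds.
#' @slot id human-readable identity, e.g. "plane:jpca1" or "pair:2-5".
#' @export
setClass("ArealVelocitySignal",
  representation(values = "numeric", fs = "numeric", tStart = "numeric",
                 id = "character"),
  validity = function(object) {
    if (anyNA(object@values) || any(!is.finite(object@values)))
      "values must be finite" else TRUE
  })

#' Three-dimensional areal-velocity vector series
#'
#' Components (AV_23, AV_31, AV_12) of 0.5 * x cross xdot for a trajectory
#' projected on three principal components; the vector's magnitude is the
#' planar areal velocity in the instantaneous plane of rotation and its
#' direction is the rotation axis.
#'
#' @slot values numeric matrix, time x 3.
#' @slot fs sampling rate, Hz.
#' @slot tStart seconds.
#' @export
setClass("ArealVelocityVector",
  representation(values = "matrix", fs = "numeric", tStart = "numeric"),
  validity = function(object) {
    if (ncol(object@values) != 3L) "values must have 3 columns" else TRUE
  })

# ---------------------------------------------------------------------------
# Fitted-model containers
# ---------------------------------------------------------------------------

#' Fitted MISO spike-to-LFP model (SRSPs)
#'
#' Per-(unit, channel) acausal impulse responses: the spike-related slow
#' potentials. A kernel value at lag tau contributes to the LFP at time
#' t from a spike at time t - tau, so negative lags describe LFP preceding
#' the spike.
#'
#' @slot kernels numeric array unit x channel x lag (LFP units per spike).
#' @slot lags lag grid, seconds, from -tPre to +tPost at binWidth spacing.
#' @slot binWidth seconds.
#' @slot offsets per-channel DC offsets.
#' @slot ridge regularization strength used.
#' @slot vaf per-channel variance accounted for on the fitted span.
#' @slot unitIds,channelIds identifiers.
#' @export
setClass("SrspModel",
  representation(kernels = "array", lags = "numeric", binWidth = "numeric",
                 offsets = "numeric", ridge = "numeric", vaf = "numeric",
                 unitIds = "character", channelIds = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@kernels)
    if (length(d) != 3L) msg <- c(msg, "kernels must be unit x channel x lag")
    else {
      if (d[1] != length(object@unitIds)) msg <- c(msg, "unit dimension mismatch")
      if (d[2] != length(object@channelIds)) msg <- c(msg, "channel dimension mismatch")
      if (d[3] != length(object@lags)) msg <- c(msg, "lag dimension mismatch")
    }
    if (any(!is.finite(object@kernels))) msg <- c(msg, "kernels must be finite")
    if (any(object@vaf > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "variance accounted for cannot exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Per-unit SRSP principal-component decomposition
#'
#' For each unit, the channel x lag SRSP matrix is decomposed into a few
#' principal-component waveforms (lag space, orthonormal) with channel
#' loadings; source-projection vectors (least-squares demixing) are the
#' pseudoinverse of the loading matrix.
#'
#' @slot unitIds unit identifiers.
#' @slot waveforms list of lag x k orthonormal PC waveform matrices.
#' @slot loadings list of channel x k loading matrices.
#' @slot projections list of k x channel source-projection matrices.
#' @slot varianceFractions list of descending explained-variance fractions.
#' @slot lags lag grid, seconds.
#' @slot binWidth seconds.
#' @slot channelIds channel identifiers.
#' @export
setClass("SrspBasis",
  representation(unitIds = "character", waveforms = "list",
                 loadings = "list", projections = "list",
                 varianceFractions = "list", lags = "numeric",
                 binWidth = "numeric", channelIds = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@unitIds)
    if (length(object@waveforms) != n || length(object@loadings) != n ||
        length(object@projections) != n)
      msg <- c(msg, "per-unit lists must match unitIds length")
    for (i in seq_len(n)) {
      w <- object@waveforms[[i]]
      g <- crossprod(w)
      if (max(abs(g - diag(ncol(w)))) > 1e-8)
        msg <- c(msg, sprintf("PC waveforms of unit '%s' not orthonormal",
                              object@unitIds[i]))
    }
    if (length(msg)) msg else TRUE
  })

#' FIR firing-rate decoder
#'
#' Per-unit FIR filter bank over LFP channels realizing Wiener deconvolution
#' of the SRSP source signals plus a least-squares source combination. The
#' rate estimate at bin t depends only on the LFP within the filter's lag
#' window around t.
#'
#' @slot filters list (per unit) of channel x lag coefficient matrices.
#' @slot lags filter lag grid, seconds (acausal).
#' @slot binWidth output bin width, seconds.
#' @slot offsets per-unit output offset (mean rate).
#' @slot nsr Wiener noise-to-signal parameter used.
#' @slot unitIds,channelIds identifiers.
#' @export
setClass("RateDecoder",
  representation(filters = "list", lags = "numeric", binWidth = "numeric",
                 offsets = "numeric", nsr = "numeric",
                 unitIds = "character", channelIds = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@filters) != length(object@unitIds))
      msg <- c(msg, "one filter matrix per unit required")
    for (f in object@filters)
      if (any(!is.finite(f))) msg <- c(msg, "filter coefficients must be finite")
    if (length(msg)) msg else TRUE
  })

#' Detected submovement events
#'
#' @slot times speed-peak times, seconds, sorted.
#' @slot speeds peak speeds, task units per second, positive.
#' @slot directions radians in (-pi, pi], angle of net displacement between
#'   the flanking speed minima.
#' @slot windowStart,windowEnd per-event window bounds (flanking minima).
#' @export
setClass("SubmovementEvents",
  representation(times = "numeric", speeds = "numeric",
                 directions = "numeric", windowStart = "numeric",
                 windowEnd = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (n && is.unsorted(object@times)) msg <- c(msg, "event times must be sorted")
    if (any(object@speeds <= 0)) msg <- c(msg, "peak speeds must be positive")
    if (n && (length(object@speeds) != n || length(object@directions) != n))
      msg <- c(msg, "speeds/directions must match times length")
    if (any(object@directions <= -pi | object@directions > pi))
      msg <- c(msg, "directions must lie in (-pi, pi]")
    if (length(msg)) msg else TRUE
  })

#' Generic persisted-model container
#'
#' One-file container holding named numeric arrays plus metadata; used by
#' [writeModel()] / [readModel()]. Round-trips bit-exactly for metadata and
#' to full floating precision for arrays.
#'
#' @slot modelKind one of "srsp", "rate_decoder", "rotation", "ground_truth".
#' @slot metadata named list (seed, config hash, creation time, ...).
#' @slot payload named list of numeric arrays.
#' @export
setClass("ModelContainer",
  representation(modelKind = "character", metadata = "list",
                 payload = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@modelKind %in% c("srsp", "rate_decoder", "rotation",
                                 "ground_truth"))
      msg <- c(msg, sprintf("unknown model kind '%s'", object@modelKind))
    for (p in object@payload)
      if (is.numeric(p) && any(!is.finite(p)))
        msg <- c(msg, "payload arrays must be finite")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ModelContainer constructor.
#' @param modelKind,metadata,payload see slots.
#' @export
ModelContainer <- function(modelKind, payload = list(), metadata = list()) {
  new("ModelContainer", modelKind = modelKind, metadata = metadata,
      payload = payload)
}
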