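# Shared preprocessing: zero-phase band filtering, binning, derivatives,
# PCA. Areal velocity is phase-sensitive, so every filter here is applied
# forward-backward (zero phase).

## Forward-backward IIR filtering with odd-reflection padding and
## steady-state initialization at the signal ends (the padding/state
## handling keeps edge transients out of the output; a constant signal
## passes through a unity-DC-gain filter bit-exactly).
zeroPhaseFilter <- function(bf, x) {
  b <- bf$b
  a <- bf$a
  n <- max(length(a), length(b))
  nfact <- 3L * (n - 1L)
  nx <- length(x)
  if (nx <= nfact + 1L)
    stop("signal too short for zero-phase filtering", call. = FALSE)
  pre <- 2 * x[1] - x[seq.int(nfact + 1L, 2L)]
  post <- 2 * x[nx] - x[seq.int(nx - 1L, nx - nfact)]
  xx <- c(pre, x, post)
  G0 <- sum(b) / sum(a)
  oneWay <- function(z)
    as.numeric(signal::filter(b, a, z, init = rep(z[1] * G0, n - 1L),
                              init.x = rep(z[1], n - 1L)))
  y <- oneWay(xx)
  y <- rev(oneWay(rev(y)))
  y[seq.int(nfact + 1L, nfact + nx)]
}

#' Zero-phase low-pass filtering (local motor potential extraction)
#'
#' Applies a Butterworth low-pass (default 4th order at 5 Hz) forward and
#' backward to every channel, isolating the slow (<5 Hz) component of the
#' LFP that carries movement-related information. Output length equals input
#' length and the filter introduces no phase shift.
#'
#' @param lfp an [LfpRecording-class].
#' @param cutoffHz cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (of the one-way filter; the forward-backward
#'   application squares its magnitude response).
#' @return an [LfpRecording-class] of the same dimensions.
#' @export
lowpassLmp <- function(lfp, cutoffHz = 5, order = 4) {
  checkScalar(cutoffHz, "cutoffHz", lower = 1e-12)
  if (cutoffHz >= lfp@fs / 2)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoffHz, lfp@fs / 2), call. = FALSE)
  bf <- signal::butter(order, cutoffHz / (lfp@fs / 2), type = "low")
  out <- apply(lfp@samples, 2L, function(x) zeroPhaseFilter(bf, x))
  LfpRecording(out, fs = lfp@fs, channelIds = lfp@channelIds,
               areaLabels = lfp@areaLabels, tStart = lfp@tStart,
               metadata = c(lfp@metadata,
                            list(filter = sprintf("butter%d-lp%gHz-zerophase",
                                                  order, cutoffHz))))
}

#' Zero-phase band-pass filtering
#'
#' @param lfp an [LfpRecording-class].
#' @param fLo,fHi band edges, Hz, `0 <= fLo < fHi < fs/2`. `fLo = 0` reduces
#'   to a low-pass.
#' @param order filter order.
#' @return an [LfpRecording-class].
#' @export
bandpassLfp <- function(lfp, fLo, fHi, order = 4) {
  nyq <- lfp@fs / 2
  if (!(fLo >= 0 && fLo < fHi && fHi < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for fs = %g Hz", fLo, fHi, lfp@fs),
         call. = FALSE)
  bf <- if (fLo <= 0) signal::butter(order, fHi / nyq, type = "low")
        else signal::butter(order, c(fLo, fHi) / nyq, type = "pass")
  out <- apply(lfp@samples, 2L, function(x) zeroPhaseFilter(bf, x))
  LfpRecording(out, fs = lfp@fs, channelIds = lfp@channelIds,
               areaLabels = lfp@areaLabels, tStart = lfp@tStart,
               metadata = c(lfp@metadata,
                            list(filter = sprintf("butter%d-bp%g-%gHz", order,
                                                  fLo, fHi))))
}

#' Bin spike trains into counts
#'
#' Half-open bins `[t, t + binWidth)` tiling `[tStart, tStop]`; the total
#' count over bins equals the number of spikes exactly.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param binWidth bin width, seconds.
#' @param alignTo left edge of the first bin (default: the set's tStart).
#' @return a [BinnedRates-class] of counts.
#' @export
binSpikes <- function(spikes, binWidth = 0.01, alignTo = NULL) {
  checkScalar(binWidth, "binWidth", lower = 1e-12)
  t0 <- alignTo %||% spikes@tStart
  nBins <- max(1L, ceiling((spikes@tStop - t0) / binWidth - 1e-9))
  counts <- matrix(0, nBins, length(spikes@unitIds))
  for (i in seq_along(spikes@spikeTimes)) {
    st <- spikes@spikeTimes[[i]]
    st <- st[st >= t0 & st <= t0 + nBins * binWidth]
    if (!length(st)) next
    idx <- floor((st - t0) / binWidth) + 1L
    idx[idx > nBins] <- nBins    # a spike exactly at the right edge
    tab <- tabulate(idx, nbins = nBins)
    counts[, i] <- tab
  }
  BinnedRates(counts, binWidth = binWidth, tStart = t0,
              unitIds = spikes@unitIds, isCounts = TRUE)
}

#' Time derivative of a multichannel signal
#'
#' Central differences in the interior, one-sided differences at the ends;
#' output in signal units per second.
#'
#' @param lfp an [LfpRecording-class] with at least 3 samples.
#' @return an [LfpRecording-class] holding the derivative.
#' @export
timeDerivative <- function(lfp) {
  n <- nrow(lfp@samples)
  if (n < 3L) stop("need at least 3 samples for a derivative", call. = FALSE)
  d <- derivMatrix(lfp@samples, lfp@fs)
  LfpRecording(d, fs = lfp@fs, channelIds = lfp@channelIds,
               areaLabels = lfp@areaLabels, tStart = lfp@tStart,
               metadata = c(lfp@metadata, list(derivative = TRUE)))
}

## matrix central-difference core (shared with areal-velocity code so the
## projected-then-differentiated and differentiated-then-projected routes
## agree exactly)
derivMatrix <- function(m, fs) {
  n <- nrow(m)
  d <- matrix(0, n, ncol(m))
  d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) *
    (fs / 2)
  d[1, ] <- (m[2, ] - m[1, ]) * fs
  d[n, ] <- (m[n, ] - m[n - 1, ]) * fs
  d
}

#' Principal component analysis of a multichannel recording
#'
#' Covariance PCA over the full provided span: per-channel means are
#' removed, variances are not normalized (amplitude information is
#' preserved for areal-velocity work). Components are ordered by descending
#' variance with a deterministic sign convention: the largest-magnitude
#' coefficient of each component is positive.
#'
#' @param lfp an [LfpRecording-class].
#' @param nComponents number of components to retain (<= channel count).
#' @return a [PcaBasis-class].
#' @export
fitPca <- function(lfp, nComponents = nChannels(lfp)) {
  x <- lfp@samples
  if (nComponents > ncol(x))
    stop("nComponents exceeds the channel count", call. = FALSE)
  vars <- apply(x, 2L, stats::var)
  if (any(vars <= .Machine$double.eps)) {
    bad <- lfp@channelIds[vars <= .Machine$double.eps]
    stop(sprintf("degenerate input: zero-variance channel(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc, nu = 0, nv = ncol(x))
  ev <- sv$d^2 / (nrow(x) - 1)
  comp <- sv$v[, seq_len(nComponents), drop = FALSE]
  # deterministic sign: largest-|coefficient| entry positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  new("PcaBasis", center = ctr, components = comp,
      varianceFractions = ev[seq_len(nComponents)] / sum(ev))
}

#' Project a recording onto a PCA basis (and back)
#'
#' `projectLfp` returns component scores (centered projection); with
#' `reconstruct = TRUE` the scores are mapped back to channel space and the
#' mean restored.
#'
#' @param lfp an [LfpRecording-class].
#' @param basis a [PcaBasis-class] fitted on compatible channels.
#' @param reconstruct return the rank-k reconstruction instead of scores.
#' @return an [LfpRecording-class] (scores labelled pc1..pck, or channels).
#' @export
projectLfp <- function(lfp, basis, reconstruct = FALSE) {
  if (length(basis@center) != ncol(lfp@samples))
    stop("basis channel count does not match the recording", call. = FALSE)
  sc <- sweep(lfp@samples, 2L, basis@center) %*% basis@components
  if (!reconstruct)
    return(LfpRecording(sc, fs = lfp@fs,
                        channelIds = paste0("pc", seq_len(ncol(sc))),
                        tStart = lfp@tStart))
  rec <- sweep(sc %*% t(basis@components), 2L, basis@center, `+`)
  LfpRecording(rec, fs = lfp@fs, channelIds = lfp@channelIds,
               areaLabels = lfp@areaLabels, tStart = lfp@tStart)
}

#' Resample an LFP onto a coarser bin grid by averaging
#'
#' Used to bring the LFP onto the spike-bin grid before MISO fitting: each
#' output bin is the mean of the `fs * binWidth` samples it covers.
#'
#' @param lfp an [LfpRecording-class].
#' @param binWidth target bin width, seconds; must be an integer multiple of
#'   the sample interval (to 1e-6 relative).
#' @return an [LfpRecording-class] at `1/binWidth` Hz.
#' @export
resampleLfp <- function(lfp, binWidth) {
  step <- binWidth * lfp@fs
  if (abs(step - round(step)) > 1e-6)
    stop("binWidth must be an integer multiple of the sample interval",
         call. = FALSE)
  step <- as.integer(round(step))
  if (step == 1L) return(lfp)
  n <- nrow(lfp@samples) %/% step
  idx <- rep(seq_len(n), each = step)
  out <- apply(lfp@samples[seq_len(n * step), , drop = FALSE], 2L,
               function(x) as.numeric(tapply(x, idx, mean)))
  dimnames(out) <- NULL
  LfpRecording(out, fs = 1 / binWidth, channelIds = lfp@channelIds,
               areaLabels = lfp@areaLabels, tStart = lfp@tStart)
}

#' Smooth binned counts into instantaneous rates
#'
#' Converts counts to Hz and applies the zero-phase low-pass of
#' [lowpassLmp()]; used when comparing spiking to rate estimates derived
#' from the slow LFP.
#'
#' @param rates a [BinnedRates-class] of counts (or rates).
#' @param cutoffHz smoothing cutoff, Hz.
#' @param order filter order.
#' @return a [BinnedRates-class] of rates in Hz.
#' @export
smoothRates <- function(rates, cutoffHz = 5, order = 4) {
  fs <- 1 / rates@binWidth
  hz <- if (rates@isCounts) rates@values / rates@binWidth else rates@values
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  sm <- apply(hz, 2L, function(x) zeroPhaseFilter(bf, x))
  BinnedRates(sm, binWidth = rates@binWidth, tStart = rates@tStart,
              unitIds = rates@unitIds, isCounts = FALSE)
}
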