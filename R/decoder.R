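# From SRSPs to real-time firing-rate estimates.
#
# Pipeline per unit: (1) decompose the channel x lag SRSP matrix into a few
# principal-component waveforms with channel loadings; (2) source
# projections = pseudoinverse of the loadings (least-squares demixing of
# the LFP into per-source signals); (3) Wiener-deconvolve each source
# signal by its PC waveform, H*(f) / (|H(f)|^2 + nsr); (4) combine the
# deconvolved sources by ordinary least squares against training rates (the
# only supervised step). The whole chain is linear and time-invariant, so
# it is collapsed into one acausal FIR filter bank per unit and applied by
# pure filtering at run time.

#' Decompose SRSPs into principal-component waveforms and sources
#'
#' For each unit, an (uncentered) SVD of the channel x lag kernel matrix
#' yields orthonormal PC waveforms in lag space with channel loadings; the
#' source-projection matrix is the Moore-Penrose pseudoinverse of the
#' loadings, so `projections %*% loadings` is the identity.
#'
#' @param model an [SrspModel-class].
#' @param nSources number of components per unit (the observed SRSP
#'   variation is typically captured by 3--4 sources; default 3).
#' @return an [SrspBasis-class].
#' @export
decomposeSrsp <- function(model, nSources = 3) {
  C <- length(model@channelIds)
  if (nSources > C)
    stop("nSources exceeds the channel count", call. = FALSE)
  U <- length(model@unitIds)
  waveforms <- loadings <- projections <- varfrac <- vector("list", U)
  for (u in seq_len(U)) {
    K <- model@kernels[u, , , drop = TRUE]          # channel x lag
    if (C == 1L) K <- matrix(K, nrow = 1L)
    sv <- svd(K)
    rnk <- sum(sv$d > max(sv$d) * 1e-10)
    if (nSources > rnk)
      stop(sprintf("unit '%s': nSources = %d exceeds attained rank %d",
                   model@unitIds[u], nSources, rnk), call. = FALSE)
    W <- sv$v[, seq_len(nSources), drop = FALSE]    # lag x k, orthonormal
    A <- sv$u[, seq_len(nSources), drop = FALSE] %*%
      diag(sv$d[seq_len(nSources)], nSources)       # channel x k
    for (j in seq_len(nSources)) {                  # deterministic sign
      i <- which.max(abs(W[, j]))
      if (W[i, j] < 0) { W[, j] <- -W[, j]; A[, j] <- -A[, j] }
    }
    waveforms[[u]] <- W
    loadings[[u]] <- A
    projections[[u]] <- MASS::ginv(A)               # k x channel
    varfrac[[u]] <- sv$d^2 / sum(sv$d^2)
  }
  new("SrspBasis", unitIds = model@unitIds, waveforms = waveforms,
      loadings = loadings, projections = projections,
      varianceFractions = varfrac, lags = model@lags,
      binWidth = model@binWidth, channelIds = model@channelIds)
}

## Wiener deconvolution kernel for one PC waveform, returned on the model's
## lag grid after raised-cosine windowing (FIR realization).
wienerKernel <- function(w, kIdx, nsr) {
  if (all(w == 0)) stop("PC waveform is identically zero", call. = FALSE)
  span <- max(abs(kIdx))
  nfft <- 2^ceiling(log2(max(8 * (2 * span + 1), 64)))
  h <- numeric(nfft)
  h[(kIdx %% nfft) + 1L] <- w           # circular placement of acausal taps
  Hf <- stats::fft(h)
  Gf <- Conj(Hf) / (Mod(Hf)^2 + nsr)
  g <- Re(stats::fft(Gf, inverse = TRUE)) / nfft
  outIdx <- seq.int(-span, span)
  gk <- g[(outIdx %% nfft) + 1L]
  taper <- 0.5 * (1 + cos(pi * outIdx / (span + 1)))   # raised cosine
  list(coef = gk * taper, lags = outIdx)
}

#' Build an FIR firing-rate decoder from an SRSP basis
#'
#' Realizes, per unit, the linear operator
#' source-projection -> Wiener deconvolution -> least-squares source
#' combination as one acausal FIR filter bank over the LFP channels. The
#' Wiener inverse `H*(f) / (|H(f)|^2 + nsr)` is windowed to the SRSP lag
#' span with a raised-cosine taper to suppress truncation ripple. As
#' `nsr -> Inf` the filters vanish and the estimate collapses to the
#' mean-rate offset.
#'
#' @param basis an [SrspBasis-class].
#' @param lfpTrain training [LfpRecording-class] (same preprocessing as at
#'   run time, e.g. [lowpassLmp()]).
#' @param ratesTrain training [BinnedRates-class] (counts; converted to Hz).
#' @param nsr Wiener noise-to-signal regularizer, >= 0.
#' @return a [RateDecoder-class].
#' @export
buildRateDecoder <- function(basis, lfpTrain, ratesTrain, nsr = 0.01) {
  if (nsr < 0) stop("nsr must be non-negative", call. = FALSE)
  dt <- basis@binWidth
  lfpTrain <- resampleLfp(lfpTrain, dt)
  if (!identical(lfpTrain@channelIds, basis@channelIds))
    stop("channel ids of the training LFP do not match the basis",
         call. = FALSE)
  T <- min(nrow(lfpTrain@samples), nrow(ratesTrain@values))
  L <- lfpTrain@samples[seq_len(T), , drop = FALSE]
  R <- ratesTrain@values[seq_len(T), , drop = FALSE]
  if (ratesTrain@isCounts) R <- R / dt                 # Hz
  kIdx <- as.integer(round(basis@lags / dt))
  U <- length(basis@unitIds)
  filters <- vector("list", U)
  offsets <- numeric(U)
  span <- max(abs(kIdx))
  valid <- seq.int(1L + span, T - span)
  outLags <- seq.int(-span, span)
  for (u in seq_len(U)) {
    Pm <- basis@projections[[u]]                       # k x channel
    k <- nrow(Pm)
    Xs <- matrix(0, length(valid), k)
    gList <- vector("list", k)
    for (j in seq_len(k)) {
      g <- wienerKernel(basis@waveforms[[u]][, j], kIdx, nsr)
      gList[[j]] <- g
      s <- as.numeric(L %*% Pm[j, ])                   # demixed source
      Xs[, j] <- acausalFilter(s, g$coef, g$lags)[valid]
    }
    fit <- stats::lm.fit(cbind(1, Xs), R[valid, u])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0        # degenerate (e.g. nsr -> Inf) sources drop out
    if (all(cf[-1] == 0)) cf[1] <- mean(R[valid, u])
    fmat <- matrix(0, ncol(L), length(outLags))        # channel x lag
    for (j in seq_len(k))
      fmat <- fmat + cf[j + 1] * outer(Pm[j, ], gList[[j]]$coef)
    filters[[u]] <- fmat
    offsets[u] <- cf[1]
  }
  new("RateDecoder", filters = filters, lags = outLags * dt, binWidth = dt,
      offsets = offsets, nsr = nsr, unitIds = basis@unitIds,
      channelIds = basis@channelIds)
}

#' Estimate firing rates from LFP alone
#'
#' Pure FIR filtering plus the offset: the output at bin t depends only on
#' the LFP within the filter's lag window around t, so the operation is
#' real-time capable (with latency equal to the acausal lag extent).
#' Estimates are linear in the LFP and may go negative; set
#' `clipNonnegative = TRUE` to clamp at zero.
#'
#' @param decoder a [RateDecoder-class].
#' @param lfp an [LfpRecording-class] with the decoder's channels.
#' @param clipNonnegative clamp negative estimates to zero (off by default:
#'   the linear contract is the documented behaviour).
#' @return a [BinnedRates-class] of rate estimates in Hz.
#' @export
estimateRates <- function(decoder, lfp, clipNonnegative = FALSE) {
  lfp <- resampleLfp(lfp, decoder@binWidth)
  if (!identical(lfp@channelIds, decoder@channelIds))
    stop("channel ids do not match the decoder", call. = FALSE)
  kIdx <- as.integer(round(decoder@lags / decoder@binWidth))
  T <- nrow(lfp@samples)
  out <- matrix(0, T, length(decoder@unitIds))
  for (u in seq_along(decoder@unitIds)) {
    acc <- rep(decoder@offsets[u], T)
    f <- decoder@filters[[u]]
    for (ch in seq_len(ncol(lfp@samples)))
      acc <- acc + acausalFilter(lfp@samples[, ch], f[ch, ], kIdx)
    out[, u] <- acc
  }
  if (clipNonnegative) out[out < 0] <- 0
  BinnedRates(out, binWidth = decoder@binWidth, tStart = lfp@tStart,
              unitIds = decoder@unitIds, isCounts = FALSE)
}

#' Cross-session stability report for a rate decoder
#'
#' For each session, estimates rates from the LFP and compares them with
#' the actual (smoothed) rates: instantaneous per-unit Pearson correlation,
#' and the correlation of event-triggered averages (estimated vs actual)
#' when alignment events are supplied.
#'
#' @param decoder a [RateDecoder-class].
#' @param sessions list of `list(spikes = SpikeTrainSet, lfp = LfpRecording)`.
#' @param events list (same length) of numeric event-time vectors for the
#'   aligned metric; a session with no events gets `NA` with a warning.
#' @param window alignment window around each event, seconds.
#' @param smoothHz smoothing cutoff for the actual rates.
#' @param path optional file path; when given, the table is also written as
#'   delimited text.
#' @return data.frame: session, unit, r_inst, r_aligned.
#' @export
stabilityReport <- function(decoder, sessions, events = NULL,
                            window = c(-0.5, 0.5), smoothHz = 5,
                            path = NULL) {
  if (length(sessions) < 1L) stop("need at least one session", call. = FALSE)
  rows <- list()
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    counts <- binSpikes(ses$spikes, binWidth = decoder@binWidth,
                        alignTo = ses$lfp@tStart)
    actual <- smoothRates(counts, cutoffHz = smoothHz)
    est <- estimateRates(decoder, ses$lfp)
    T <- min(nrow(actual@values), nrow(est@values))
    ev <- if (is.null(events)) numeric() else events[[s]]
    evOk <- length(ev) > 0L
    if (!evOk)
      warning(sprintf("session %d has no alignment events; aligned metric is NA",
                      s))
    for (u in seq_along(decoder@unitIds)) {
      rInst <- safeCor(actual@values[seq_len(T), u], est@values[seq_len(T), u])
      rAl <- NA_real_
      if (evOk) {
        taA <- eventSnippetMean(actual@values[, u], actual@tStart,
                                1 / actual@binWidth, ev, window)
        taE <- eventSnippetMean(est@values[, u], est@tStart,
                                1 / est@binWidth, ev, window)
        if (!is.null(taA) && !is.null(taE)) rAl <- safeCor(taA, taE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(session = s, unit = decoder@unitIds[u],
                   r_inst = rInst, r_aligned = rAl)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    body <- apply(out, 1L, function(r) paste(trimws(r), collapse = ","))
    writeHeaderedCsv(path, meta = list(n_rows = nrow(out)),
                     header = names(out), body = body)
  }
  out
}

## mean event-aligned snippet of a sampled signal; NULL if no event fits
eventSnippetMean <- function(x, t0, fs, events, window) {
  iPre <- round(window[1] * fs); iPost <- round(window[2] * fs)
  centers <- round((events - t0) * fs) + 1L
  keep <- centers + iPre >= 1L & centers + iPost <= length(x)
  centers <- centers[keep]
  if (!length(centers)) return(NULL)
  snips <- vapply(centers, function(c0) x[seq.int(c0 + iPre, c0 + iPost)],
                  numeric(iPost - iPre + 1L))
  rowMeans(snips)
}
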