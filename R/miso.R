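# Multiple-input single-output (MISO) identification of spike -> LFP
# impulse responses (spike-related slow potentials, SRSPs).
#
# The model for each LFP channel y is
#     y(t) = sum_units sum_lags h_u(tau) x_u(t - tau) + offset,
# with an acausal lag grid tau in [-tPre, +tPost] (negative lags: LFP
# preceding the spike). Coefficients solve least squares over the interior
# bins where the full lag window fits inside the record; the normal
# equations are assembled from windowed auto-/cross-correlation functions of
# the inputs (computed by a sliding-window recursion along the Gram
# diagonals), which makes them exactly equal to crossprod of the explicit
# lagged design matrix while costing O(U^2 K (M + K)) rather than O(U^2 K^2 M).

## Gram block between the lagged copies of xu and xv over interior rows.
## kk = integer lags (-P):Q; interior rows I = (1+Q):(T-P).
## E[a, b] = sum_{t in I} xu(t - kk[a]) * xv(t - kk[b])
gramBlock <- function(xu, xv, P, Q) {
  T <- length(xu)
  K <- P + Q + 1L
  I <- seq.int(1L + Q, T - P)
  E <- matrix(0, K, K)
  # first row / first column: windowed cross-correlations
  for (b in seq_len(K))
    E[1, b] <- sum(xu[I + P] * xv[I + P - b + 1L])
  for (a in seq_len(K))
    E[a, 1] <- sum(xu[I + P - a + 1L] * xv[I + P])
  # diagonal recursion: stepping (a, b) -> (a+1, b+1) shifts both windows by
  # one bin, so only two boundary products change.
  if (K > 1L) {
    for (b0 in seq_len(K - 1L)) {        # diagonals starting in row 1
      r <- seq_len(K - b0)
      inc <- xu[K - r] * xv[K - b0 - r + 1L] -
             xu[T + 1L - r] * xv[T - b0 - r + 2L]
      E[cbind(1L + r, b0 + r)] <- E[1, b0] + cumsum(inc)
    }
    for (a0 in 2L:K) {                   # diagonals starting in column 1
      if (a0 > K - 1L) break
      r <- seq_len(K - a0)
      inc <- xu[K - a0 - r + 1L] * xv[K - r] -
             xu[T - a0 - r + 2L] * xv[T + 1L - r]
      E[cbind(a0 + r, 1L + r)] <- E[a0, 1] + cumsum(inc)
    }
  }
  E
}

#' Fit the MISO spike-to-LFP model (SRSP extraction)
#'
#' Identifies, for every LFP channel independently, the acausal impulse
#' response of each unit's spike train plus a DC offset, by solving the
#' least-squares normal equations assembled from input auto- and
#' cross-correlation functions (a block system with one block per unit
#' pair). Because the inputs' correlation structure enters the solve, the
#' contribution of correlated spikes in other recorded trains is removed
#' from each unit's SRSP; correlated but unrecorded neurons cannot be
#' accounted for.
#'
#' @param rates a [BinnedRates-class] of spike counts (binned, not
#'   smoothed -- the linear time-invariant convolution model is taken
#'   literally).
#' @param lfp an [LfpRecording-class]; decimated by averaging to the rate
#'   bin width if sampled faster.
#' @param tPre,tPost lag window extent, seconds, before (negative lags) and
#'   after the spike. Defaults cover one 1--4 Hz submovement cycle on either
#'   side.
#' @param ridge ridge penalty added to the normal-equation diagonal
#'   (0 = ordinary least squares).
#' @return an [SrspModel-class] with kernels (unit x channel x lag),
#'   per-channel offsets and fitted-span variance accounted for.
#' @export
fitMiso <- function(rates, lfp, tPre = 0.5, tPost = 0.5, ridge = 0) {
  checkScalar(tPre, "tPre", lower = 0)
  checkScalar(tPost, "tPost", lower = 0)
  checkScalar(ridge, "ridge", lower = 0)
  dt <- rates@binWidth
  lfp <- resampleLfp(lfp, dt)
  if (abs(rates@tStart - lfp@tStart) > dt / 2)
    stop("rates and LFP must start at the same time", call. = FALSE)
  T <- min(nrow(rates@values), nrow(lfp@samples))
  X <- rates@values[seq_len(T), , drop = FALSE]
  Y <- lfp@samples[seq_len(T), , drop = FALSE]
  P <- as.integer(round(tPre / dt))
  Q <- as.integer(round(tPost / dt))
  K <- P + Q + 1L
  U <- ncol(X)
  if (T * dt < 10 * (tPre + tPost))
    stop("span too short: need at least 10x the total lag span", call. = FALSE)
  I <- seq.int(1L + Q, T - P)
  M <- length(I)
  kk <- seq.int(-P, Q)

  nc <- U * K + 1L                    # + intercept
  G <- matrix(0, nc, nc)
  for (u in seq_len(U)) for (v in seq_len(U)) {
    if (v < u) {
      blk <- t(G[(v - 1L) * K + seq_len(K), (u - 1L) * K + seq_len(K)])
    } else {
      blk <- gramBlock(X[, u], X[, v], P, Q)
    }
    G[(u - 1L) * K + seq_len(K), (v - 1L) * K + seq_len(K)] <- blk
  }
  # intercept row/column: windowed sums of each lagged input
  for (u in seq_len(U)) {
    cs <- c(0, cumsum(X[, u]))
    s <- cs[I[M] - kk + 1L] - cs[I[1] - kk]     # sum over I - kk[a]
    G[nc, (u - 1L) * K + seq_len(K)] <- s
    G[(u - 1L) * K + seq_len(K), nc] <- s
  }
  G[nc, nc] <- M

  B <- matrix(0, nc, ncol(Y))
  for (ch in seq_len(ncol(Y))) {
    y <- Y[I, ch]
    for (u in seq_len(U)) {
      xu <- X[, u]
      B[(u - 1L) * K + seq_len(K), ch] <-
        vapply(kk, function(k) sum(xu[I - k] * y), 0)
    }
    B[nc, ch] <- sum(y)
  }

  Gr <- G
  if (ridge > 0) diag(Gr)[seq_len(nc - 1L)] <-
      diag(Gr)[seq_len(nc - 1L)] + ridge
  H <- tryCatch(solve(Gr, B), error = function(e) {
    if (ridge > 0)
      stop(sprintf("normal equations could not be solved: %s",
                   conditionMessage(e)), call. = FALSE)
    sug <- suggestRidge(G, nc)
    stop(sprintf(paste0("singular normal matrix with ridge = 0; ",
                        "consider ridge > 0 (suggested lambda ~ %g)"), sug),
         call. = FALSE)
  })

  kern <- array(0, dim = c(U, ncol(Y), K))
  for (u in seq_len(U))
    kern[u, , ] <- t(H[(u - 1L) * K + seq_len(K), , drop = FALSE])
  offsets <- H[nc, ]
  model <- new("SrspModel", kernels = kern, lags = kk * dt, binWidth = dt,
               offsets = as.numeric(offsets), ridge = ridge,
               vaf = rep(NA_real_, ncol(Y)),
               unitIds = rates@unitIds, channelIds = lfp@channelIds)
  pred <- predictLfp(model, rates)
  vaf <- vapply(seq_len(ncol(Y)), function(ch) {
    r <- Y[I, ch] - pred@samples[I, ch]
    1 - stats::var(r) / stats::var(Y[I, ch])
  }, 0)
  model@vaf <- vaf
  model
}

## smallest lambda on a log grid that makes the (ridged) system solvable
## with acceptable conditioning
suggestRidge <- function(G, nc) {
  base <- sum(diag(G)[seq_len(nc - 1L)]) / (nc - 1L)
  for (f in 10^seq(-6, -2)) {
    lam <- f * base
    Gr <- G
    diag(Gr)[seq_len(nc - 1L)] <- diag(Gr)[seq_len(nc - 1L)] + lam
    ok <- tryCatch({ solve(Gr, diag(nrow(Gr))[, 1]); TRUE },
                   error = function(e) FALSE)
    if (ok && rcond(Gr) > 1e-12) return(lam)
  }
  base * 1e-2
}

#' Predict LFP from spike counts with a fitted SRSP model
#'
#' Acausal convolution of each train with each kernel, summed per channel,
#' plus the channel offset. Bins whose lag window extends beyond the record
#' ("edge" bins, where the zero-extended inputs truncate the convolution)
#' are flagged in `metadata$edge`.
#'
#' @param model an [SrspModel-class].
#' @param rates a [BinnedRates-class] whose units match the model.
#' @return an [LfpRecording-class] of predicted potentials.
#' @export
predictLfp <- function(model, rates) {
  if (!identical(rates@unitIds, model@unitIds))
    stop("unit ids of the rates do not match the model", call. = FALSE)
  if (abs(rates@binWidth - model@binWidth) > 1e-9)
    stop("bin width mismatch between rates and model", call. = FALSE)
  X <- rates@values
  T <- nrow(X)
  kIdx <- as.integer(round(model@lags / model@binWidth))
  C <- length(model@channelIds)
  out <- matrix(rep(model@offsets, each = T), T, C)
  for (ch in seq_len(C))
    for (u in seq_len(nrow(model@kernels)))
      out[, ch] <- out[, ch] +
        acausalFilter(X[, u], model@kernels[u, ch, ], kIdx)
  Q <- max(kIdx); P <- -min(kIdx)
  edge <- rep(TRUE, T)
  if (T > P + Q) edge[seq.int(1L + Q, T - P)] <- FALSE
  LfpRecording(out, fs = 1 / model@binWidth, channelIds = model@channelIds,
               tStart = rates@tStart, metadata = list(edge = edge))
}

#' Evaluate an SRSP model on (held-out) data
#'
#' Compares predicted and recorded LFP per channel over the non-edge bins.
#'
#' @param model an [SrspModel-class].
#' @param rates a [BinnedRates-class] (spike counts of the evaluation span).
#' @param lfp the recorded [LfpRecording-class] for the same span.
#' @return data.frame with one row per channel: Pearson `r` and variance
#'   accounted for `vaf`.
#' @export
evaluateFit <- function(model, rates, lfp) {
  lfp <- resampleLfp(lfp, model@binWidth)
  T <- min(nrow(rates@values), nrow(lfp@samples))
  ratesT <- BinnedRates(rates@values[seq_len(T), , drop = FALSE],
                        rates@binWidth, rates@tStart, rates@unitIds,
                        rates@isCounts)
  pred <- predictLfp(model, ratesT)
  keep <- !pred@metadata$edge
  out <- data.frame(channel = model@channelIds,
                    r = NA_real_, vaf = NA_real_)
  for (ch in seq_along(model@channelIds)) {
    y <- lfp@samples[seq_len(T), ch][keep]
    p <- pred@samples[keep, ch]
    if (stats::sd(y) == 0)
      stop(sprintf("zero-variance target on channel '%s': correlation undefined",
                   model@channelIds[ch]), call. = FALSE)
    out$r[ch] <- stats::cor(y, p)
    out$vaf[ch] <- 1 - stats::var(y - p) / stats::var(y)
  }
  out
}
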