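# Shared builders for the test suite. Everything is generated in code under
# fixed seeds; nothing is loaded from disk except the small format examples
# under inst/extdata.

## sinusoidal multichannel recording: columns are given channel-space
## patterns modulated by cos/sin at freqHz
sineLfp <- function(patterns, freqHz, dur = 10, fs = 100, noise = 0,
                    phase = 0) {
  tt <- seq(0, dur, by = 1 / fs)
  x <- matrix(0, length(tt), nrow(patterns))
  for (j in seq_len(ncol(patterns))) {
    carrier <- if (j %% 2 == 1) cos(2 * pi * freqHz * tt + phase)
               else sin(2 * pi * freqHz * tt + phase)
    x <- x + outer(carrier, patterns[, j])
  }
  if (noise > 0) x <- x + matrix(rnorm(length(x), sd = noise), nrow(x))
  LfpRecording(x, fs = fs)
}

## random orthonormal matrix (fixed by the caller's seed)
randomOrthonormal <- function(n) qr.Q(qr(matrix(rnorm(n * n), n, n)))

## independent reference implementation of acausal FIR filtering with
## zero-extended inputs: y(t) = sum_a coef[a] x(t - lags[a])
acausalFilter_test <- function(x, coef, lags) {
  n <- length(x)
  y <- numeric(n)
  for (a in seq_along(lags)) {
    k <- lags[a]
    xs <- if (k >= 0) c(rep(0, k), x[seq_len(n - k)])
          else c(x[seq.int(1 - k, n)], rep(0, -k))
    y <- y + coef[a] * xs
  }
  y
}

## explicit design-matrix least-squares oracle for the MISO fit: builds the
## full lagged design over the interior rows and solves by QR -- a route
## independent of the correlation-function assembly in fitMiso()
olsMisoOracle <- function(X, Y, P, Q) {
  T <- nrow(X)
  K <- P + Q + 1L
  kk <- seq.int(-P, Q)
  I <- seq.int(1L + Q, T - P)
  cols <- vector("list", ncol(X) * K)
  n <- 0L
  for (u in seq_len(ncol(X))) for (a in seq_len(K)) {
    n <- n + 1L
    cols[[n]] <- X[I - kk[a], u]
  }
  D <- cbind(do.call(cbind, cols), 1)
  qr.solve(D, Y[I, , drop = FALSE])
}

## pack an SrspModel's coefficients into the oracle's layout
packMisoCoefficients <- function(model) {
  K <- length(model@lags)
  U <- length(model@unitIds)
  H <- matrix(0, U * K + 1L, length(model@channelIds))
  for (u in seq_len(U))
    H[(u - 1L) * K + seq_len(K), ] <- t(matrix(model@kernels[u, , ],
                                               ncol = K))
  H[U * K + 1L, ] <- model@offsets
  H
}

## split a generated recording into train/test spans on a common bin grid
splitSession <- function(gen, bin, trainFrac = 0.75, lmpCutoff = 5) {
  lmp <- lowpassLmp(gen$lfp, cutoffHz = lmpCutoff)
  all <- resampleLfp(lmp, bin)
  cts <- binSpikes(gen$spikes, bin)
  T <- min(nrow(values(all)), nrow(values(cts)))
  Ttr <- round(T * trainFrac)
  mk <- function(idx) list(
    lfp = LfpRecording(values(all)[idx, , drop = FALSE], fs = 1 / bin,
                       channelIds = channelIds(all)),
    counts = BinnedRates(values(cts)[idx, , drop = FALSE], bin,
                         unitIds = unitIds(cts)))
  list(train = mk(seq_len(Ttr)), test = mk(seq.int(Ttr + 1L, T)))
}

## angle wrapping into (-pi, pi], independent of the package internals
wrapAngle_test <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## the package's angular CoD (internal); anchored by definitional tests
angularCoD_test <- function(predicted, actual)
  lfpdec:::angularCoD(predicted, actual)

## per-unit correlation between estimated and (smoothed) actual rates
heldOutRateR <- function(decoder, session) {
  est <- estimateRates(decoder, session$lfp)
  act <- smoothRates(session$counts)
  T <- min(nrow(values(est)), nrow(values(act)))
  vapply(seq_len(ncol(values(est))), function(u)
    cor(values(est)[seq_len(T), u], values(act)[seq_len(T), u]), 0)
}

## principal angles between the spans of two n x 2 bases
principalAngles <- function(A, B) {
  acos(pmin(1, svd(crossprod(qr.Q(qr(A)), qr.Q(qr(B))))$d))
}
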