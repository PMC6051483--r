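# Rotational structure in multichannel low-frequency LFP, and areal
# velocity: the area swept per unit time by the LFP trajectory in a plane.
#
# For a plane spanned by orthonormal channel-space vectors u, v:
#     AV_{u,v} = 0.5 * ((u.l)(v.ldot) - (v.l)(u.ldot))
# which decomposes exactly into pairwise terms
#     AV_{u,v} = sum_{i<j} (u_i v_j - u_j v_i) AV_{i,j},
#     AV_{i,j} = 0.5 * (l_i ldot_j - l_j ldot_i).
# AV rejects all in-phase components shared across channels (a rank-1
# signal sweeps no area), is antisymmetric under index swap and under time
# reversal, and scales with the square of the LFP amplitude. No mean
# removal or smoothing is applied here: AV is evaluated on the signal as
# given (projection through a PcaBasis is the centered route).

#' Fit rotational planes by a skew-symmetric dynamics fit (jPCA-style)
#'
#' The recording is reduced to `nPcs` principal components, and the
#' component-space dynamics are fit as `xdot = M x` with `M` constrained
#' skew-symmetric, solved in closed form by least squares over the
#' skew basis. The eigenvalues of a real skew-symmetric matrix are purely
#' imaginary conjugate pairs; each pair yields one plane (orthonormalized
#' real and imaginary eigenvector parts), ordered by |eigenvalue| so the
#' strongest rotation comes first, and mapped back to channel space.
#' Each plane is oriented so that the mean areal velocity over the fitting
#' span is non-negative.
#'
#' @param lfp an [LfpRecording-class] (apply [lowpassLmp()] first for the
#'   slow-oscillation planes).
#' @param nPcs dimension of the PCA pre-reduction (even values accommodate
#'   `nPcs/2` planes).
#' @param nPlanes number of planes to return.
#' @return list of [ProjectionPlane-class] with rotation-frequency
#'   estimates (Hz) from the eigenvalues.
#' @export
fitJpca <- function(lfp, nPcs = 6, nPlanes = 2) {
  sk <- fitSkewDynamics(lfp, nPcs)
  M <- sk$M
  basis <- sk$basis
  k <- ncol(M)
  if (nPlanes > floor(k / 2))
    stop(sprintf("nPlanes = %d exceeds the %d plane(s) available from %d PCs",
                 nPlanes, floor(k / 2), k), call. = FALSE)
  eg <- eigen(M)
  im <- Im(eg$values)
  sel <- which(im > max(abs(im)) * 1e-9)         # one of each conjugate pair
  sel <- sel[order(abs(im[sel]), decreasing = TRUE)]
  if (length(sel) < nPlanes)
    stop("fewer rotational planes than requested (near-zero eigenvalues)",
         call. = FALSE)
  planes <- vector("list", nPlanes)
  for (q in seq_len(nPlanes)) {
    v <- eg$vectors[, sel[q]]
    pcPlane <- qr.Q(qr(cbind(Re(v), Im(v))))     # orthonormal in PC space
    uC <- as.numeric(basis@components %*% pcPlane[, 1])
    vC <- as.numeric(basis@components %*% pcPlane[, 2])
    pl <- ProjectionPlane(uC, vC, provenance = "jpca",
                          freqHz = abs(im[sel[q]]) / (2 * pi))
    # orientation: positive mean AV on the fitting span
    av <- arealVelocityPlane(lfp, pl)
    if (mean(av@values) < 0)
      pl <- ProjectionPlane(uC, -vC, provenance = "jpca",
                            freqHz = pl@freqHz)
    planes[[q]] <- pl
  }
  planes
}

#' Skew-symmetric dynamics matrix (for diagnostics)
#'
#' Same fit as [fitJpca()] but returning the component-space matrix `M`
#' and the PCA basis, for tests and inspection.
#'
#' @inheritParams fitJpca
#' @return list(M, basis); `M` is exactly skew-symmetric by construction.
#' @export
fitSkewDynamics <- function(lfp, nPcs = 6) {
  nPcs <- min(nPcs, nChannels(lfp))
  basis <- fitPca(lfp, nPcs)
  X <- projectLfp(lfp, basis)@samples
  D <- derivMatrix(X, lfp@fs)
  k <- ncol(X)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  G <- matrix(0, nrow(X) * k, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    col <- matrix(0, nrow(X), k)
    col[, j] <- -X[, i]; col[, i] <- X[, j]
    G[, p] <- as.numeric(col)
  }
  m <- qr.solve(G, as.numeric(D))
  M <- matrix(0, k, k)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    M[i, j] <- m[p]; M[j, i] <- -m[p]
  }
  list(M = M, basis = basis)
}

#' Areal velocity in a plane
#'
#' Sample-wise evaluation of the cross-product formula; counter-clockwise
#' rotation in (u, v) coordinates is positive. The time derivative is the
#' central-difference estimate of [timeDerivative()].
#'
#' @param lfp an [LfpRecording-class].
#' @param plane a [ProjectionPlane-class] with matching channel count.
#' @return an [ArealVelocitySignal-class] in (LFP units)^2 / s.
#' @export
arealVelocityPlane <- function(lfp, plane) {
  validObject(plane)
  if (length(plane@u) != nChannels(lfp))
    stop("plane dimension does not match the channel count", call. = FALSE)
  x <- lfp@samples %*% cbind(plane@u, plane@v)
  d <- derivMatrix(x, lfp@fs)
  av <- 0.5 * (x[, 1] * d[, 2] - x[, 2] * d[, 1])
  new("ArealVelocitySignal", values = av, fs = lfp@fs, tStart = lfp@tStart,
      id = sprintf("plane:%s", plane@provenance))
}

#' Pairwise areal-velocity signals
#'
#' `AV_{i,j} = 0.5 (l_i ldot_j - l_j ldot_i)` for channel pairs i < j.
#' With `pairs = "all"`, all `N(N-1)/2` pairs are returned in lexicographic
#' order. `AV_{j,i} = -AV_{i,j}`, so only i < j is computed; requesting
#' i = j is an error (the signal is identically zero).
#'
#' @param lfp an [LfpRecording-class].
#' @param pairs "all", or a 2-column matrix of channel index pairs.
#' @return list of [ArealVelocitySignal-class], ids "pair:i-j".
#' @export
arealVelocityPairs <- function(lfp, pairs = "all") {
  N <- nChannels(lfp)
  if (identical(pairs, "all")) {
    pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs < 1L | pairs > N))
      stop("channel index out of range", call. = FALSE)
    if (any(pairs[, 1] == pairs[, 2]))
      stop("i = j requested: the pairwise areal velocity of a channel with itself is identically zero",
           call. = FALSE)
  }
  d <- derivMatrix(lfp@samples, lfp@fs)
  lapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    av <- 0.5 * (lfp@samples[, i] * d[, j] - lfp@samples[, j] * d[, i])
    new("ArealVelocitySignal", values = av, fs = lfp@fs,
        tStart = lfp@tStart, id = sprintf("pair:%d-%d", i, j))
  })
}

#' Verify the pairwise decomposition identity
#'
#' The plane areal velocity is an exact linear sum of pairwise terms,
#' `AV_{u,v} = sum_{i<j} (u_i v_j - u_j v_i) AV_{i,j}`. Returns the maximum
#' absolute residual between the two routes over time (an algebraic
#' identity: the residual is numerical round-off only).
#'
#' @param lfp an [LfpRecording-class].
#' @param plane a [ProjectionPlane-class].
#' @return max abs residual (scalar).
#' @export
planeDecompositionCheck <- function(lfp, plane) {
  avPlane <- arealVelocityPlane(lfp, plane)@values
  pairAv <- arealVelocityPairs(lfp, "all")
  N <- nChannels(lfp)
  acc <- numeric(length(avPlane))
  p <- 0L
  for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
    p <- p + 1L
    w <- plane@u[i] * plane@v[j] - plane@u[j] * plane@v[i]
    acc <- acc + w * pairAv[[p]]@values
  }
  max(abs(avPlane - acc))
}

#' Three-dimensional areal-velocity vector
#'
#' For the trajectory `x` projected on exactly three principal components,
#' `v(t) = 0.5 x(t) cross xdot(t)`, with components ordered
#' (AV_23, AV_31, AV_12). The vector's magnitude equals the planar areal
#' velocity in the instantaneous plane of rotation and its direction is the
#' rotation axis, enabling joint speed (magnitude) and direction (axis)
#' decoding of submovements.
#'
#' @param lfp an [LfpRecording-class].
#' @param basis a [PcaBasis-class] with exactly 3 components.
#' @return an [ArealVelocityVector-class].
#' @export
arealVelocityVector3 <- function(lfp, basis) {
  if (ncol(basis@components) != 3L)
    stop("basis must have exactly 3 components", call. = FALSE)
  x <- projectLfp(lfp, basis)@samples
  d <- derivMatrix(x, lfp@fs)
  v <- 0.5 * cbind(x[, 2] * d[, 3] - x[, 3] * d[, 2],
                   x[, 3] * d[, 1] - x[, 1] * d[, 3],
                   x[, 1] * d[, 2] - x[, 2] * d[, 1])
  new("ArealVelocityVector", values = v, fs = lfp@fs, tStart = lfp@tStart)
}

#' Band-limited areal velocity
#'
#' Zero-phase band-pass filtering per channel, then the plane areal
#' velocity: separates the areal-velocity signal of rotations at different
#' frequencies.
#'
#' @param lfp an [LfpRecording-class].
#' @param plane a [ProjectionPlane-class].
#' @param band numeric length-2, `(fLo, fHi)` Hz with
#'   `0 <= fLo < fHi < fs/2`.
#' @param order filter order.
#' @return an [ArealVelocitySignal-class].
#' @export
bandedArealVelocity <- function(lfp, plane, band, order = 4) {
  if (length(band) != 2L)
    stop("band must be (fLo, fHi)", call. = FALSE)
  filt <- bandpassLfp(lfp, band[1], band[2], order = order)
  av <- arealVelocityPlane(filt, plane)
  av@id <- sprintf("%s|band:%g-%gHz", av@id, band[1], band[2])
  av
}
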