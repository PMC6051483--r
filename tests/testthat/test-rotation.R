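# Rotational-plane fitting and areal-velocity algebra.

test_that("skew-symmetric dynamics recover a constructed rotation plane", {
  set.seed(41)
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  Qm <- randomOrthonormal(6)
  traj <- outer(cos(2 * pi * 1.5 * tt), Qm[, 1]) +
    outer(sin(2 * pi * 1.5 * tt), Qm[, 2])
  lfp <- LfpRecording(traj + 1e-6 * matrix(rnorm(length(tt) * 6), ncol = 6),
                      fs = fs)
  pl <- fitJpca(lfp, nPcs = 6, nPlanes = 1)[[1]]
  ang <- principalAngles(Qm[, 1:2], planeVectors(pl))
  expect_lt(max(ang), 1e-3)
  expect_equal(pl@freqHz, 1.5, tolerance = 0.01)
  # orientation convention: positive mean AV on the fitting span
  expect_gt(mean(values(arealVelocityPlane(lfp, pl))), 0)

  sk <- fitSkewDynamics(lfp, 6)
  expect_identical(sk$M, -t(sk$M))                  # skew by construction
  expect_lt(max(abs(Re(eigen(sk$M)$values))), 1e-10)

  expect_error(fitJpca(lfp, nPcs = 4, nPlanes = 3), "exceeds")
})

test_that("areal velocity of a unit circle at 1 Hz equals pi (discretization-bounded)", {
  fs <- 1000
  tt <- seq(0, 10, by = 1 / fs)
  x <- cbind(cos(2 * pi * tt), sin(2 * pi * tt), 0 * tt)
  lfp <- LfpRecording(x, fs = fs)
  pl <- ProjectionPlane(c(1, 0, 0), c(0, 1, 0))
  av <- values(arealVelocityPlane(lfp, pl))
  interior <- 3:(length(tt) - 2)
  # analytic oracle: central differences give AV = (r^2/2) sin(w h) / h
  h <- 1 / fs; w <- 2 * pi
  oracle <- 0.5 * sin(w * h) / h
  expect_lt(max(abs(av[interior] - oracle)), 1e-9)
  expect_lt(abs(mean(av[interior]) - pi), pi * w^2 * h^2 / 6)

  # time reversal negates AV exactly
  rev <- LfpRecording(x[rev(seq_len(nrow(x))), ], fs = fs)
  avR <- values(arealVelocityPlane(rev, pl))
  expect_equal(avR, -rev(av), tolerance = 1e-12)
})

test_that("in-phase (rank-1) signals sweep no area; differential power is non-zero", {
  set.seed(42)
  w <- signal::filtfilt(signal::butter(4, 0.1), rnorm(3000))
  gains <- c(1, -0.3, 2, 0.7)
  lfp <- LfpRecording(outer(w, gains), fs = 100)
  pl <- ProjectionPlane(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_lt(max(abs(values(arealVelocityPlane(lfp, pl)))), 1e-9)
  for (s in arealVelocityPairs(lfp, "all"))
    expect_lt(max(abs(values(s))), 1e-9)

  # the Fig-4-style contrast: an in-phase component with *unequal*
  # amplitudes across channels defeats differential recording (non-zero
  # power) but still sweeps no area
  withInPhase <- LfpRecording(outer(w, gains) + outer(w, c(2, 0.5, 1, 3)),
                              fs = 100)
  for (s in arealVelocityPairs(withInPhase, rbind(c(1, 2), c(2, 3))))
    expect_lt(max(abs(values(s))), 1e-9)
  diffSig <- values(withInPhase)[, 1] - values(withInPhase)[, 2]
  expect_gt(var(diffSig), 0.1 * var(w))
})

test_that("pairwise signals enumerate i<j and average to zero on white noise", {
  set.seed(44)
  lfp22 <- LfpRecording(matrix(rnorm(200 * 22), ncol = 22), fs = 100)
  prs <- arealVelocityPairs(lfp22, "all")
  expect_length(prs, 231L)
  expect_equal(prs[[1]]@id, "pair:1-2")
  expect_equal(prs[[231]]@id, "pair:21-22")
  expect_error(arealVelocityPairs(lfp22, rbind(c(3, 3))), "identically zero")

  # swapped indices give the negated signal (computed via a swapped plane)
  e <- function(i) { v <- rep(0, 22); v[i] <- 1; v }
  av12 <- values(arealVelocityPlane(lfp22, ProjectionPlane(e(1), e(2))))
  av21 <- values(arealVelocityPlane(lfp22, ProjectionPlane(e(2), e(1))))
  expect_equal(av12, -av21, tolerance = 1e-12)

  # zero-mean null: independent channels, autocorrelation-aware 3 SE bound
  long <- LfpRecording(matrix(rnorm(50000 * 2), ncol = 2), fs = 100)
  av <- values(arealVelocityPairs(long, rbind(c(1, 2)))[[1]])
  rho <- acf(av, lag.max = 5, plot = FALSE)$acf[-1]
  se <- sd(av) * sqrt((1 + 2 * sum(rho)) / length(av))
  expect_lt(abs(mean(av)), 3 * se)
})

test_that("plane AV decomposes exactly into weighted pairwise terms", {
  set.seed(45)
  lfp <- LfpRecording(matrix(rnorm(800 * 5), ncol = 5), fs = 100)
  Qm <- randomOrthonormal(5)
  for (j in c(1, 3)) {
    pl <- ProjectionPlane(Qm[, j], Qm[, j + 1])
    expect_lt(planeDecompositionCheck(lfp, pl),
              1e-9 * max(abs(values(arealVelocityPlane(lfp, pl)))))
  }
  # axis-aligned plane reduces to the single pairwise signal
  e <- function(i) { v <- rep(0, 5); v[i] <- 1; v }
  plAxis <- ProjectionPlane(e(2), e(4))
  expect_equal(values(arealVelocityPlane(lfp, plAxis)),
               values(arealVelocityPairs(lfp, rbind(c(2, 4)))[[1]]),
               tolerance = 1e-12)
})

test_that("AV obeys the c^2 scale law and channel-space rotation invariance", {
  set.seed(46)
  lfp <- LfpRecording(matrix(rnorm(500 * 4), ncol = 4), fs = 100)
  Qm <- randomOrthonormal(4)
  pl <- ProjectionPlane(Qm[, 1], Qm[, 2])
  av <- values(arealVelocityPlane(lfp, pl))
  scaled <- LfpRecording(3 * values(lfp), fs = 100)
  expect_equal(values(arealVelocityPlane(scaled, pl)), 9 * av,
               tolerance = 1e-12)

  R <- randomOrthonormal(4)
  rot <- LfpRecording(values(lfp) %*% t(R), fs = 100)
  plRot <- ProjectionPlane(as.numeric(R %*% Qm[, 1]),
                           as.numeric(R %*% Qm[, 2]))
  expect_lt(max(abs(values(arealVelocityPlane(rot, plRot)) - av)), 1e-9)
})

test_that("the 3D areal-velocity vector has the cross-product geometry", {
  fs <- 500
  tt <- seq(0, 10, by = 1 / fs)
  basis <- new("PcaBasis", center = rep(0, 3), components = diag(3),
               varianceFractions = c(0.5, 0.3, 0.2))
  # rotation confined to the (1,2) plane
  x12 <- cbind(cos(2 * pi * tt), sin(2 * pi * tt), 0 * tt)
  av3 <- values(arealVelocityVector3(LfpRecording(x12, fs = fs), basis))
  interior <- 3:(length(tt) - 2)
  expect_lt(max(abs(av3[interior, 1:2])), 1e-9)
  expect_equal(mean(av3[interior, 3]), pi, tolerance = 1e-4)

  # tilted circle: magnitude is tilt-invariant, direction is the normal
  n <- c(sin(0.4) * cos(1.1), sin(0.4) * sin(1.1), cos(0.4))
  e1 <- c(-sin(1.1), cos(1.1), 0)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  xt <- outer(cos(2 * pi * tt), e1) + outer(sin(2 * pi * tt), e2)
  avT <- values(arealVelocityVector3(LfpRecording(xt, fs = fs), basis))
  mag <- sqrt(rowSums(avT[interior, ]^2))
  expect_equal(mean(mag), pi, tolerance = 1e-4)
  dirs <- avT[interior, ] / mag
  expect_gt(min(dirs %*% n), 1 - 1e-6)

  # consistency: components equal the pairwise AV of the projected signals
  proj <- projectLfp(LfpRecording(xt, fs = fs), basis)
  av12 <- values(arealVelocityPairs(proj, rbind(c(1, 2)))[[1]])
  expect_equal(avT[, 3], av12, tolerance = 1e-12)

  basis2 <- new("PcaBasis", center = rep(0, 3), components = diag(3)[, 1:2],
                varianceFractions = c(0.5, 0.3))
  expect_error(arealVelocityVector3(LfpRecording(xt, fs = fs), basis2),
               "exactly 3")
})

test_that("band-limited AV separates superposed rotations by frequency", {
  set.seed(47)
  fs <- 100
  tt <- seq(0, 60, by = 1 / fs)
  Q8 <- randomOrthonormal(8)
  x <- outer(cos(2 * pi * 2 * tt), Q8[, 1]) +
    outer(sin(2 * pi * 2 * tt), Q8[, 2]) +
    outer(cos(2 * pi * 8 * tt), Q8[, 3]) +
    outer(sin(2 * pi * 8 * tt), Q8[, 4])
  noisy <- LfpRecording(x + 0.01 * matrix(rnorm(length(tt) * 8), ncol = 8),
                        fs = fs)
  plSlow <- ProjectionPlane(Q8[, 1], Q8[, 2])
  plFast <- ProjectionPlane(Q8[, 3], Q8[, 4])
  inBand <- mean(values(bandedArealVelocity(noisy, plSlow, c(1, 4))))
  crossBand <- mean(values(bandedArealVelocity(noisy, plFast, c(1, 4))))
  expect_gt(inBand, 0)
  expect_lt(abs(crossBand), 0.05 * abs(inBand))

  # a band with no signal energy averages to ~zero
  quiet <- mean(values(bandedArealVelocity(noisy, plSlow, c(20, 40))))
  expect_lt(abs(quiet), 0.01 * inBand)

  # when the band spans all signal energy, banded == unbanded (noiseless)
  clean <- LfpRecording(x, fs = fs)
  avFull <- values(bandedArealVelocity(clean, plSlow, c(0.5, 20)))
  avUn <- values(arealVelocityPlane(clean, plSlow))
  v <- 1000:5000
  relErr <- sqrt(mean((avFull[v] - avUn[v])^2)) / sqrt(mean(avUn[v]^2))
  expect_lt(relErr, 0.01)

  expect_error(bandedArealVelocity(noisy, plSlow, c(4, 1)), "invalid band")
  expect_error(arealVelocityPlane(noisy, ProjectionPlane(Q8[, 1], Q8[, 2],
                                                         freqHz = 1)),
               NA)
})
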