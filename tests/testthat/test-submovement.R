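# Submovement detection, triggered averages, speed proportionality and
# direction decoding.

## kinematics made of Gaussian speed pulses at known times/directions
pulseKinematics <- function(times, speeds, dirs, dur = 30, fs = 100,
                            width = 0.08) {
  tt <- seq(0, dur, by = 1 / fs)
  vel <- matrix(0, length(tt), 2)
  for (e in seq_along(times)) {
    p <- speeds[e] * exp(-(tt - times[e])^2 / (2 * width^2))
    vel[, 1] <- vel[, 1] + p * cos(dirs[e])
    vel[, 2] <- vel[, 2] + p * sin(dirs[e])
  }
  KinematicsTrace(tt, apply(vel, 2, cumsum) / fs)
}

test_that("speed peaks are detected at the constructed times, nothing more", {
  times <- c(2, 3.1, 5, 8.4, 12, 15.5, 20, 25.2)
  dirs <- seq(-pi + 0.1, pi, length.out = 8)
  kin <- pulseKinematics(times, rep(1.5, 8), dirs)
  ev <- detectSubmovements(kin)
  expect_length(ev@times, 8L)
  expect_lt(max(abs(ev@times - times)), 0.011)
  expect_lt(max(abs(wrapAngle_test(ev@directions - dirs))), 0.1)
  expect_true(all(ev@windowStart < ev@times & ev@times < ev@windowEnd))

  # flat speed -> no events
  flat <- KinematicsTrace(seq(0, 5, 0.01), cbind(seq(0, 5, 0.01) * 0, 0))
  expect_length(detectSubmovements(flat)@times, 0L)

  # relative threshold: uniform speed scaling leaves the count unchanged
  kinBig <- KinematicsTrace(timeAxis(kin), values(kin) * 37)
  expect_length(detectSubmovements(kinBig)@times, 8L)

  # fixture event rate falls in the 1-4 per second submovement band
  fx <- defaultFixture()
  evFx <- detectSubmovements(fx$kin)
  rate <- length(evFx@times) / (max(timeAxis(fx$kin)) - min(timeAxis(fx$kin)))
  expect_gt(rate, 1); expect_lt(rate, 4)
})

test_that("triggered averages recover a planted template and conserve counts", {
  set.seed(51)
  fs <- 100
  dur <- 120
  tt <- seq(0, dur, by = 1 / fs)
  times <- seq(2, dur - 2, by = 1.1)
  lagIdx <- -25:25
  template <- sin(2 * pi * 3 * lagIdx / fs) * exp(-(lagIdx / fs)^2 / 0.02)
  x <- numeric(length(tt))
  for (t0 in times) x[round(t0 * fs) + 1 + lagIdx] <- x[round(t0 * fs) + 1 + lagIdx] + template
  sigma <- 0.5
  noisy <- x + rnorm(length(tt), sd = sigma)
  sig <- new("ArealVelocitySignal", values = noisy, fs = fs, tStart = 0,
             id = "test")
  ev <- new("SubmovementEvents", times = times,
            speeds = rep(1, length(times)) + runif(length(times)),
            directions = wrapAngle_test(seq_along(times)),
            windowStart = times - 0.25, windowEnd = times + 0.25)

  ta1 <- triggeredAverage(sig, ev, c(-0.25, 0.25), "speed", 1)
  expect_equal(ta1$counts, length(times))
  expect_lt(max(abs(ta1$means[[1]][, 1] - template)),
            4 * sigma / sqrt(length(times)))

  # one event: the average is the raw snippet
  one <- new("SubmovementEvents", times = times[3], speeds = 1,
             directions = 0.5, windowStart = times[3] - 0.2,
             windowEnd = times[3] + 0.2)
  taOne <- triggeredAverage(sig, one, c(-0.1, 0.1), "speed", 1)
  c0 <- round(times[3] * fs) + 1
  expect_equal(taOne$means[[1]][, 1], noisy[c0 + (-10:10)],
               ignore_attr = TRUE)

  # direction sectors cover all events
  ta8 <- triggeredAverage(sig, ev, c(-0.1, 0.1), "direction", 8)
  expect_equal(sum(ta8$counts), length(times))
  expect_error(triggeredAverage(sig, ev, c(-0.1, 0.1), "speed", 0), "nBins")
})

test_that("speed regression: null slope on constant AV, c^2 slope under LFP scaling", {
  set.seed(52)
  g <- generate(generatorConfig(seed = 52, duration = 150, eventRate = 1.2,
                                speedSdLog = 0.6))
  lmp <- lowpassLmp(g$lfp)
  ev <- detectSubmovements(g$kin)
  b <- fitPca(lmp, 3)
  pl <- ProjectionPlane(b@components[, 1], b@components[, 2])

  # constant AV regardless of speed: slope CI includes 0
  const <- new("ArealVelocitySignal",
               values = rep(2, nrow(values(lmp))) + rnorm(nrow(values(lmp)),
                                                          sd = 1e-3),
               fs = 100, tStart = 0, id = "const")
  srC <- speedAvRegression(const, ev)
  ciSlope <- confint(srC$fit)[2, ]
  expect_true(ciSlope[1] <= 0 && ciSlope[2] >= 0)

  # doubling the LFP scale quadruples the slope (AV ~ amplitude^2)
  sr1 <- speedAvRegression(lmp, ev, plane = pl, metric = "integral",
                           baselineCorrect = FALSE)
  doubled <- LfpRecording(2 * values(lmp), fs = 100,
                          channelIds = channelIds(lmp))
  sr4 <- speedAvRegression(doubled, ev, plane = pl, metric = "integral",
                           baselineCorrect = FALSE)
  expect_equal(sr4$slope, 4 * sr1$slope, tolerance = 1e-9)

  expect_error(speedAvRegression(lmp, ev, plane = pl, nBins = 2), "3 speed")
  expect_error(speedAvRegression(lmp, ev), "plane is required")
})

test_that("angular CoD has its definitional anchors", {
  th <- c(-2.5, -1, 0, 0.5, 1.2, 2.8)
  expect_equal(angularCoD_test(th, th), 1)
  # predicting the circular mean for every event gives exactly 0
  thetaBar <- atan2(mean(sin(th)), mean(cos(th)))
  expect_equal(angularCoD_test(rep(thetaBar, length(th)), th), 0)
  expect_error(angularCoD_test(th, rep(1, 6)), "identical")
})

test_that("direction decoding is seed-reproducible and frame-invariant", {
  g <- generate(generatorConfig(seed = 53))
  lmp <- lowpassLmp(g$lfp)
  ev <- detectSubmovements(g$kin)
  av3 <- arealVelocityVector3(lmp, fitPca(lmp, 3))

  d1 <- decodeDirection(av3, ev, nShuffles = 50, seed = 99)
  d2 <- decodeDirection(av3, ev, nShuffles = 50, seed = 99)
  expect_identical(d1$shuffleCod, d2$shuffleCod)
  expect_identical(d1$cod, d2$cod)
  expect_lte(d1$cod, 1)
  expect_length(d1$shuffleCod, 50L)

  # rotating the task frame (constant added to all angles) leaves CoD
  # unchanged once the decoder map is refit
  evRot <- new("SubmovementEvents", times = ev@times, speeds = ev@speeds,
               directions = wrapAngle_test(ev@directions + 1.1),
               windowStart = ev@windowStart, windowEnd = ev@windowEnd)
  d3 <- decodeDirection(av3, evRot, nShuffles = 50, seed = 99)
  expect_equal(d3$cod, d1$cod, tolerance = 1e-6)

  few <- new("SubmovementEvents", times = ev@times[1:10],
             speeds = ev@speeds[1:10], directions = ev@directions[1:10],
             windowStart = ev@windowStart[1:10],
             windowEnd = ev@windowEnd[1:10])
  expect_error(decodeDirection(av3, few), "16")
  same <- new("SubmovementEvents", times = ev@times,
              speeds = ev@speeds,
              directions = rep(1, length(ev@times)),
              windowStart = ev@windowStart, windowEnd = ev@windowEnd)
  expect_error(decodeDirection(av3, same), "identical")
})
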