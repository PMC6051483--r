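# SRSP decomposition, Wiener/FIR rate decoding, stability.

makeRankKModel <- function(nSources = 3, C = 6, lagIdx = -40:40,
                           seed = 31) {
  set.seed(seed)
  lags <- lagIdx * 0.01
  W <- vapply(seq_len(nSources), function(k)
    exp(-(lags - 0.03 * k)^2 / 0.01) * sin(2 * pi * k * lags), numeric(length(lags)))
  A <- matrix(rnorm(C * nSources), C, nSources)
  kern <- array(0, c(1, C, length(lags)))
  kern[1, , ] <- A %*% t(W)
  new("SrspModel", kernels = kern, lags = lags, binWidth = 0.01,
      offsets = rep(0, C), ridge = 0, vaf = rep(1, C), unitIds = "u1",
      channelIds = paste0("ch", seq_len(C)))
}

test_that("SRSP decomposition recovers exact low-rank structure", {
  m <- makeRankKModel(3)
  b <- decomposeSrsp(m, 3)
  expect_gt(sum(b@varianceFractions[[1]][1:3]), 1 - 1e-9)
  # demixing inverts the loadings
  expect_lt(max(abs(b@projections[[1]] %*% b@loadings[[1]] - diag(3))), 1e-8)
  # waveforms orthonormal (validity also enforces this)
  W <- b@waveforms[[1]]
  expect_lt(max(abs(crossprod(W) - diag(3))), 1e-10)
  expect_error(decomposeSrsp(m, 5), "rank 3")
})

test_that("single-channel decomposition returns the normalized kernel", {
  set.seed(32)
  k <- sin(seq(-1, 1, length.out = 21))
  kern <- array(k, c(1, 1, 21))
  m <- new("SrspModel", kernels = kern, lags = (-10:10) * 0.01,
           binWidth = 0.01, offsets = 0, ridge = 0, vaf = 1,
           unitIds = "u1", channelIds = "ch1")
  b <- decomposeSrsp(m, 1)
  w <- b@waveforms[[1]][, 1]
  expect_lt(min(max(abs(w - k / sqrt(sum(k^2)))),
                max(abs(w + k / sqrt(sum(k^2))))), 1e-10)
})

test_that("Wiener deconvolution inverts an invertible noiseless system", {
  set.seed(33)
  bin <- 0.01; T <- 30000
  lagIdx <- -50:50; lags <- lagIdx * bin
  # broadband (near-delta) waveform: spectrum bounded away from zero
  w <- exp(-(lags - 0.02)^2 / (2 * 0.01^2)) +
    0.3 * exp(-(lags + 0.03)^2 / (2 * 0.015^2))
  mixv <- c(1, 0.6, -0.4)
  bf <- signal::butter(4, 2 / (0.5 / bin), type = "low")
  rate <- 10 + 5 * signal::filtfilt(bf, rnorm(T))
  s <- acausalFilter_test(rate, w, lagIdx)
  L <- outer(s, mixv)
  kern <- array(0, c(1, 3, length(lags)))
  for (c in 1:3) kern[1, c, ] <- mixv[c] * w
  m <- new("SrspModel", kernels = kern, lags = lags, binWidth = bin,
           offsets = rep(0, 3), ridge = 0, vaf = rep(1, 3),
           unitIds = "u1", channelIds = paste0("ch", 1:3))
  basis <- decomposeSrsp(m, 1)
  half <- seq_len(T / 2)
  dec <- buildRateDecoder(basis, LfpRecording(L[half, ], fs = 1 / bin),
                          BinnedRates(matrix(rate[half], ncol = 1), bin,
                                      isCounts = FALSE), nsr = 1e-9)
  est <- estimateRates(dec, LfpRecording(L[-half, ], fs = 1 / bin))
  v <- 200:14800
  expect_gt(cor(values(est)[v, 1], rate[-half][v]), 0.99)

  # infinite noise-to-signal collapses the estimate to the mean rate
  decInf <- buildRateDecoder(basis, LfpRecording(L[half, ], fs = 1 / bin),
                             BinnedRates(matrix(rate[half], ncol = 1), bin,
                                         isCounts = FALSE), nsr = Inf)
  estInf <- estimateRates(decInf, LfpRecording(L[-half, ], fs = 1 / bin))
  expect_equal(sd(values(estInf)), 0)
  # offset is the mean rate over the training rows inside the filter span
  expect_equal(values(estInf)[1, 1], mean(rate[half]), tolerance = 1e-3)

  expect_error(buildRateDecoder(basis, LfpRecording(L, fs = 1 / bin),
                                BinnedRates(matrix(rate, ncol = 1), bin,
                                            isCounts = FALSE), nsr = -1),
               "non-negative")
})

test_that("rate estimation is a pure linear time-invariant filter", {
  g <- generate(generatorConfig(seed = 34, duration = 60))
  lmp <- lowpassLmp(g$lfp)
  cts <- binSpikes(g$spikes, 0.01)
  dec <- buildRateDecoder(decomposeSrsp(fitMiso(cts, lmp), 3), lmp, cts)

  # zero (mean-level) input -> constant offsets
  zero <- LfpRecording(matrix(0, 500, nChannels(lmp)), fs = 100,
                       channelIds = channelIds(lmp))
  est0 <- estimateRates(dec, zero)
  expect_true(all(abs(sweep(values(est0), 2, dec@offsets)) < 1e-12))

  # superposition to 1e-9
  set.seed(34)
  A <- LfpRecording(matrix(rnorm(2000 * nChannels(lmp)), ncol = nChannels(lmp)),
                    fs = 100, channelIds = channelIds(lmp))
  B <- LfpRecording(matrix(rnorm(2000 * nChannels(lmp)), ncol = nChannels(lmp)),
                    fs = 100, channelIds = channelIds(lmp))
  AB <- LfpRecording(1.3 * values(A) - 0.4 * values(B), fs = 100,
                     channelIds = channelIds(lmp))
  lhs <- values(estimateRates(dec, AB))
  # affine map: f(aX + bY) = a f(X) + b f(Y) + (1 - a - b) * offset
  rhs <- 1.3 * values(estimateRates(dec, A)) -
    0.4 * values(estimateRates(dec, B)) +
    0.1 * matrix(rep(dec@offsets, each = 2000), 2000)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # shifting the LFP shifts the output exactly (time invariance)
  k <- 7
  shifted <- LfpRecording(rbind(matrix(0, k, nChannels(lmp)),
                                values(A)[seq_len(2000 - k), ]),
                          fs = 100, channelIds = channelIds(lmp))
  e1 <- values(estimateRates(dec, A))
  e2 <- values(estimateRates(dec, shifted))
  v <- 300:1800
  expect_equal(e2[v + k, ], e1[v, ], tolerance = 1e-12)

  # clipping is optional and only truncates below zero
  estC <- estimateRates(dec, A, clipNonnegative = TRUE)
  expect_gte(min(values(estC)), 0)

  wrong <- LfpRecording(values(A)[, 1:3], fs = 100,
                        channelIds = paste0("x", 1:3))
  expect_error(estimateRates(dec, wrong), "channel ids")
})

test_that("stability: estimates persist across sessions, silencing and scrambling hurt spikes", {
  fx <- defaultFixture()
  lmp <- lowpassLmp(fx$lfp)
  cts <- binSpikes(fx$spikes, 0.01)
  dec <- buildRateDecoder(decomposeSrsp(fitMiso(cts, lmp), 3), lmp, cts)
  ev1 <- detectSubmovements(fx$kin)

  g2 <- generate(generatorConfig(seed = 424))          # a "later" session
  ev2 <- detectSubmovements(g2$kin)
  spk2 <- spikeTimes(g2$spikes)
  scrambled <- SpikeTrainSet(unitIds(g2$spikes), spk2[c(6, 5, 4, 3, 2, 1)],
                             0, 120)
  rep <- stabilityReport(dec,
    sessions = list(list(spikes = fx$spikes, lfp = lmp),
                    list(spikes = g2$spikes, lfp = lowpassLmp(g2$lfp)),
                    list(spikes = scrambled, lfp = lowpassLmp(g2$lfp))),
    events = list(ev1@times, ev2@times, ev2@times))
  al <- tapply(rep$r_aligned, rep$session, mean)
  inst <- tapply(rep$r_inst, rep$session, mean)

  # self-session aligned averages beat instantaneous correlations
  expect_gt(al[["1"]], inst[["1"]])
  expect_gt(al[["1"]], 0.7)
  # estimates generalize to a later session from the same generative model
  expect_gt(al[["2"]], 0.7)
  # scrambled unit identities degrade both metrics
  expect_gt(al[["2"]], al[["3"]])
  expect_gt(inst[["2"]], inst[["3"]])

  # LFP-driven estimates survive losing half the units, a spikes-only
  # readout does not: the silenced units' own rates carry no signal
  silenced <- SpikeTrainSet(unitIds(g2$spikes),
                            c(spk2[1:3], rep(list(numeric()), 3)), 0, 120)
  silCts <- smoothRates(binSpikes(silenced, 0.01))
  actCts <- smoothRates(binSpikes(g2$spikes, 0.01))
  est <- estimateRates(dec, lowpassLmp(g2$lfp))
  T <- min(nrow(values(est)), nrow(values(actCts)))
  rLfp <- vapply(4:6, function(u)
    cor(values(est)[1:T, u], values(actCts)[1:T, u]), 0)
  rSpk <- vapply(4:6, function(u)
    suppressWarnings(cor(values(silCts)[1:T, u], values(actCts)[1:T, u])), 0)
  rSpk[is.na(rSpk)] <- 0
  expect_gt(mean(rLfp), mean(rSpk) + 0.2)

  # a session without events warns and yields NA for the aligned metric
  expect_warning(
    rep0 <- stabilityReport(dec,
      sessions = list(list(spikes = fx$spikes, lfp = lmp)),
      events = list(numeric())),
    "no alignment events")
  expect_true(all(is.na(rep0$r_aligned)))
})
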