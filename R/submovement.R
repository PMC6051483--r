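# Submovement analysis: continuous movements decompose into discrete speed
# pulses at 1-4 per second, each phase-locked to one cycle of the slow LFP
# oscillation. This module detects the pulses from cursor kinematics,
# builds event-triggered averages, quantifies the linear relation between
# areal velocity and submovement speed, and decodes submovement direction
# from the 3D areal-velocity vector with an angular coefficient of
# determination (CoD) and a permutation control.

#' Detect submovements from cursor kinematics
#'
#' Speed = |d position / dt| (central differences), low-passed at
#' `smoothHz` (zero phase). Submovements are local speed maxima above
#' `thresholdFrac` times a robust maximum (the 99th speed percentile),
#' separated by at least `minSeparation`; the detection count is invariant
#' to uniform speed scaling because the threshold is relative. Each event's
#' direction is the angle of the net displacement between the flanking
#' speed minima.
#'
#' @param kin a [KinematicsTrace-class] spanning more than 1 s.
#' @param smoothHz speed smoothing cutoff, Hz.
#' @param minSeparation minimum peak separation, seconds.
#' @param thresholdFrac detection threshold as a fraction of the robust
#'   maximum speed.
#' @return a [SubmovementEvents-class] (possibly with zero events).
#' @export
detectSubmovements <- function(kin, smoothHz = 10, minSeparation = 0.2,
                               thresholdFrac = 0.1) {
  fs <- samplingRate(kin)
  if (length(kin@times) / fs <= 1)
    stop("kinematics span must exceed 1 s", call. = FALSE)
  vel <- derivMatrix(kin@position, fs)
  speed <- sqrt(rowSums(vel^2))
  if (smoothHz < fs / 2) {
    bf <- signal::butter(4, smoothHz / (fs / 2), type = "low")
    speed <- zeroPhaseFilter(bf, speed)
  }
  robustMax <- stats::quantile(speed, 0.99, names = FALSE)
  thr <- thresholdFrac * robustMax
  n <- length(speed)
  emptyEvents <- new("SubmovementEvents", times = numeric(),
                     speeds = numeric(), directions = numeric(),
                     windowStart = numeric(), windowEnd = numeric())
  if (robustMax <= 0) return(emptyEvents)
  isPeak <- c(FALSE, speed[2:(n - 1)] > speed[1:(n - 2)] &
                speed[2:(n - 1)] >= speed[3:n], FALSE) & speed > thr
  pk <- which(isPeak)
  if (!length(pk)) return(emptyEvents)
  # enforce minimum separation, keeping the larger peak
  minSep <- round(minSeparation * fs)
  keep <- logical(length(pk))
  ord <- order(speed[pk], decreasing = TRUE)
  taken <- integer()
  for (i in ord) {
    if (!length(taken) || all(abs(pk[i] - taken) >= minSep)) {
      keep[i] <- TRUE
      taken <- c(taken, pk[i])
    }
  }
  pk <- sort(pk[keep])
  isMin <- c(TRUE, speed[2:(n - 1)] < speed[1:(n - 2)] &
               speed[2:(n - 1)] <= speed[3:n], TRUE)
  mins <- which(isMin)
  lo <- hi <- integer(length(pk))
  for (i in seq_along(pk)) {
    lo[i] <- max(mins[mins < pk[i]])
    hi[i] <- min(mins[mins > pk[i]])
  }
  disp <- kin@position[hi, , drop = FALSE] - kin@position[lo, , drop = FALSE]
  new("SubmovementEvents",
      times = kin@times[pk], speeds = speed[pk],
      directions = wrapAngle(atan2(disp[, 2], disp[, 1])),
      windowStart = kin@times[lo], windowEnd = kin@times[hi])
}

## Extract per-event snippets of a sampled signal matrix around event times.
## Returns list(snips = lag x chan x event array, lags, used, dropped).
eventSnippets <- function(x, t0, fs, events, window) {
  x <- as.matrix(x)
  iPre <- round(window[1] * fs); iPost <- round(window[2] * fs)
  lags <- seq.int(iPre, iPost) / fs
  centers <- round((events - t0) * fs) + 1L
  ok <- centers + iPre >= 1L & centers + iPost <= nrow(x)
  arr <- array(0, dim = c(length(lags), ncol(x), sum(ok)))
  ii <- 0L
  for (e in which(ok)) {
    ii <- ii + 1L
    arr[, , ii] <- x[seq.int(centers[e] + iPre, centers[e] + iPost), ,
                     drop = FALSE]
  }
  list(snips = arr, lags = lags, used = which(ok), dropped = sum(!ok))
}

#' Event-triggered averages grouped by submovement speed or direction
#'
#' Extracts a window around every retained event (events whose window
#' leaves the recording are dropped and counted), groups events into
#' equal-count speed quantile bins or equal-width direction sectors, and
#' averages the snippets per group. Deterministic given its inputs.
#'
#' @param signal an [ArealVelocitySignal-class], [ArealVelocityVector-class]
#'   or [LfpRecording-class].
#' @param events a [SubmovementEvents-class].
#' @param window c(tPre, tPost) seconds around the speed peak (tPre
#'   negative).
#' @param groupBy "speed" (quantile bins) or "direction" (sectors of
#'   (-pi, pi]).
#' @param nBins number of groups, >= 1.
#' @return list of class "TriggeredAverage": lag grid, per-group mean
#'   array (lag x channel), event counts, group labels, dropped-event
#'   count.
#' @export
triggeredAverage <- function(signal, events, window = c(-0.25, 0.25),
                             groupBy = c("speed", "direction"), nBins = 5) {
  groupBy <- match.arg(groupBy)
  if (nBins < 1L) stop("nBins must be >= 1", call. = FALSE)
  x <- values(signal)
  fs <- samplingRate(signal)
  t0 <- startTime(signal)
  sn <- eventSnippets(x, t0, fs, events@times, window)
  nEv <- dim(sn$snips)[3]
  if (nEv == 0L) stop("no events fall inside the recording", call. = FALSE)
  speeds <- events@speeds[sn$used]
  dirs <- events@directions[sn$used]
  if (groupBy == "speed") {
    qs <- stats::quantile(speeds, probs = seq(0, 1, length.out = nBins + 1L),
                          names = FALSE)
    grp <- findInterval(speeds, qs, rightmost.closed = TRUE,
                        all.inside = TRUE)
    labels <- vapply(seq_len(nBins), function(b)
      sprintf("speed[%.3g,%.3g]", qs[b], qs[b + 1]), "")
    centers <- vapply(seq_len(nBins), function(b)
      mean(speeds[grp == b]), 0)
  } else {
    edges <- seq(-pi, pi, length.out = nBins + 1L)
    grp <- findInterval(dirs, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    labels <- vapply(seq_len(nBins), function(b)
      sprintf("dir[%.2f,%.2f]", edges[b], edges[b + 1]), "")
    centers <- (edges[-1] + edges[-(nBins + 1L)]) / 2
  }
  means <- vector("list", nBins)
  counts <- integer(nBins)
  for (b in seq_len(nBins)) {
    idx <- which(grp == b)
    counts[b] <- length(idx)
    means[[b]] <- if (length(idx))
      apply(sn$snips[, , idx, drop = FALSE], c(1, 2), mean)
    else matrix(numeric(), 0, dim(sn$snips)[2])
  }
  structure(list(lags = sn$lags, means = means, counts = counts,
                 labels = labels, centers = centers, groupBy = groupBy,
                 dropped = sn$dropped),
            class = "TriggeredAverage")
}

#' @export
print.TriggeredAverage <- function(x, ...) {
  cat(sprintf("TriggeredAverage by %s: %d groups, %d events (%d dropped)\n",
              x$groupBy, length(x$counts), sum(x$counts), x$dropped))
  invisible(x)
}

#' Areal velocity versus submovement speed
#'
#' Bins events by speed and fits an ordinary least-squares line of a
#' per-bin areal-velocity metric against the bin mean speed. The preferred
#' route (pass the LFP plus a plane) computes the areal velocity *of the
#' submovement-triggered average trajectory* per speed bin -- averaging
#' the trajectory first cancels incoherent noise linearly before the
#' quadratic AV is taken. Passing a precomputed
#' [ArealVelocitySignal-class] instead averages the AV signal itself
#' (noisier: the event-incoherent AV does not average out). The metric is
#' the trace peak (or windowed integral) after baseline correction
#' (subtracting the mean over the outer quarters of the window, which
#' removes the speed-independent areal velocity of ongoing background
#' activity). Because areal velocity scales with the square of the LFP
#' amplitude, doubling the LFP scale quadruples the slope.
#'
#' @param signal an [LfpRecording-class] (with `plane`) or an
#'   [ArealVelocitySignal-class].
#' @param events a [SubmovementEvents-class].
#' @param window seconds around the speed peak.
#' @param nBins number of speed bins (>= 3).
#' @param metric "peak" or "integral" of the per-bin trace.
#' @param plane a [ProjectionPlane-class]; required when `signal` is an
#'   LFP recording.
#' @param baselineCorrect subtract the outer-window mean (default TRUE).
#' @return list: slope, intercept, r.squared, interceptCI (95%), per-bin
#'   speeds and AV metrics, and the underlying lm fit.
#' @export
speedAvRegression <- function(signal, events, window = c(-0.25, 0.25),
                              nBins = 5, metric = c("peak", "integral"),
                              plane = NULL, baselineCorrect = TRUE) {
  metric <- match.arg(metric)
  if (nBins < 3L) stop("need at least 3 speed bins", call. = FALSE)
  fromTrajectory <- is(signal, "LfpRecording")
  if (fromTrajectory && is.null(plane))
    stop("a plane is required when 'signal' is an LfpRecording",
         call. = FALSE)
  ta <- triggeredAverage(signal, events, window, "speed", nBins)
  fs <- samplingRate(signal)
  nL <- length(ta$lags)
  outer <- c(seq_len(ceiling(nL / 4)), seq.int(nL - ceiling(nL / 4) + 1L, nL))
  met <- vapply(seq_len(nBins), function(b) {
    tr <- ta$means[[b]]
    if (!nrow(tr)) return(NA_real_)
    tr <- if (fromTrajectory) {
      meanLfp <- LfpRecording(tr, fs = fs, channelIds = channelIds(signal))
      arealVelocityPlane(meanLfp, plane)@values
    } else tr[, 1]
    if (baselineCorrect) tr <- tr - mean(tr[outer])
    if (metric == "peak") max(tr) else sum(tr) / fs
  }, 0)
  ok <- is.finite(met)
  fit <- stats::lm(met[ok] ~ ta$centers[ok])
  ci <- stats::confint(fit)[1, ]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = summary(fit)$r.squared,
       interceptCI = unname(ci),
       binSpeeds = ta$centers, binAv = met, fit = fit)
}

## Orthogonal Procrustes: rotation R minimizing ||A R - B||_F
procrustesRotation <- function(A, B) {
  sv <- svd(crossprod(A, B))
  sv$u %*% t(sv$v)
}

## angular coefficient of determination against the circular-mean baseline
angularCoD <- function(predicted, actual) {
  thetaBar <- circularMean(actual)
  denom <- sum(wrapAngle(thetaBar - actual)^2)
  if (denom == 0)
    stop("all directions identical: angular CoD undefined", call. = FALSE)
  1 - sum(wrapAngle(predicted - actual)^2) / denom
}

#' Decode submovement direction from the 3D areal-velocity vector
#'
#' Per event, the areal-velocity vector is integrated over a window around
#' the speed peak and normalized to a unit rotation axis. A least-squares
#' orthogonal map (Procrustes) from event axes to the unit vectors
#' `(cos theta, sin theta, 0)` of the true directions is fit on training
#' folds and applied to validation folds (k-fold cross-validation);
#' the predicted direction is the atan2 of the first two mapped
#' components. Accuracy is the angular coefficient of determination
#' `CoD = 1 - sum d(theta_hat, theta)^2 / sum d(theta_bar, theta)^2`
#' (d = wrapped difference, theta_bar = circular mean of the true
#' directions), compared against the 95th percentile of the CoD over
#' `nShuffles` seeded permutations of the event-direction pairing.
#'
#' @param av3 an [ArealVelocityVector-class].
#' @param events a [SubmovementEvents-class] with >= 16 usable events.
#' @param window integration window, seconds around the speed peak.
#' @param nShuffles permutations for the null distribution.
#' @param seed RNG seed (shuffles and fold assignment are bit-reproducible
#'   given the seed).
#' @param nFolds cross-validation folds.
#' @return list of class "DirectionDecodeResult": predicted directions,
#'   `cod`, shuffle distribution, 95th-percentile threshold, pass flag.
#' @export
decodeDirection <- function(av3, events, window = c(-0.25, 0.25),
                            nShuffles = 1000, seed = 1, nFolds = 5) {
  sn <- eventSnippets(av3@values, av3@tStart, av3@fs, events@times, window)
  nEv <- dim(sn$snips)[3]
  if (nEv < 16L)
    stop(sprintf("need at least 16 usable events, got %d", nEv),
         call. = FALSE)
  dirs <- events@directions[sn$used]
  if (max(abs(wrapAngle(dirs - dirs[1]))) < 1e-12)
    stop("all directions identical: angular CoD undefined", call. = FALSE)
  axes <- t(apply(sn$snips, 3L, function(s) colSums(s) / av3@fs))
  nrm <- sqrt(rowSums(axes^2))
  nrm[nrm == 0] <- 1
  axes <- axes / nrm

  # The population rotation has a dominant common axis; submovement
  # direction lives in the deviation around it. Each fold therefore
  # centers the axes on the training-fold mean before fitting the
  # orthogonal map -- an orthogonal map cannot send a tight cone of raw
  # axes onto the full equator of direction targets.
  runCv <- function(theta, fold) {
    pred <- numeric(nEv)
    B <- cbind(cos(theta), sin(theta), 0)
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      if (!any(tr) || all(tr)) next
      ctr <- colMeans(axes[tr, , drop = FALSE])
      Ac <- sweep(axes, 2L, ctr)
      nr <- sqrt(rowSums(Ac^2)); nr[nr == 0] <- 1
      Ac <- Ac / nr
      R <- procrustesRotation(Ac[tr, , drop = FALSE], B[tr, , drop = FALSE])
      mapped <- Ac[!tr, , drop = FALSE] %*% R
      pred[!tr] <- atan2(mapped[, 2], mapped[, 1])
    }
    pred
  }

  withSeed(seed, {
    fold <- sample(rep_len(seq_len(nFolds), nEv))
    pred <- runCv(dirs, fold)
    cod <- angularCoD(pred, dirs)
    shuffles <- vapply(seq_len(nShuffles), function(s) {
      sh <- sample(dirs)
      angularCoD(runCv(sh, fold), sh)
    }, 0)
    thr <- stats::quantile(shuffles, 0.95, names = FALSE)
    structure(list(predicted = pred, actual = dirs, cod = cod,
                   shuffleCod = shuffles, threshold95 = thr,
                   pass = cod > thr, nEvents = nEv, seed = seed),
              class = "DirectionDecodeResult")
  })
}

#' @export
print.DirectionDecodeResult <- function(x, ...) {
  cat(sprintf(
    "DirectionDecodeResult: %d events, angular CoD %.3f (shuffle 95%%: %.3f) -> %s\n",
    x$nEvents, x$cod, x$threshold95, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
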