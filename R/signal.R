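#' @include AllClasses.R utils.R
NULL

identityCalibration <- function(flags = character(), nStatic = 0L,
                                sphereErrorMg = NA_real_) {
  new("CalibrationModel", gain = c(1, 1, 1), offset = c(0, 0, 0),
      nStatic = as.integer(nStatic), sphereErrorMg = sphereErrorMg,
      converged = FALSE, flags = flags)
}

# mean acceleration per static window (windowSec), excluding windows with
# per-axis SD above sdCrit (g) or any clipped sample
staticWindowMeans <- function(rec, windowSec = 10, sdCrit = 0.013) {
  w <- round(rec@sampleRate * windowSec)
  nWin <- floor(nrow(rec@acc) / w)
  if (nWin == 0L) return(matrix(numeric(), 0, 3))
  idx <- seq_len(nWin * w)
  g <- rep(seq_len(nWin), each = w)
  clipLim <- 0.95 * rec@dynamicRange
  means <- vapply(1:3, function(k)
    tapply(rec@acc[idx, k], g, mean), numeric(nWin))
  sds <- vapply(1:3, function(k)
    tapply(rec@acc[idx, k], g, stats::sd), numeric(nWin))
  clip <- tapply(apply(abs(rec@acc[idx, , drop = FALSE]), 1, max) > clipLim,
                 g, any)
  keep <- rowSums(sds < sdCrit) == 3L & !clip
  matrix(means[keep, ], ncol = 3)
}

#' Auto-calibrate a raw recording
#'
#' Estimates per-axis gain and offset by the static-window sphere fit: mean
#' acceleration vectors of low-movement windows (10-s windows with per-axis
#' SD below 13 mg) are iteratively regressed, axis by axis, onto their
#' projections on the unit sphere. When fewer than 10 static windows exist,
#' or the static orientations do not spread over the sphere, the identity
#' model is returned with a diagnostic flag — never an error.
#'
#' @param rec a [RawRecording-class].
#' @param windowSec static window length in seconds.
#' @param sdCrit static threshold for the per-axis SD, in g.
#' @param minWindows minimum number of static windows for a fit.
#' @param maxIter,tol iteration controls.
#' @return A [CalibrationModel-class].
#' @export
#' @examples
#' prof <- stillProfile(hours = 1)
#' rec <- generateRawRecording(prof, seed = 1)
#' autoCalibrate(rec)
autoCalibrate <- function(rec, windowSec = 10, sdCrit = 0.013,
                          minWindows = 10L, maxIter = 200L, tol = 1e-10) {
  stopifnot(is(rec, "RawRecording"))
  M <- staticWindowMeans(rec, windowSec, sdCrit)
  if (nrow(M) < minWindows)
    return(identityCalibration("too few static windows", nrow(M)))
  spread <- apply(M, 2, function(v) diff(range(v)))
  if (all(spread < 0.25))
    return(identityCalibration("static orientations under-determined (single posture)",
                               nrow(M)))
  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  prevErr <- Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    cal <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    for (k in 1:3) {
      fit <- stats::lm.fit(cbind(1, M[, k]), target[, k])
      offset[k] <- fit$coefficients[1]
      gain[k] <- fit$coefficients[2]
    }
    err <- mean(abs(nrm - 1))
    if (abs(prevErr - err) < tol) { converged <- TRUE; break }
    prevErr <- err
  }
  cal <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
  new("CalibrationModel", gain = gain, offset = offset,
      nStatic = nrow(M), sphereErrorMg = 1000 * mean(abs(sqrt(rowSums(cal^2)) - 1)),
      converged = converged, flags = character())
}

#' Apply a calibration model
#'
#' @param rec a [RawRecording-class].
#' @param cal a [CalibrationModel-class].
#' @return The recording with `calibrated = raw * gain + offset` per axis.
#' @export
#' @examples
#' rec <- generateRawRecording(stillProfile(hours = 0.1), seed = 1)
#' applyCalibration(rec, autoCalibrate(rec))
applyCalibration <- function(rec, cal) {
  rec@acc <- sweep(sweep(rec@acc, 2, cal@gain, "*"), 2, cal@offset, "+")
  rec
}

#' Detect sustained clipping
#'
#' Flags 5-s epochs in which more than half of the samples sit above 95% of
#' the device dynamic range on any axis (abnormally high sustained values).
#' Flagged epochs are excluded from calibration and carried as a flag in the
#' epoch series.
#'
#' @param rec a [RawRecording-class].
#' @param epochSeconds epoch length in seconds.
#' @return Logical vector, one flag per (complete) epoch.
#' @export
#' @examples
#' rec <- generateRawRecording(stillProfile(hours = 0.01), seed = 1)
#' any(detectClipping(rec))
detectClipping <- function(rec, epochSeconds = EPOCH_SECONDS) {
  w <- round(rec@sampleRate * epochSeconds)
  nEp <- floor(nrow(rec@acc) / w)
  if (nEp == 0L) return(logical())
  lim <- 0.95 * rec@dynamicRange
  over <- apply(abs(rec@acc[seq_len(nEp * w), , drop = FALSE]), 1, max) > lim
  frac <- tapply(over, rep(seq_len(nEp), each = w), mean)
  as.vector(frac > 0.5)
}

#' Compute calibrated 5-s ENMO epochs
#'
#' Applies the calibration, computes the per-sample Euclidean norm minus one
#' with negative values truncated to zero (ENMO), averages it over 5-s
#' epochs (in mg), and derives the epoch z-angle from the epoch-mean
#' calibrated accelerations: `atan(z / sqrt(x^2 + y^2))` in degrees. A
#' trailing partial epoch is dropped. No noise filter is applied.
#'
#' @param rec a [RawRecording-class].
#' @param cal a [CalibrationModel-class] (identity by default).
#' @param epochSeconds epoch length in seconds.
#' @param participant participant id for the resulting series.
#' @return An [EpochSeries-class] (clipping flags included).
#' @export
#' @examples
#' rec <- generateRawRecording(stillProfile(hours = 0.05), seed = 1)
#' computeEnmoEpochs(rec)
computeEnmoEpochs <- function(rec, cal = identityCalibration(),
                              epochSeconds = EPOCH_SECONDS,
                              participant = "P1") {
  stopifnot(is(rec, "RawRecording"))
  rec <- applyCalibration(rec, cal)
  w <- round(rec@sampleRate * epochSeconds)
  nEp <- floor(nrow(rec@acc) / w)
  if (nEp == 0L)
    return(newEpochSeries(participant, rec@startTime, numeric(), numeric()))
  idx <- seq_len(nEp * w)
  g <- rep(seq_len(nEp), each = w)
  e <- pmax(0, sqrt(rowSums(rec@acc[idx, , drop = FALSE]^2)) - 1)
  enmoMg <- as.vector(tapply(e, g, mean)) * 1000
  axMeans <- vapply(1:3, function(k) as.vector(tapply(rec@acc[idx, k], g, mean)),
                    numeric(nEp))
  zang <- computeZAngle(axMeans)
  newEpochSeries(participant, rec@startTime, enmoMg, zang,
                 clipped = detectClipping(rec, epochSeconds))
}

#' Z-angle from calibrated accelerations
#'
#' `atan(z / sqrt(x^2 + y^2))` in degrees, computed on epoch-mean
#' accelerations. A zero vector yields 0 degrees.
#'
#' @param xyz numeric matrix (n x 3) or length-3 vector of calibrated
#'   accelerations in g.
#' @return Z-angle in degrees, in \[-90, 90\].
#' @export
#' @examples
#' computeZAngle(c(0, 0, 1))  # 90
#' computeZAngle(c(1, 0, 0))  # 0
computeZAngle <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  horiz <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  ang <- atan2(xyz[, 3], horiz) * 180 / pi
  ang[horiz == 0 & xyz[, 3] == 0] <- 0
  pmax(-90, pmin(90, ang))
}
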