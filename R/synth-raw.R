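#' @include AllClasses.R utils.R
NULL

#' Activity profiles for raw-signal simulation
#'
#' An activity profile is a data.frame of consecutive segments with columns
#' `durationSec`, `type` (`"still"` or `"active"`), `enmoTarget` (mean
#' per-sample ENMO of the segment, mg) and the body orientation `ox`, `oy`,
#' `oz` (unit vector of gravity in device axes). `stillProfile()` builds an
#' all-still profile cycling through orientations spread over the sphere
#' (a golden-spiral arrangement, so static-window calibration is
#' well-determined); `activityProfile()` validates a hand-built one.
#'
#' @param segments data.frame as above.
#' @param hours profile length in hours.
#' @param segMin still segment length in minutes.
#' @return A validated profile data.frame.
#' @export
#' @examples
#' head(stillProfile(hours = 1))
activityProfile <- function(segments) {
  need <- c("durationSec", "type", "enmoTarget", "ox", "oy", "oz")
  stopifnot(all(need %in% names(segments)))
  if (any(segments$durationSec <= 0)) stop("segment durations must be > 0")
  if (any(segments$enmoTarget < 0)) stop("target ENMO must be >= 0")
  if (!all(segments$type %in% c("still", "active")))
    stop("segment type must be 'still' or 'active'")
  nrm <- sqrt(segments$ox^2 + segments$oy^2 + segments$oz^2)
  segments[c("ox", "oy", "oz")] <- segments[c("ox", "oy", "oz")] / nrm
  segments
}

#' @rdname activityProfile
#' @export
stillProfile <- function(hours = 2, segMin = 5) {
  nSeg <- max(2L, round(hours * 60 / segMin))
  i <- seq_len(nSeg)
  # golden-spiral points on the sphere
  zc <- 1 - 2 * (i - 0.5) / nSeg
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - zc^2)
  activityProfile(data.frame(
    durationSec = hours * 3600 / nSeg, type = "still", enmoTarget = 0,
    ox = r * cos(th), oy = r * sin(th), oz = zc))
}

#' Simulate a raw triaxial recording
#'
#' Generates a 40-Hz (configurable) triaxial signal from an activity
#' profile: still segments carry the orientation's unit-gravity vector plus
#' sensor noise; active segments oscillate along the gravity axis with
#' amplitude `pi * target` so the mean per-sample ENMO matches the
#' segment's target. A per-axis calibration error is then injected:
#' `measured = true * gainError + offsetError`.
#'
#' @param profile an [activityProfile()].
#' @param sampleRate sampling frequency in Hz.
#' @param gainError,offsetError per-axis injected calibration error
#'   (offset in g).
#' @param noiseSd sensor noise SD in g.
#' @param startTime recording start (naive local clock).
#' @param dynamicRange device range in g.
#' @param seed integer seed.
#' @return A [RawRecording-class].
#' @export
#' @examples
#' rec <- generateRawRecording(stillProfile(hours = 0.1), seed = 1)
#' rec
generateRawRecording <- function(profile, sampleRate = 40,
                                 gainError = c(1, 1, 1),
                                 offsetError = c(0, 0, 0),
                                 noiseSd = 0.002,
                                 startTime = "2019-11-04 00:00:00",
                                 dynamicRange = 8, seed = 1) {
  stopifnot(sampleRate > 0, all(gainError > 0))
  profile <- activityProfile(profile)
  set.seed(seed)
  segs <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    p <- profile[i, ]
    m <- round(p$durationSec * sampleRate)
    u <- c(p$ox, p$oy, p$oz)
    base <- matrix(u, m, 3, byrow = TRUE)
    if (p$type == "active" && p$enmoTarget > 0) {
      amp <- pi * p$enmoTarget / 1000
      t <- seq_len(m) / sampleRate
      osc <- amp * sin(2 * pi * 2 * t + stats::runif(1, 0, 2 * pi))
      base <- base * (1 + osc)
    }
    segs[[i]] <- base
  }
  acc <- do.call(rbind, segs)
  acc <- acc + matrix(stats::rnorm(length(acc), 0, noiseSd), ncol = 3)
  acc <- sweep(sweep(acc, 2, gainError, "*"), 2, offsetError, "+")
  acc <- pmax(pmin(acc, dynamicRange), -dynamicRange)
  rawRecording(time = seq_len(nrow(acc)) / sampleRate, acc = acc,
               startTime = startTime, sampleRate = sampleRate,
               dynamicRange = dynamicRange)
}
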