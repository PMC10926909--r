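#' @include AllClasses.R utils.R cutpoints.R
NULL

clockToSec <- function(x) {
  if (is.numeric(x)) return(x)
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60 + if (length(p) > 2) p[3] else 0
}

#' School schedule and calendar
#'
#' Clock schedule of the school day (default 9:00-14:00 with a 30-minute
#' recess starting between 11:00 and 12:00), the PE class intervals per
#' weekday, and holiday / per-child absence dates.
#'
#' @param schoolStart,schoolEnd school hours ("HH:MM" or seconds since
#'   midnight).
#' @param recessStart,recessMin recess start and duration (minutes).
#' @param peWeekdays integer weekdays (1 = Monday) with a PE class.
#' @param peStart,peMin PE class start and duration (minutes).
#' @param holidays Date vector of holidays.
#' @param absences named list: participant id -> Date vector of school
#'   absences.
#' @return An object of class `SchoolSchedule` (a validated list with all
#'   times in seconds since midnight).
#' @export
#' @examples
#' schoolSchedule(peWeekdays = c(1, 3))
schoolSchedule <- function(schoolStart = "09:00", schoolEnd = "14:00",
                           recessStart = "11:30", recessMin = 30,
                           peWeekdays = c(2, 4), peStart = "12:00",
                           peMin = 60, holidays = as.Date(character()),
                           absences = list()) {
  s <- list(schoolStart = clockToSec(schoolStart),
            schoolEnd = clockToSec(schoolEnd),
            recessStart = clockToSec(recessStart),
            recessEnd = clockToSec(recessStart) + recessMin * 60,
            peWeekdays = as.integer(peWeekdays),
            peStart = clockToSec(peStart),
            peEnd = clockToSec(peStart) + peMin * 60,
            holidays = as.Date(holidays), absences = absences)
  if (s$recessStart < s$schoolStart || s$recessEnd > s$schoolEnd)
    stop("recess must lie inside school hours")
  if (length(peWeekdays) &&
      (s$peStart < s$schoolStart || s$peEnd > s$schoolEnd))
    stop("PE class must lie inside school hours")
  class(s) <- "SchoolSchedule"
  s
}

# slowly drifting posture angle with segment shifts; degrees
postureAngle <- function(n, segMeanEpochs, jitterSd, drift = TRUE) {
  nSeg <- max(1L, stats::rpois(1, n / segMeanEpochs) + 1L)
  lens <- apportion(n, stats::rexp(nSeg) + 0.2)
  base <- rep(stats::runif(nSeg, -55, 55), lens)[seq_len(n)]
  if (length(base) < n) base <- c(base, rep(base[length(base)], n - length(base)))
  ang <- base + stats::rnorm(n, 0, jitterSd)
  if (drift)
    ang <- ang + 2.5 * sin(2 * pi * seq_len(n) / (45 * EPOCHS_PER_MIN))
  pmax(-90, pmin(90, ang))
}

# draw epoch ENMO values for a band: log-uniform inside the band, sedentary
# half-normal below the first cut-point (avoids stacking at the edges)
drawBandEnmo <- function(band, k, cuts = intensityCutPoints()) {
  if (k == 0L) return(numeric())
  edges <- switch(band,
    SB = return(pmin(abs(stats::rnorm(k, 0, 18)), cuts[[1]] - 0.1)),
    LPA = c(cuts[[1]], cuts[[2]]),
    MPA = c(cuts[[2]], cuts[[3]]),
    VPA = c(cuts[[3]], 2500))
  exp(stats::runif(k, log(edges[1]), log(edges[2])))
}

#' Generate an epoch-level recording from daily truth
#'
#' Materializes a gapless 5-s ENMO epoch series (17,280 epochs per day) whose
#' minutes per intensity band match the supplied daily truth to within one
#' epoch per band. Activity epochs are placed over the waking day with
#' weights that emulate the study's daily structure: concentrated
#' moderate-to-vigorous activity during PE classes (about 7 min/h vigorous
#' and 23 min/h MVPA), elevated activity at recess and in the late
#' afternoon, quiet school lessons, and sedentary sleep with slow posture
#' drift overnight.
#'
#' @param dailyTruth data.frame for one participant: `date`, `dayType`
#'   (`"schoolPE"`, `"schoolNoPE"`, `"weekend"`, `"holiday"`), and minutes
#'   `lpa`, `mpa`, `vpa` (optionally `sb`; the remainder of the day is
#'   sedentary).
#' @param schedule a [schoolSchedule()].
#' @param participant participant id.
#' @param seed integer seed (reproducible given the seed).
#' @return An [EpochSeries-class] starting at midnight of the first date.
#' @export
#' @examples
#' truth <- data.frame(date = as.Date("2019-11-05"), dayType = "schoolPE",
#'                     lpa = 210, mpa = 85, vpa = 25)
#' es <- generateEpochSeries(truth, schoolSchedule(), seed = 1)
#' classifyIntensity(es)$minutes
generateEpochSeries <- function(dailyTruth, schedule = schoolSchedule(),
                                participant = "P1", seed = 1) {
  stopifnot(all(c("date", "dayType", "lpa", "mpa", "vpa") %in%
                  names(dailyTruth)))
  if (any(dailyTruth$lpa + dailyTruth$mpa + dailyTruth$vpa > 1440))
    stop("daily truth minutes exceed 1440: inconsistent day")
  set.seed(seed)
  dailyTruth <- dailyTruth[order(dailyTruth$date), ]
  days <- lapply(seq_len(nrow(dailyTruth)), function(i)
    generateEpochDay(dailyTruth[i, ], schedule))
  newEpochSeries(participant, paste(dailyTruth$date[1], "00:00:00"),
                 enmo = unlist(lapply(days, `[[`, "enmo")),
                 zangle = unlist(lapply(days, `[[`, "zangle")))
}

generateEpochDay <- function(truth, schedule) {
  n <- EPOCHS_PER_DAY
  sec <- (seq_len(n) - 1) * EPOCH_SECONDS
  wake <- sec >= 7.5 * 3600 & sec < 22.5 * 3600
  isSchool <- truth$dayType %in% c("schoolPE", "schoolNoPE")
  inSchool <- isSchool & sec >= schedule$schoolStart & sec < schedule$schoolEnd
  inRecess <- inSchool & sec >= schedule$recessStart & sec < schedule$recessEnd
  inPe <- truth$dayType == "schoolPE" &
    sec >= schedule$peStart & sec < schedule$peEnd
  lesson <- inSchool & !inRecess & !inPe
  evening <- wake & sec >= 16 * 3600 & sec < 20 * 3600

  nBand <- c(LPA = round(truth$lpa * EPOCHS_PER_MIN),
             MPA = round(truth$mpa * EPOCHS_PER_MIN),
             VPA = round(truth$vpa * EPOCHS_PER_MIN))
  band <- rep("SB", n)
  free <- wake
  if (sum(nBand) > sum(free)) free <- rep(TRUE, n)

  # concentrate MVPA inside the PE class (about 7 min/h VPA, 23 min/h MVPA)
  if (any(inPe)) {
    peCap <- sum(inPe)
    hours <- peCap / (12 * 60)
    peIdx <- which(inPe)
    take <- function(k, pool) pool[seq_len(min(k, length(pool)))]
    vIn <- take(min(round(7.4 * 60 / 5 * hours), nBand[["VPA"]]), sample(peIdx))
    band[vIn] <- "VPA"; nBand[["VPA"]] <- nBand[["VPA"]] - length(vIn)
    rest <- setdiff(peIdx, vIn)
    mIn <- take(min(round(15.6 * 60 / 5 * hours), nBand[["MPA"]]), sample(rest))
    band[mIn] <- "MPA"; nBand[["MPA"]] <- nBand[["MPA"]] - length(mIn)
    free[c(vIn, mIn)] <- FALSE
  }

  weightActive <- rep(0, n)
  weightActive[free] <- 1
  weightActive[free & lesson] <- 0.08
  weightActive[free & inRecess] <- 4
  weightActive[free & inPe] <- 6
  weightActive[free & evening] <- 3
  for (b in c("VPA", "MPA", "LPA")) {
    k <- nBand[[b]]
    if (k <= 0) next
    pool <- which(weightActive > 0)
    k <- min(k, length(pool))
    pick <- pool[sample.int(length(pool), k,
                            prob = weightActive[pool])]
    band[pick] <- b
    weightActive[pick] <- 0
  }

  enmoVal <- numeric(n)
  for (b in BAND_LEVELS) {
    idx <- which(band == b)
    enmoVal[idx] <- drawBandEnmo(b, length(idx))
  }
  zang <- numeric(n)
  zang[!wake] <- postureAngle(sum(!wake), segMeanEpochs = 20 * EPOCHS_PER_MIN,
                              jitterSd = 0.8)
  zang[wake] <- postureAngle(sum(wake), segMeanEpochs = 6 * EPOCHS_PER_MIN,
                             jitterSd = 4)
  list(enmo = enmoVal, zangle = zang)
}

#' Inject non-wear episodes into an epoch series
#'
#' Overwrites the given clock intervals with a non-wear signature (near-zero
#' ENMO and a constant z-angle) and returns the ground-truth mask so
#' detectors can be scored against it. Overlapping intervals are merged with
#' a warning. With `mode = "off"` the intervals are marked as
#' device-not-recording (`NA` ENMO) instead.
#'
#' @param es an [EpochSeries-class].
#' @param intervals data.frame with POSIXct (or coercible) columns `start`,
#'   `end`.
#' @param mode `"nonwear"` (default) or `"off"`.
#' @return list with `series` (modified `EpochSeries`) and `truth` (logical
#'   per-epoch mask of injected epochs).
#' @export
#' @examples
#' truth <- data.frame(date = as.Date("2019-11-09"), dayType = "weekend",
#'                     lpa = 180, mpa = 50, vpa = 10)
#' es <- generateEpochSeries(truth, seed = 4)
#' out <- injectNonwear(es, data.frame(start = "2019-11-09 10:00:00",
#'                                     end = "2019-11-09 11:00:00"))
#' sum(out$truth) / 12  # minutes injected
injectNonwear <- function(es, intervals, mode = c("nonwear", "off")) {
  mode <- match.arg(mode)
  stopifnot(is(es, "EpochSeries"))
  mask <- rep(FALSE, length(es@enmo))
  if (!nrow(intervals)) return(list(series = es, truth = mask))
  t0 <- as.numeric(es@start)
  s <- as.numeric(asClock(intervals$start)) - t0
  e <- as.numeric(asClock(intervals$end)) - t0
  if (any(s < 0) || any(e > length(es@enmo) * EPOCH_SECONDS))
    stop("intervals must lie within the recording span")
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (any(s[-1] < e[-length(e)]))
    warning("overlapping non-wear intervals merged")
  for (i in seq_along(s)) {
    idx <- seq.int(floor(s[i] / EPOCH_SECONDS) + 1,
                   ceiling(e[i] / EPOCH_SECONDS))
    mask[idx] <- TRUE
  }
  if (mode == "off") {
    es@enmo[mask] <- NA_real_
    es@zangle[mask] <- NA_real_
    es@wear[mask] <- FALSE
    es@provenance[mask] <- "off"
    return(list(series = es, truth = mask))
  }
  runs <- trueRuns(mask)
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    es@enmo[idx] <- abs(stats::rnorm(length(idx), 0, 2))
    es@zangle[idx] <- pmax(-90, pmin(90, es@zangle[runs$start[i]] +
                                       stats::rnorm(length(idx), 0, 0.05)))
  }
  list(series = es, truth = mask)
}
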