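#' @include AllClasses.R utils.R cutpoints.R
NULL

# smallest start index i(j) such that range(zangle[i..j]) < rangeDeg,
# computed with monotonic deques; NA angles break runs. Returns iStart.
slidingRangeStarts <- function(z, rangeDeg) {
  n <- length(z)
  iStart <- integer(n)
  qmin <- integer(n); qmax <- integer(n)  # deques of indices
  hmin <- 1L; tmin <- 0L; hmax <- 1L; tmax <- 0L
  i <- 1L
  for (j in seq_len(n)) {
    if (is.na(z[j])) {
      i <- j + 1L
      hmin <- 1L; tmin <- 0L; hmax <- 1L; tmax <- 0L
      iStart[j] <- j + 1L  # empty run
      next
    }
    while (tmin >= hmin && z[qmin[tmin]] >= z[j]) tmin <- tmin - 1L
    tmin <- tmin + 1L; qmin[tmin] <- j
    while (tmax >= hmax && z[qmax[tmax]] <= z[j]) tmax <- tmax - 1L
    tmax <- tmax + 1L; qmax[tmax] <- j
    while (z[qmax[hmax]] - z[qmin[hmin]] >= rangeDeg) {
      i <- i + 1L
      if (qmin[hmin] < i) hmin <- hmin + 1L
      if (qmax[hmax] < i) hmax <- hmax + 1L
    }
    iStart[j] <- i
  }
  iStart
}

#' Detect non-wear time
#'
#' Unions two rules. (a) Baseline rule: 60-min windows advanced in 15-min
#' steps are classified non-wear when the epoch-ENMO SD is below 13 mg and
#' the posture is stable (z-angle range below `baselineAngleRange`); all
#' epochs of a flagged window become non-wear. (b) Strict rule: maximal
#' epoch runs whose z-angle range stays below 2 degrees are flagged where
#' they fall inside the daily 08:00-22:00 window, provided the inside
#' portion lasts at least 30 minutes (portions outside the window never
#' count). Epochs with no recording are non-wear with provenance "off".
#'
#' @param es an [EpochSeries-class] with z-angle.
#' @param baselineWindowMin,baselineStepMin,baselineSdCrit baseline rule:
#'   window and step length (min) and ENMO SD threshold (mg).
#' @param baselineAngleRange posture-stability range (degrees) required by
#'   the baseline surrogate.
#' @param strictMinMin,strictAngleRange strict rule: minimum in-window
#'   duration (min) and z-angle range (degrees).
#' @param strictWindow clock window (start/end, "HH:MM" or seconds) within
#'   which the strict rule applies.
#' @return A [WearMask-class].
#' @export
#' @examples
#' truth <- data.frame(date = as.Date("2019-11-09"), dayType = "weekend",
#'                     lpa = 180, mpa = 50, vpa = 10)
#' es <- generateEpochSeries(truth, seed = 4)
#' out <- injectNonwear(es, data.frame(start = "2019-11-09 10:00:00",
#'                                     end = "2019-11-09 10:45:00"))
#' mask <- detectNonwear(out$series)
#' table(provenance(mask)[!wearFlag(mask)])
detectNonwear <- function(es, baselineWindowMin = 60, baselineStepMin = 15,
                          baselineSdCrit = 13, baselineAngleRange = 5,
                          strictMinMin = 30, strictAngleRange = 2,
                          strictWindow = c("08:00", "22:00")) {
  stopifnot(is(es, "EpochSeries"))
  n <- length(es@enmo)
  nonwear <- rep(FALSE, n)
  prov <- rep("", n)

  # baseline rule
  wlen <- baselineWindowMin * EPOCHS_PER_MIN
  step <- baselineStepMin * EPOCHS_PER_MIN
  if (n >= wlen) {
    starts <- seq.int(1L, n - wlen + 1L, by = step)
    for (s in starts) {
      idx <- s:(s + wlen - 1L)
      e <- es@enmo[idx]
      if (anyNA(e)) next
      if (stats::sd(e) < baselineSdCrit &&
          diff(range(es@zangle[idx])) < baselineAngleRange) {
        nonwear[idx] <- TRUE
        prov[idx] <- "baseline"
      }
    }
  }

  # strict rule
  iStart <- slidingRangeStarts(es@zangle, strictAngleRange)
  maximalEnd <- c(iStart[-1] > iStart[-n], TRUE)
  clock <- epochClockSec(es)
  w0 <- clockToSec(strictWindow[1]); w1 <- clockToSec(strictWindow[2])
  inWindow <- clock >= w0 & clock < w1
  minEp <- strictMinMin * EPOCHS_PER_MIN
  for (j in which(maximalEnd)) {
    a <- iStart[j]
    if (j - a + 1L < minEp) next
    idx <- a:j
    portions <- trueRuns(inWindow[idx])
    for (r in seq_len(nrow(portions))) {
      if (portions$end[r] - portions$start[r] + 1L >= minEp) {
        sel <- idx[portions$start[r]:portions$end[r]]
        nonwear[sel] <- TRUE
        prov[sel] <- "strict"
      }
    }
  }

  off <- is.na(es@enmo)
  nonwear[off] <- TRUE
  prov[off] <- "off"
  new("WearMask", wear = !nonwear, provenance = prov)
}

#' Apply a wear mask to an epoch series
#'
#' @param es an [EpochSeries-class].
#' @param mask a [WearMask-class] of the same length.
#' @return The series with wear flags and provenance codes set.
#' @export
applyWearMask <- function(es, mask) {
  stopifnot(length(mask@wear) == length(es@enmo))
  es@wear <- mask@wear
  es@provenance <- mask@provenance
  es
}

# wear-equivalent epochs: worn, or reported-sport substituted
effectiveWear <- function(es) es@wear | es@provenance == "sport"

#' Non-wear intervals of a mask
#'
#' @param mask a [WearMask-class] (or `EpochSeries`).
#' @return data.frame with epoch indices `start`, `end` of each maximal
#'   non-wear run.
#' @export
nonwearIntervals <- function(mask) {
  trueRuns(!wearFlag(mask))
}

#' Substitute reported sport removals
#'
#' When a participant reports removing the device for a known sporting
#' activity, the report is verified against detected non-wear; only the
#' overlap is replaced, using the mean intensity trajectory of the same
#' sport observed in other participants (donor profiles, band minutes per
#' 30-min slot from the start of the activity). Substituted epochs are
#' flagged imputed with provenance "sport" and count as worn downstream.
#'
#' @param es an [EpochSeries-class] with wear flags set.
#' @param reports data.frame with columns `start`, `end` (clock times) and
#'   `sport`.
#' @param donors data.frame with columns `sport`, `slotOffsetMin` (0, 30,
#'   ...), and minutes `sb`, `lpa`, `mpa`, `vpa` per 30-min slot.
#' @param cuts intensity cut-points.
#' @return The modified series.
#' @export
#' @examples
#' donors <- data.frame(sport = "football", slotOffsetMin = c(0, 30),
#'                      sb = c(5, 5), lpa = c(10, 10), mpa = c(10, 10),
#'                      vpa = c(5, 5))
substituteReportedSport <- function(es, reports, donors,
                                    cuts = intensityCutPoints()) {
  stopifnot(is(es, "EpochSeries"))
  if (!nrow(reports)) return(es)
  rep6 <- bandRepresentativeEnmo(cuts)
  t0 <- as.numeric(es@start)
  for (i in seq_len(nrow(reports))) {
    sport <- reports$sport[i]
    prof <- donors[donors$sport == sport, , drop = FALSE]
    if (!nrow(prof)) {
      warning(sprintf("no donor profile for sport '%s'; no substitution",
                      sport))
      next
    }
    s <- as.numeric(asClock(reports$start[i])) - t0
    e <- as.numeric(asClock(reports$end[i])) - t0
    idx <- seq.int(max(1L, floor(s / EPOCH_SECONDS) + 1L),
                   min(length(es@enmo), ceiling(e / EPOCH_SECONDS)))
    overlap <- idx[!es@wear[idx] & !es@imputed[idx] &
                     es@provenance[idx] %in% c("baseline", "strict")]
    if (!length(overlap)) next
    slotOf <- pmin(floor(((overlap - 1L) * EPOCH_SECONDS - s) / 1800),
                   max(prof$slotOffsetMin) %/% 30)
    for (sl in unique(slotOf)) {
      row <- prof[which.min(abs(prof$slotOffsetMin %/% 30 - sl)), ]
      gap <- overlap[slotOf == sl]
      counts <- apportion(length(gap),
                          c(row$sb, row$lpa, row$mpa, row$vpa))
      bands <- rep(BAND_LEVELS, counts)
      es@enmo[gap] <- rep6[bands]
      es@imputed[gap] <- TRUE
      es@provenance[gap] <- "sport"
    }
  }
  es
}

#' Impute residual non-wear by day-type clock intervals
#'
#' For every analysis-valid day, each 30-min clock slot containing non-wear
#' is filled, in intensity-minute space, with the participant's mean band
#' composition over the same clock slot on their other valid days of the
#' same day type; if no such day exists, the mean over all the participant's
#' valid days is used (weekly fallback). Imputed epochs carry representative
#' in-band ENMO values so that intensity classification reproduces the
#' donor composition; they are flagged imputed and keep counting as non-wear
#' for validity accounting. Slots with no donor data anywhere are left as
#' non-wear with a warning.
#'
#' @param es an [EpochSeries-class] with wear flags set.
#' @param days a [dayRecords()] data.frame for this participant (validity
#'   verdicts and day types already assigned).
#' @param slotMin imputation slot width in minutes.
#' @param cuts intensity cut-points.
#' @return The imputed series.
#' @export
imputeNonwear <- function(es, days, slotMin = 30,
                          cuts = intensityCutPoints()) {
  stopifnot(is(es, "EpochSeries"))
  rep6 <- bandRepresentativeEnmo(cuts)
  dates <- epochDates(es)
  clock <- epochClockSec(es)
  slot <- floor(clock / (slotMin * 60))
  band <- classifyIntensity(es@enmo, cuts)
  eff <- effectiveWear(es) & !is.na(es@enmo)
  countable <- eff | es@imputed
  validDays <- days$date[days$valid]
  nMissed <- 0L
  for (d in validDays) {
    type <- days$dayType[days$date == d]
    donorsSame <- setdiff(days$date[days$valid & days$dayType == type], d)
    donorsAll <- setdiff(validDays, d)
    dayIdx <- which(dates == d)
    gaps <- dayIdx[!countable[dayIdx]]
    if (!length(gaps)) next
    for (sl in unique(slot[gaps])) {
      gap <- gaps[slot[gaps] == sl]
      frac <- slotComposition(band, countable, dates, slot, donorsSame, sl)
      if (is.null(frac))
        frac <- slotComposition(band, countable, dates, slot, donorsAll, sl)
      if (is.null(frac)) { nMissed <- nMissed + 1L; next }
      counts <- apportion(length(gap), frac)
      bands <- rep(BAND_LEVELS, counts)
      es@enmo[gap] <- rep6[bands]
      es@imputed[gap] <- TRUE
      es@provenance[gap] <- "imputed"
    }
  }
  if (nMissed > 0L)
    warning(sprintf("%d slot(s) had no donor data and were left as non-wear",
                    nMissed))
  es
}

# mean band composition (SB, LPA, MPA, VPA fractions) of one clock slot over
# donor days; NULL when no donor day has usable epochs in the slot
slotComposition <- function(band, countable, dates, slot, donorDates, sl) {
  fracs <- NULL
  for (d in donorDates) {
    idx <- which(dates == d & slot == sl & countable)
    if (!length(idx)) next
    counts <- tabulate(band[idx], nbins = 4L)
    fracs <- rbind(fracs, counts / sum(counts))
  }
  if (is.null(fracs)) return(NULL)
  colMeans(fracs)
}
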