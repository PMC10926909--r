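#' @include AllClasses.R utils.R cutpoints.R wear.R
NULL

#' Day and school-time validity rules
#'
#' A calendar day is valid when the device was recording for at least 20 of
#' its 24 hours and accumulated no more than 2 hours of non-wear between
#' 8:00 and 22:00. School time (9:00-14:00) is valid when at least 4 hours
#' were recorded with no more than 1 hour of non-wear during school hours.
#' A PE class is valid when it accumulated less than 1 minute of non-wear
#' and (under the default conjunctive reading) either at least 3 minutes of
#' MVPA or no more than 30 minutes of sedentary behaviour; with
#' `rule = "disjunction"` the three clauses are a pure disjunction.
#'
#' @param recordedHours hours the device recorded over the day.
#' @param nonwearWindowMin non-wear minutes accumulated 8:00-22:00.
#' @return Logical verdict.
#' @export
#' @examples
#' validateDay(24, 60)    # TRUE
#' validateDay(24, 121)   # FALSE
#' validateDay(19.9, 0)   # FALSE
validateDay <- function(recordedHours, nonwearWindowMin) {
  recordedHours >= 20 & nonwearWindowMin <= 120
}

#' @rdname validateDay
#' @param schoolRecordedHours hours recorded during school hours.
#' @param schoolNonwearMin non-wear minutes during school hours.
#' @export
#' @examples
#' validateSchoolTime(5, 10)   # TRUE
#' validateSchoolTime(3.5, 0)  # FALSE
validateSchoolTime <- function(schoolRecordedHours, schoolNonwearMin) {
  schoolRecordedHours >= 4 & schoolNonwearMin <= 60
}

#' @rdname validateDay
#' @param peNonwearMin,peMvpaMin,peSbMin non-wear, MVPA and sedentary
#'   minutes inside the scheduled PE interval.
#' @param rule `"conjunction"` (non-wear AND (MVPA OR sedentary)) or
#'   `"disjunction"`.
#' @export
#' @examples
#' validatePeClass(0, 20, 40)  # TRUE
#' validatePeClass(2, 20, 40)  # FALSE under the conjunctive reading
validatePeClass <- function(peNonwearMin, peMvpaMin, peSbMin,
                            rule = c("conjunction", "disjunction")) {
  rule <- match.arg(rule)
  a <- peNonwearMin < 1
  b <- peMvpaMin >= 3
  c_ <- peSbMin <= 30
  if (rule == "conjunction") a & (b | c_) else a | b | c_
}

#' Classify the analysis day type
#'
#' Saturdays and Sundays are weekend days; holidays and school-absence days
#' are excluded from analysis; school days are split into days with and
#' without a valid PE class. A valid school day requires valid school time.
#'
#' @param weekday integer weekday (1 = Monday).
#' @param isHoliday,isAbsence logical calendar exclusions.
#' @param peScheduled logical; a PE class was scheduled that day.
#' @param validPE logical PE-class verdict.
#' @return One of `"schoolPE"`, `"schoolNoPE"`, `"weekend"`, `"holiday"`,
#'   `"absence"`.
#' @export
#' @examples
#' classifyDayType(2, FALSE, FALSE, TRUE, TRUE)  # schoolPE
#' classifyDayType(6, FALSE, FALSE, FALSE, NA)   # weekend
classifyDayType <- function(weekday, isHoliday, isAbsence,
                            peScheduled = FALSE, validPE = FALSE) {
  ifelse(isHoliday, "holiday",
         ifelse(isAbsence, "absence",
                ifelse(weekday >= 6, "weekend",
                       ifelse(peScheduled & !is.na(validPE) & validPE,
                              "schoolPE", "schoolNoPE"))))
}

#' Per-day records for one participant
#'
#' Assembles one row per calendar day of the series: recording and non-wear
#' accounting, school-time and PE-class accounting, validity verdicts, day
#' type, and minutes per intensity band (counting worn, substituted and
#' imputed epochs). Reported-sport substituted epochs count as worn for the
#' validity accounting; generically imputed epochs do not.
#'
#' @param es an [EpochSeries-class] (wear flags set).
#' @param schedule a [schoolSchedule()].
#' @param participant id used to look up absences in the schedule.
#' @param peRule PE validity rule (see [validatePeClass()]).
#' @param cuts intensity cut-points.
#' @return data.frame, one row per day.
#' @export
#' @examples
#' truth <- data.frame(date = as.Date("2019-11-04") + 0:7,
#'                     dayType = c("schoolNoPE", "schoolPE", "schoolNoPE",
#'                                 "schoolPE", "schoolNoPE", "weekend",
#'                                 "weekend", "schoolNoPE"),
#'                     lpa = 200, mpa = 70, vpa = 15)
#' es <- generateEpochSeries(truth, schoolSchedule(), seed = 1)
#' es <- applyWearMask(es, detectNonwear(es))
#' dayRecords(es, schoolSchedule())[, c("date", "dayType", "valid")]
dayRecords <- function(es, schedule = schoolSchedule(),
                       participant = es@participant,
                       peRule = c("conjunction", "disjunction"),
                       cuts = intensityCutPoints()) {
  peRule <- match.arg(peRule)
  stopifnot(is(es, "EpochSeries"))
  dates <- epochDates(es)
  clock <- epochClockSec(es)
  eff <- effectiveWear(es)
  recording <- !is.na(es@enmo)
  inWindow <- clock >= 8 * 3600 & clock < 22 * 3600
  inSchool <- clock >= schedule$schoolStart & clock < schedule$schoolEnd
  inPe <- clock >= schedule$peStart & clock < schedule$peEnd
  band <- classifyIntensity(es@enmo, cuts)
  counted <- (es@wear | es@imputed) & recording
  absDates <- schedule$absences[[participant]]
  if (is.null(absDates)) absDates <- as.Date(character())

  rows <- lapply(split(seq_along(dates), dates), function(i) {
    d <- dates[i[1]]
    wd <- weekdayIndex(d)
    isHoliday <- d %in% schedule$holidays
    isAbsence <- d %in% as.Date(absDates)
    recHours <- sum(recording[i]) / (12 * 60)
    nwWin <- sum(!eff[i] & inWindow[i]) / EPOCHS_PER_MIN
    vDay <- validateDay(recHours, nwWin)
    isSchoolDay <- wd <= 5 & !isHoliday & !isAbsence
    if (isSchoolDay) {
      si <- i[inSchool[i]]
      schRec <- sum(recording[si]) / (12 * 60)
      schNw <- sum(!eff[si]) / EPOCHS_PER_MIN
      vSchool <- validateSchoolTime(schRec, schNw)
    } else {
      schRec <- NA_real_; schNw <- NA_real_; vSchool <- NA
    }
    peScheduled <- isSchoolDay && wd %in% schedule$peWeekdays
    if (peScheduled) {
      pi_ <- i[inPe[i]]
      peNw <- sum(!eff[pi_]) / EPOCHS_PER_MIN
      peMvpa <- sum(band[pi_] %in% c("MPA", "VPA") & counted[pi_]) /
        EPOCHS_PER_MIN
      peSb <- sum(band[pi_] %in% "SB" & counted[pi_]) / EPOCHS_PER_MIN
      vPe <- validatePeClass(peNw, peMvpa, peSb, peRule)
    } else {
      peNw <- NA_real_; peMvpa <- NA_real_; peSb <- NA_real_; vPe <- NA
    }
    type <- classifyDayType(wd, isHoliday, isAbsence, peScheduled, vPe)
    valid <- !isHoliday && !isAbsence && isTRUE(vDay) &&
      (wd >= 6 || isTRUE(vSchool))
    cnt <- tabulate(band[i][counted[i]], nbins = 4L) / EPOCHS_PER_MIN
    data.frame(id = participant, date = d, weekday = WEEKDAY_NAMES[wd],
               dayType = type, recordedHours = recHours,
               nonwearWindowMin = nwWin, schoolRecordedHours = schRec,
               schoolNonwearMin = schNw, peNonwearMin = peNw,
               peMvpaMin = peMvpa, peSbMin = peSb,
               validDay = vDay, validSchoolTime = vSchool, validPE = vPe,
               valid = valid,
               sb = cnt[1], lpa = cnt[2], mpa = cnt[3], vpa = cnt[4],
               mvpa = cnt[3] + cnt[4], lmvpa = cnt[2] + cnt[3] + cnt[4],
               nonwear = sum(!counted[i]) / EPOCHS_PER_MIN)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

BANDS6 <- c("sb", "lpa", "mpa", "vpa", "mvpa", "lmvpa")

# duplicate-weekday averaging, then mean over the distinct weekdays
weekdayAveragedMean <- function(days, cols) {
  if (!nrow(days)) return(stats::setNames(rep(NA_real_, length(cols)), cols))
  perWd <- lapply(split(days[cols], days$weekday), colMeans)
  colMeans(do.call(rbind, perWd))
}

#' Weekly weighted summary for one participant
#'
#' Valid days only. Duplicate weekdays (e.g. two Mondays) are averaged
#' first; the school-day mean (over up to five distinct weekdays) and the
#' weekend mean (up to two) are then combined with weights 5/7 and 2/7. The
#' assessment is valid with at least four distinct valid weekdays, of which
#' at least two school days and at least one weekend day; without any valid
#' weekend (or school) day the weighted mean is undefined (NA).
#'
#' @param days a [dayRecords()] data.frame for one participant.
#' @return One-row data.frame: per-band weekly weighted means
#'   (`sbWeekly`...`lmvpaWeekly`), per-day-type means
#'   (`*SchoolPE`, `*SchoolNoPE`, `*Weekend`), valid-day counts and the
#'   `validAssessment` flag.
#' @export
#' @examples
#' wk <- data.frame(id = "P1", date = as.Date("2019-11-04") + 0:6,
#'   weekday = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
#'   dayType = c(rep("schoolNoPE", 5), "weekend", "weekend"),
#'   valid = TRUE, sb = 900, lpa = 200, mpa = 60, vpa = 20, mvpa = 80,
#'   lmvpa = 280)
#' weeklySummary(wk)$mvpaWeekly  # 80
weeklySummary <- function(days) {
  v <- days[days$valid, , drop = FALSE]
  school <- v[v$dayType %in% c("schoolPE", "schoolNoPE"), , drop = FALSE]
  weekend <- v[v$dayType == "weekend", , drop = FALSE]
  schoolMean <- weekdayAveragedMean(school, BANDS6)
  weekendMean <- weekdayAveragedMean(weekend, BANDS6)
  weekly <- 5 / 7 * schoolMean + 2 / 7 * weekendMean
  out <- data.frame(id = if (nrow(days)) days$id[1] else NA_character_)
  for (b in BANDS6) out[[paste0(b, "Weekly")]] <- weekly[[b]]
  for (ty in c("schoolPE", "schoolNoPE", "weekend")) {
    m <- weekdayAveragedMean(v[v$dayType == ty, , drop = FALSE], BANDS6)
    suf <- c(schoolPE = "SchoolPE", schoolNoPE = "SchoolNoPE",
             weekend = "Weekend")[[ty]]
    for (b in BANDS6) out[[paste0(b, suf)]] <- m[[b]]
  }
  nDistinct <- length(unique(v$weekday))
  nSchool <- length(unique(school$weekday))
  nWeekend <- length(unique(weekend$weekday))
  out$validDays <- nrow(v)
  out$validWeekdays <- nDistinct
  out$validSchoolDays <- nrow(school)
  out$validWeekendDays <- nrow(weekend)
  out$validAssessment <- nDistinct >= 4 && nSchool >= 2 && nWeekend >= 1
  out
}
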