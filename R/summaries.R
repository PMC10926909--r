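#' @include AllClasses.R day-typing.R
NULL

#' Anthropometry derived variables
#'
#' BMI (kg/m^2), waist-to-height ratio (waist cm / height cm) and the
#' central-obesity flag (WHtR greater than or equal to 0.5, boundary
#' inclusive).
#'
#' @param waist waist circumference in cm.
#' @param weight body weight in kg.
#' @param height height in cm.
#' @return data.frame with `bmi`, `whtr`, `centralObesity`.
#' @export
#' @examples
#' computeAnthropometry(65, 32.2, 130)   # WHtR 0.5 -> centrally obese
#' computeAnthropometry(60.7, 32.2, 130.9)
computeAnthropometry <- function(waist, weight, height) {
  if (any(c(waist, weight, height) <= 0, na.rm = TRUE))
    stop("waist, weight and height must all be positive")
  whtr <- waist / height
  data.frame(bmi = weight / (height / 100)^2, whtr = whtr,
             centralObesity = whtr >= 0.5)
}

#' Summarize one participant
#'
#' Combines the weekly weighted summary, per-day-type means over the
#' participant's valid days, and anthropometry into one row. Participants
#' with an invalid assessment are excluded (NULL, with a message giving the
#' reason).
#'
#' @param days a [dayRecords()] data.frame for one participant.
#' @param anthropometry one-row data.frame with `sex`, `age`, `waist`,
#'   `weight`, `height` (and optionally `parentalEducation`,
#'   `schoolStatus`).
#' @return One-row data.frame, or NULL for an invalid assessment.
#' @export
summarizeParticipant <- function(days, anthropometry) {
  wk <- weeklySummary(days)
  if (!wk$validAssessment) {
    message(sprintf(
      "participant %s excluded: %d valid days (%d school, %d weekend)",
      wk$id, wk$validDays, wk$validSchoolDays, wk$validWeekendDays))
    return(NULL)
  }
  extra <- anthropometry[setdiff(names(anthropometry), "id")]
  out <- cbind(wk, extra)
  if (all(c("waist", "weight", "height") %in% names(anthropometry)))
    out <- cbind(out, computeAnthropometry(anthropometry$waist,
                                           anthropometry$weight,
                                           anthropometry$height))
  out
}

#' Summarize a cohort of epoch recordings
#'
#' Runs the per-participant pipeline tail (day records are supplied already
#' imputed) and stacks the valid participant summaries.
#'
#' @param dayList named list: participant id -> [dayRecords()] data.frame.
#' @param participants data.frame of per-child metadata (row per id).
#' @return data.frame with one row per assessment-valid participant.
#' @export
summarizeCohort <- function(dayList, participants) {
  rows <- lapply(names(dayList), function(id) {
    meta <- participants[participants$id == id, , drop = FALSE]
    summarizeParticipant(dayList[[id]], meta)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}
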