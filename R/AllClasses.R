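#' @import methods
NULL

EPOCH_SECONDS <- 5L
EPOCHS_PER_MIN <- 12L
EPOCHS_PER_DAY <- 17280L

#' Cohort simulation specification
#'
#' Parameters of the synthetic cohort generator: cohort size and sex ratio,
#' protocol length, the per-sex per-day-type activity targets (mean and SD of
#' daily minutes in each intensity band), the logistic link between weekly
#' activity and central obesity, non-wear episode rates, anthropometry targets
#' and the seed. Construct with [cohortSpec()].
#'
#' @slot nChildren number of children.
#' @slot sexRatio proportion of boys.
#' @slot nDays protocol length in consecutive 24-h days.
#' @slot peDaysPerWeek number of school days per week with a physical
#'   education class.
#' @slot activityTable data.frame with columns `sex`, `dayType`, `band`,
#'   `mean`, `sd` (minutes/day).
#' @slot obesityLink list with `intercept` (named per sex), `slopeVPA`,
#'   `slopeMVPA` (per min/day of weekly activity, on the logit scale).
#' @slot nonwearRate expected non-wear episodes per day.
#' @slot nonwearDuration lognormal `meanlog`/`sdlog` of episode minutes.
#' @slot anthro list of anthropometry targets (means, SDs, correlation).
#' @slot fullProtocol logical; when TRUE the protocol-length invariant
#'   (at least 8 days) is enforced.
#' @slot seed integer seed.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nChildren = "integer",
  sexRatio = "numeric",
  nDays = "integer",
  peDaysPerWeek = "integer",
  activityTable = "data.frame",
  obesityLink = "list",
  nonwearRate = "numeric",
  nonwearDuration = "numeric",
  anthro = "list",
  fullProtocol = "logical",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nChildren < 0L) msg <- c(msg, "nChildren must be >= 0")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must be a proportion in [0, 1]")
  if (object@fullProtocol && object@nDays < 8L)
    msg <- c(msg, "nDays must be >= 8 for the full wear protocol")
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (object@peDaysPerWeek < 0L || object@peDaysPerWeek > 5L)
    msg <- c(msg, "peDaysPerWeek must be in 0..5")
  at <- object@activityTable
  need <- c("sex", "dayType", "band", "mean", "sd")
  if (!all(need %in% names(at))) {
    msg <- c(msg, sprintf("activityTable must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (any(at$mean < 0) || any(at$sd < 0))
      msg <- c(msg, "activityTable means and SDs must be nonnegative")
  }
  if (object@nonwearRate < 0) msg <- c(msg, "nonwearRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raw triaxial accelerometer recording
#'
#' One participant-device session of raw acceleration samples in g on a
#' nominally regular grid. Construct with [rawRecording()] or simulate with
#' [generateRawRecording()].
#'
#' @slot time numeric seconds since `startTime` (strictly increasing).
#' @slot acc numeric matrix with columns x, y, z in g.
#' @slot startTime POSIXct start of the recording (naive local clock).
#' @slot sampleRate nominal sampling frequency in Hz.
#' @slot dynamicRange device dynamic range in g (symmetric).
#' @exportClass RawRecording
setClass("RawRecording", representation(
  time = "numeric",
  acc = "matrix",
  startTime = "POSIXct",
  sampleRate = "numeric",
  dynamicRange = "numeric"
))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (ncol(object@acc) != 3L) msg <- c(msg, "acc must have 3 columns (x, y, z)")
  if (nrow(object@acc) != length(object@time))
    msg <- c(msg, "time and acc must have the same length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@acc) && max(abs(object@acc)) > object@dynamicRange + 1e-9)
    msg <- c(msg, "acceleration exceeds the device dynamic range")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Auto-calibration model
#'
#' Per-axis gain and offset mapping raw device units to calibrated g
#' (`calibrated = raw * gain + offset`), with fit diagnostics from the
#' static-window sphere fit. Construct with [autoCalibrate()].
#'
#' @slot gain per-axis multiplicative correction.
#' @slot offset per-axis additive correction in g.
#' @slot nStatic number of static windows used.
#' @slot sphereErrorMg mean post-fit deviation of static vector norms from
#'   1 g, in mg.
#' @slot converged logical convergence flag.
#' @slot flags character diagnostics (e.g. too few static windows).
#' @exportClass CalibrationModel
setClass("CalibrationModel", representation(
  gain = "numeric",
  offset = "numeric",
  nStatic = "integer",
  sphereErrorMg = "numeric",
  converged = "logical",
  flags = "character"
))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (length(object@gain) != 3L || length(object@offset) != 3L)
    msg <- c(msg, "gain and offset must each have length 3")
  if (any(object@gain <= 0.5) || any(object@gain >= 2))
    msg <- c(msg, "gains must lie in (0.5, 2)")
  if (length(msg)) msg else TRUE
})

#' Five-second ENMO epoch series
#'
#' Contiguous 5-s epochs for one participant: ENMO (mg, nonnegative by
#' construction), z-angle (degrees), wear / imputed / clipped flags and a
#' non-wear provenance code. Epochs with `NA` ENMO denote periods where the
#' device was not recording. The grid is gapless: epoch `i` starts
#' `(i - 1) * 5` seconds after `start`.
#'
#' @slot participant participant identifier.
#' @slot start POSIXct start of the first epoch (naive local clock).
#' @slot enmo epoch ENMO in mg (NA where not recording).
#' @slot zangle epoch z-angle in degrees, in \[-90, 90\].
#' @slot wear logical wear flag.
#' @slot imputed logical; TRUE where the epoch value was imputed or
#'   substituted.
#' @slot clipped logical sustained-clipping flag.
#' @slot provenance character per-epoch code: "" (worn), "baseline",
#'   "strict", "sport", "imputed".
#' @exportClass EpochSeries
setClass("EpochSeries", representation(
  participant = "character",
  start = "POSIXct",
  enmo = "numeric",
  zangle = "numeric",
  wear = "logical",
  imputed = "logical",
  clipped = "logical",
  provenance = "character"
))

setValidity("EpochSeries", function(object) {
  msg <- character()
  n <- length(object@enmo)
  lens <- c(length(object@zangle), length(object@wear), length(object@imputed),
            length(object@clipped), length(object@provenance))
  if (any(lens != n)) msg <- c(msg, "all epoch vectors must have equal length")
  if (any(object@enmo < 0, na.rm = TRUE))
    msg <- c(msg, "epoch ENMO must be nonnegative")
  za <- object@zangle
  if (any(za < -90 - 1e-9 | za > 90 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "z-angle must lie in [-90, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' Wear mask
#'
#' Per-epoch wear status with a provenance code for every non-wear epoch.
#' Produced by [detectNonwear()]; applied with [applyWearMask()].
#'
#' @slot wear logical wear status per epoch.
#' @slot provenance character: "" for worn epochs, else "baseline" or
#'   "strict" (detector rules) or "sport" (reported-sport substitution).
#' @exportClass WearMask
setClass("WearMask", representation(
  wear = "logical",
  provenance = "character"
))

setValidity("WearMask", function(object) {
  msg <- character()
  if (length(object@wear) != length(object@provenance))
    msg <- c(msg, "wear and provenance must have the same length")
  bad <- !object@wear & !nzchar(object@provenance)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "every non-wear epoch must carry a provenance code")
  if (length(msg)) msg else TRUE
})

#' ROC curve for an activity-obesity association
#'
#' Candidate thresholds (midpoints between consecutive distinct activity
#' values plus infinite sentinels), sensitivity and specificity at each
#' (obesity is the positive class; a child is flagged when activity falls
#' below the threshold), the rank-based AUC with its asymptotic standard
#' error, confidence bounds and p-value. Construct with [rocCurve()].
#'
#' @slot thresholds candidate thresholds (min/day).
#' @slot sensitivity sensitivity at each threshold.
#' @slot specificity specificity at each threshold.
#' @slot auc area under the curve.
#' @slot aucSe asymptotic (DeLong) standard error of the AUC.
#' @slot aucCI 95 percent confidence bounds.
#' @slot p two-sided p-value against AUC = 0.5.
#' @slot nPos number of obese (positive) children.
#' @slot nNeg number of non-obese children.
#' @exportClass RocCurve
setClass("RocCurve", representation(
  thresholds = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  auc = "numeric",
  aucSe = "numeric",
  aucCI = "numeric",
  p = "numeric",
  nPos = "integer",
  nNeg = "integer"
))

setValidity("RocCurve", function(object) {
  msg <- character()
  k <- length(object@thresholds)
  if (length(object@sensitivity) != k || length(object@specificity) != k)
    msg <- c(msg, "thresholds, sensitivity and specificity lengths must match")
  if (is.unsorted(object@sensitivity))
    msg <- c(msg, "sensitivity must be nondecreasing in the threshold")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Set of physical activity recommendations
#'
#' Named daily-average thresholds (min/day), possibly sex-specific, each with
#' a provenance ("fixed" or "roc"). Construct with [recommendationSet()] or
#' derive from a cohort with [deriveRecommendations()].
#'
#' @slot entries data.frame with columns `name`, `band`, `male`, `female`,
#'   `pooled`, `provenance`.
#' @slot granularity rounding granularity (min) used for ROC-derived entries.
#' @exportClass RecommendationSet
setClass("RecommendationSet", representation(
  entries = "data.frame",
  granularity = "numeric"
))

setValidity("RecommendationSet", function(object) {
  msg <- character()
  need <- c("name", "band", "male", "female", "pooled", "provenance")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, sprintf("entries must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    th <- unlist(object@entries[c("male", "female", "pooled")])
    if (any(th <= 0, na.rm = TRUE)) msg <- c(msg, "thresholds must be > 0")
  }
  if (length(msg)) msg else TRUE
})
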