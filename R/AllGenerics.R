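#' @include AllClasses.R
NULL

#' Epoch-series accessors
#'
#' Accessor generics for [EpochSeries-class] objects: ENMO values (mg),
#' z-angle (degrees), wear / imputed / clipped flags, provenance codes,
#' epoch start times and the epoch count.
#'
#' @param x an `EpochSeries`.
#' @return A vector of per-epoch values (`epochTimes` returns POSIXct,
#'   `nEpochs` a single integer).
#' @name epoch-accessors
#' @aliases enmo zAngle wearFlag imputedFlag clippedFlag provenance
#'   epochTimes nEpochs
#' @examples
#' es <- generateEpochSeries(
#'   data.frame(date = as.Date("2019-11-04"), dayType = "schoolNoPE",
#'              lpa = 200, mpa = 60, vpa = 10),
#'   schoolSchedule(), participant = "P1", seed = 1)
#' nEpochs(es)
#' head(enmo(es))
NULL

#' @rdname epoch-accessors
#' @export
setGeneric("enmo", function(x) standardGeneric("enmo"))
#' @rdname epoch-accessors
#' @export
setGeneric("zAngle", function(x) standardGeneric("zAngle"))
#' @rdname epoch-accessors
#' @export
setGeneric("wearFlag", function(x) standardGeneric("wearFlag"))
#' @rdname epoch-accessors
#' @export
setGeneric("imputedFlag", function(x) standardGeneric("imputedFlag"))
#' @rdname epoch-accessors
#' @export
setGeneric("clippedFlag", function(x) standardGeneric("clippedFlag"))
#' @rdname epoch-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname epoch-accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname epoch-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname epoch-accessors
#' @export
setMethod("enmo", "EpochSeries", function(x) x@enmo)
#' @rdname epoch-accessors
#' @export
setMethod("zAngle", "EpochSeries", function(x) x@zangle)
#' @rdname epoch-accessors
#' @export
setMethod("wearFlag", "EpochSeries", function(x) x@wear)
#' @rdname epoch-accessors
#' @export
setMethod("imputedFlag", "EpochSeries", function(x) x@imputed)
#' @rdname epoch-accessors
#' @export
setMethod("clippedFlag", "EpochSeries", function(x) x@clipped)
#' @rdname epoch-accessors
#' @export
setMethod("provenance", "EpochSeries", function(x) x@provenance)
#' @rdname epoch-accessors
#' @export
setMethod("epochTimes", "EpochSeries",
          function(x) x@start + (seq_along(x@enmo) - 1L) * EPOCH_SECONDS)
#' @rdname epoch-accessors
#' @export
setMethod("nEpochs", "EpochSeries", function(x) length(x@enmo))

#' @rdname epoch-accessors
#' @export
setMethod("wearFlag", "WearMask", function(x) x@wear)
#' @rdname epoch-accessors
#' @export
setMethod("provenance", "WearMask", function(x) x@provenance)

#' Area under the ROC curve
#'
#' @param x a [RocCurve-class].
#' @return The rank-based AUC (a single number).
#' @export
#' @examples
#' rc <- rocCurve(c(5, 8, 10, 12), c(1, 1, 0, 0))
#' auc(rc)
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname auc
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' Recommendation-set entries
#'
#' @param x a [RecommendationSet-class].
#' @return data.frame of entries (name, band, per-sex and pooled thresholds
#'   in min/day, provenance).
#' @export
#' @examples
#' recommendationEntries(recommendationSet())
setGeneric("recommendationEntries",
           function(x) standardGeneric("recommendationEntries"))

#' @rdname recommendationEntries
#' @export
setMethod("recommendationEntries", "RecommendationSet", function(x) x@entries)

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@enmo)
  cat(sprintf("EpochSeries '%s': %d epochs of %ds (%.2f days) from %s\n",
              object@participant, n, EPOCH_SECONDS, n / EPOCHS_PER_DAY,
              format(object@start, "%Y-%m-%d %H:%M:%S")))
  cat(sprintf("  wear %.1f%% | imputed %.1f%% | recording %.1f%%\n",
              100 * mean(object@wear), 100 * mean(object@imputed),
              100 * mean(!is.na(object@enmo))))
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d samples at %g Hz (%.2f h), +/-%g g, from %s\n",
              nrow(object@acc), object@sampleRate,
              length(object@time) / object@sampleRate / 3600,
              object@dynamicRange, format(object@startTime)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel\n")
  cat(sprintf("  gain   : %s\n", paste(sprintf("%.5f", object@gain), collapse = " ")))
  cat(sprintf("  offset : %s g\n", paste(sprintf("%+.5f", object@offset), collapse = " ")))
  cat(sprintf("  %d static windows, sphere error %.2f mg, converged: %s\n",
              object@nStatic, object@sphereErrorMg, object@converged))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d obese vs %d non-obese, AUC %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
              object@nPos, object@nNeg, object@auc,
              object@aucCI[1], object@aucCI[2], object@p))
})

setMethod("show", "RecommendationSet", function(object) {
  cat("RecommendationSet (min/day):\n")
  print(object@entries, row.names = FALSE)
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d children (%.0f%% boys), %d days, %d PE days/week, seed %d\n",
              object@nChildren, 100 * object@sexRatio, object@nDays,
              object@peDaysPerWeek, object@seed))
})
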