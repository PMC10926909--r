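#' @include AllClasses.R
NULL

#' ROC curve for low activity predicting central obesity
#'
#' Obesity is the positive class and a child is flagged positive when their
#' average daily activity falls below a candidate threshold. Candidate
#' thresholds are the midpoints between consecutive distinct activity
#' values, plus infinite sentinels; sensitivity is P(activity < t | obese)
#' and specificity P(activity >= t | non-obese). The AUC is computed by the
#' rank (Mann-Whitney) formulation with midrank ties, its standard error by
#' the asymptotic placement-value (DeLong) variance, and the p-value is a
#' two-sided normal test against AUC = 0.5.
#'
#' @param activity numeric vector of average daily minutes per child.
#' @param obese logical (or 0/1) central-obesity flags.
#' @return A [RocCurve-class].
#' @export
#' @examples
#' rocCurve(c(5, 8, 10, 12), c(TRUE, TRUE, FALSE, FALSE))  # AUC 1
rocCurve <- function(activity, obese) {
  obese <- as.logical(obese)
  stopifnot(length(activity) == length(obese), !anyNA(activity),
            !anyNA(obese))
  n1 <- sum(obese); n0 <- sum(!obese)
  if (n1 == 0L || n0 == 0L)
    stop(sprintf("both classes must be present (obese: %d, non-obese: %d)",
                 n1, n0))
  s <- sort(unique(activity))
  thr <- if (length(s) > 1)
    c(-Inf, (s[-length(s)] + s[-1]) / 2, Inf) else c(-Inf, Inf)
  sens <- vapply(thr, function(t) mean(activity[obese] < t), numeric(1))
  spec <- vapply(thr, function(t) mean(activity[!obese] >= t), numeric(1))

  # AUC = P(activity_nonobese > activity_obese) + 0.5 P(tie), via midranks
  r <- rank(activity)
  aucHat <- (sum(r[!obese]) - n0 * (n0 + 1) / 2) / (n0 * n1)
  # placement values for the asymptotic variance
  x1 <- activity[obese]; x0 <- activity[!obese]
  v10 <- vapply(x1, function(xi)
    (sum(x0 > xi) + 0.5 * sum(x0 == xi)) / n0, numeric(1))
  v01 <- vapply(x0, function(xj)
    (sum(x1 < xj) + 0.5 * sum(x1 == xj)) / n1, numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  if (!is.finite(se)) se <- NA_real_
  z <- (aucHat - 0.5) / se
  p <- if (is.na(se) || se == 0) NA_real_ else 2 * stats::pnorm(-abs(z))
  ci <- pmin(1, pmax(0, aucHat + c(-1, 1) * 1.96 * se))
  new("RocCurve", thresholds = thr, sensitivity = sens, specificity = spec,
      auc = aucHat, aucSe = se, aucCI = ci, p = p,
      nPos = as.integer(n1), nNeg = as.integer(n0))
}

#' Youden-optimal threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's candidate
#' thresholds; ties are broken toward the higher threshold (higher
#' sensitivity). The reported threshold is rounded down to the configured
#' granularity (default half a minute).
#'
#' @param curve a [RocCurve-class].
#' @param granularity rounding granularity in minutes (0 disables
#'   rounding).
#' @return list with `threshold` (rounded), `raw` (unrounded maximizer),
#'   `J`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' yt <- youdenThreshold(rocCurve(c(5, 8, 10, 12), c(1, 1, 0, 0)))
#' yt$raw  # 9 (midpoint), J = 1
youdenThreshold <- function(curve, granularity = 0.5) {
  stopifnot(is(curve, "RocCurve"), length(curve@thresholds) > 0)
  J <- curve@sensitivity + curve@specificity - 1
  best <- max(J)
  i <- max(which(J >= best - 1e-12))
  raw <- curve@thresholds[i]
  th <- if (granularity > 0 && is.finite(raw))
    floor(raw / granularity) * granularity else raw
  list(threshold = th, raw = raw, J = J[i],
       sensitivity = curve@sensitivity[i], specificity = curve@specificity[i])
}

#' Pool sex-specific thresholds
#'
#' When the relative gap between the two sex-specific thresholds is below
#' `poolGap` (5% by default), a common threshold is emitted: the
#' sample-size-weighted mean rounded to the nearest `granularity` minutes
#' (5 by default). Otherwise NA (the thresholds stay sex-specific).
#'
#' @param male,female sex-specific thresholds (min/day).
#' @param nMale,nFemale per-sex sample sizes.
#' @param poolGap maximum relative gap for pooling.
#' @param granularity rounding granularity of the pooled value (min).
#' @return The pooled threshold, or NA.
#' @export
#' @examples
#' poolThresholds(76.4, 73.8, 156, 168)  # 75
poolThresholds <- function(male, female, nMale, nFemale, poolGap = 0.05,
                           granularity = 5) {
  gap <- abs(male - female) / mean(c(male, female))
  if (gap >= poolGap) return(NA_real_)
  w <- c(nMale, nFemale)
  round(sum(w * c(male, female)) / sum(w) / granularity) * granularity
}

#' Construct a recommendation set
#'
#' The two fixed entries are 60 min/day of MVPA (the WHO guideline) and 15
#' min/day of VPA (from earlier literature); ROC-derived entries are added
#' by [deriveRecommendations()].
#'
#' @param entries data.frame of entries; by default the two fixed ones.
#' @param granularity rounding granularity for ROC-derived entries.
#' @return A [RecommendationSet-class].
#' @export
#' @examples
#' recommendationSet()
recommendationSet <- function(entries = NULL, granularity = 0.5) {
  if (is.null(entries))
    entries <- data.frame(
      name = c("RecMVPA-WHO", "RecVPA-15"),
      band = c("mvpa", "vpa"),
      male = NA_real_, female = NA_real_, pooled = c(60, 15),
      provenance = "fixed")
  new("RecommendationSet", entries = entries, granularity = granularity)
}

#' Threshold applying to one child
#'
#' @param recs a [RecommendationSet-class].
#' @param name entry name.
#' @param sex "male" or "female".
#' @return The threshold in min/day (pooled when available, else the
#'   sex-specific value).
#' @export
recommendationThreshold <- function(recs, name, sex) {
  e <- recs@entries[recs@entries$name == name, , drop = FALSE]
  if (!nrow(e)) stop(sprintf("unknown recommendation '%s'", name))
  if (is.na(e$pooled)) {
    unname(ifelse(sex == "male", e$male, e$female))
  } else {
    rep(e$pooled, length(sex))
  }
}

#' Derive ROC-based activity recommendations
#'
#' Runs the ROC / Youden analysis of average daily MVPA and VPA against
#' central obesity separately per sex. VPA thresholds are always
#' sex-specific, rounded down to the nearest half minute. If the
#' sex-specific MVPA thresholds differ by less than 5% relatively, a pooled
#' MVPA threshold is emitted: their sample-size-weighted mean rounded to
#' the nearest 5 minutes (both per-sex values are kept). The fixed entries
#' (60 min MVPA, 15 min VPA) are attached unchanged.
#'
#' @param summaries data.frame with columns `sex`, `mvpaWeekly`,
#'   `vpaWeekly`, `centralObesity` (assessment-valid children only).
#' @param granularity rounding granularity for VPA thresholds (min).
#' @param poolGap maximum relative gap for pooling the MVPA thresholds.
#' @param mvpaGranularity rounding granularity of the pooled MVPA
#'   threshold (min).
#' @return list with `recommendations` (a [RecommendationSet-class]) and
#'   `roc` (per sex and band, the [RocCurve-class] and Youden results).
#' @export
deriveRecommendations <- function(summaries, granularity = 0.5,
                                  poolGap = 0.05, mvpaGranularity = 5) {
  if (!"sex" %in% names(summaries)) stop("missing 'sex' column")
  keep <- !is.na(summaries$centralObesity)
  summaries <- summaries[keep, , drop = FALSE]
  sexes <- intersect(c("male", "female"), unique(summaries$sex))
  roc <- list()
  th <- list()
  nBySex <- list()
  for (s in sexes) {
    d <- summaries[summaries$sex == s, ]
    nBySex[[s]] <- nrow(d)
    for (b in c("mvpa", "vpa")) {
      curve <- rocCurve(d[[paste0(b, "Weekly")]], d$centralObesity)
      y <- youdenThreshold(curve, granularity)
      roc[[paste(s, b, sep = ".")]] <- list(curve = curve, youden = y)
      th[[paste(s, b, sep = ".")]] <- y
    }
  }
  entries <- recommendationEntries(recommendationSet())
  getTh <- function(s, b, what = "threshold")
    if (is.null(th[[paste(s, b, sep = ".")]])) NA_real_ else
      th[[paste(s, b, sep = ".")]][[what]]
  mvpaM <- getTh("male", "mvpa", "raw"); mvpaF <- getTh("female", "mvpa", "raw")
  if (!is.na(mvpaM) && !is.na(mvpaF)) {
    pooled <- poolThresholds(mvpaM, mvpaF, nBySex[["male"]],
                             nBySex[["female"]], poolGap, mvpaGranularity)
  } else {
    pooled <- NA_real_
    message("single-sex cohort: MVPA pooling skipped")
  }
  entries <- rbind(entries, data.frame(
    name = c("RecMVPA", "RecVPA"),
    band = c("mvpa", "vpa"),
    male = c(mvpaM, getTh("male", "vpa")),
    female = c(mvpaF, getTh("female", "vpa")),
    pooled = c(pooled, NA_real_),
    provenance = "roc"))
  list(recommendations = new("RecommendationSet", entries = entries,
                             granularity = granularity),
       roc = roc)
}
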