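#' @include AllClasses.R utils.R
NULL

#' Default per-sex, per-day-type activity targets
#'
#' Mean and SD of daily minutes in each intensity band, by sex and day type
#' (school day with PE class, school day without, weekend), calibrated to the
#' reference cohort of 8- and 9-year-old Andalusian schoolchildren. Vigorous
#' and moderate-to-vigorous targets are taken per day type; light activity is
#' held flat across day types at the weekly target. Moderate targets are the
#' MVPA target minus the vigorous target, with SDs combined in quadrature.
#'
#' @return data.frame with columns `sex`, `dayType`, `band`, `mean`, `sd`.
#' @export
#' @examples
#' subset(defaultActivityTable(), band == "VPA")
defaultActivityTable <- function() {
  dt <- c("schoolPE", "schoolNoPE", "weekend")
  vpa <- data.frame(
    sex = rep(c("male", "female"), each = 3), dayType = rep(dt, 2),
    band = "VPA",
    mean = c(28.0, 18.8, 14.3, 16.4, 10.4, 8.0),
    sd = c(14.3, 12.0, 11.7, 7.9, 6.0, 5.6))
  mvpaMean <- c(118.1, 91.6, 85.8, 91.5, 72.6, 66.9)
  mvpaSd <- c(38.4, 35.0, 41.8, 28.8, 24.1, 27.7)
  mpa <- data.frame(
    sex = vpa$sex, dayType = vpa$dayType, band = "MPA",
    mean = mvpaMean - vpa$mean,
    sd = sqrt(pmax(mvpaSd^2 - vpa$sd^2, 25)))
  lpa <- data.frame(
    sex = rep(c("male", "female"), each = 3), dayType = rep(dt, 2),
    band = "LPA",
    mean = rep(c(212.5, 223.6), each = 3),
    sd = rep(c(33.3, 32.7), each = 3))
  rbind(lpa, mpa, vpa)
}

#' Calibrate the obesity-link intercept
#'
#' For a logistic link `logit P(obese) = a + b * VPA` and weekly VPA
#' distributed as a zero-floored normal, the Youden-optimal threshold t*
#' satisfies `a + b t* = logit(prevalence)` (the point where the obese and
#' non-obese densities cross). This solves, by deterministic quadrature and
#' root finding, for the intercept `a` that places t* at a requested value.
#'
#' @param slope logistic slope per min/day of weekly VPA (negative: more
#'   activity, less obesity).
#' @param target desired Youden-optimal threshold (min/day).
#' @param mu,sd mean and SD of the underlying normal for weekly VPA before
#'   flooring at zero.
#' @return The intercept (a single number).
#' @export
#' @examples
#' calibrateObesityLink(-1.5, target = 9.5, mu = 11.4, sd = 5.1)
calibrateObesityLink <- function(slope, target, mu, sd) {
  stopifnot(slope < 0, sd > 0)
  prevalence <- function(a) {
    atZero <- stats::pnorm(0, mu, sd) * stats::plogis(a)
    atZero + stats::integrate(function(x)
      stats::plogis(a + slope * x) * stats::dnorm(x, mu, sd),
      0, mu + 12 * sd, rel.tol = 1e-10)$value
  }
  stats::uniroot(function(a) prevalence(a) - stats::plogis(a + slope * target),
                 interval = c(-60, 60), tol = 1e-10)$root
}

#' Default obesity link
#'
#' Logistic link from weekly vigorous activity to central obesity, with
#' per-sex intercepts calibrated so that the population Youden-optimal
#' thresholds are 12.5 min/day (boys) and 9.5 min/day (girls). The slope is
#' deliberately steep so the thresholds are sharply identified in cohorts of
#' a few hundred children.
#'
#' @param slopeVPA,slopeMVPA logistic slopes per min/day of weekly VPA and
#'   MVPA.
#' @param targets named per-sex Youden-optimal VPA thresholds used to
#'   calibrate the intercepts (only when `slopeMVPA == 0` and
#'   `slopeVPA < 0`; otherwise supply `intercept`).
#' @param intercept optional named per-sex intercepts, overriding
#'   calibration.
#' @return list with `intercept` (named per sex), `slopeVPA`, `slopeMVPA`.
#' @export
#' @examples
#' defaultObesityLink()
defaultObesityLink <- function(slopeVPA = -1.5, slopeMVPA = 0,
                               targets = c(male = 12.5, female = 9.5),
                               intercept = NULL) {
  if (is.null(intercept)) {
    if (slopeMVPA != 0 || slopeVPA >= 0)
      stop("intercepts can only be auto-calibrated for a pure negative ",
           "VPA slope; supply 'intercept'")
    intercept <- c(
      male = calibrateObesityLink(slopeVPA, targets[["male"]], 19.9, 10.5),
      female = calibrateObesityLink(slopeVPA, targets[["female"]], 11.4, 5.1))
  }
  list(intercept = intercept, slopeVPA = slopeVPA, slopeMVPA = slopeMVPA)
}

#' Specify a synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' Defaults emulate the reference study conditions: 360 children (48.9%
#' boys), at least eight consecutive 24-h days, school 9:00-14:00 with a
#' 30-min recess, two PE days per week, activity targets from
#' [defaultActivityTable()] and the calibrated obesity link from
#' [defaultObesityLink()].
#'
#' @param nChildren number of children.
#' @param sexRatio proportion of boys.
#' @param nDays consecutive protocol days (>= 8 unless
#'   `fullProtocol = FALSE`).
#' @param peDaysPerWeek school days per week with a PE class.
#' @param activityTable per-sex per-day-type band targets.
#' @param obesityLink logistic obesity link (see [defaultObesityLink()]).
#' @param nonwearRate expected non-wear episodes per day.
#' @param nonwearDuration lognormal `meanlog`, `sdlog` of episode minutes.
#' @param anthro anthropometry targets: means/SDs of waist (cm), height
#'   (cm), BMI (kg/m^2), waist-height correlation, and age mean/SD.
#' @param fullProtocol enforce the 8-day protocol invariant.
#' @param seed integer seed.
#' @return A validated [CohortSpec-class].
#' @export
#' @examples
#' cohortSpec(nChildren = 10, seed = 3)
cohortSpec <- function(nChildren = 360, sexRatio = 176 / 360, nDays = 8,
                       peDaysPerWeek = 2,
                       activityTable = defaultActivityTable(),
                       obesityLink = defaultObesityLink(),
                       nonwearRate = 0.7,
                       nonwearDuration = c(meanlog = log(45), sdlog = 0.4),
                       anthro = list(waist = c(61.4, 8.9),
                                     height = c(131.4, 6.3),
                                     bmi = c(18.4, 3.7),
                                     waistHeightCor = 0.6,
                                     age = c(8.5, 0.4)),
                       fullProtocol = TRUE, seed = 1) {
  obj <- new("CohortSpec", nChildren = as.integer(nChildren),
             sexRatio = sexRatio, nDays = as.integer(nDays),
             peDaysPerWeek = as.integer(peDaysPerWeek),
             activityTable = activityTable, obesityLink = obesityLink,
             nonwearRate = nonwearRate, nonwearDuration = nonwearDuration,
             anthro = anthro, fullProtocol = fullProtocol,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

# between-child share of the day-type variance: child latent level vs
# day-to-day noise (correlation of two days of the same type ~ 0.81)
CHILD_LEVEL_SHARE <- 0.9

#' Generate a synthetic cohort
#'
#' Draws a cohort at the summary level: per-child latent day-type activity
#' means, realized per-day minutes (zero-floored normal around the latent
#' mean), weekly weighted averages, an obesity label from the logistic
#' activity link, and anthropometry consistent with the label (waist shifted
#' so that WHtR >= 0.5 agrees with the drawn obesity status).
#'
#' The protocol calendar starts on a Monday and covers `nDays` consecutive
#' days; PE classes fall on the first `peDaysPerWeek` school weekdays
#' (Tuesday and Thursday by default order).
#'
#' @param spec a [CohortSpec-class].
#' @param startDate first protocol day (a Monday keeps the default calendar
#'   aligned; any date is accepted).
#' @return list with `participants` (one row per child: sex, age,
#'   anthropometry, central obesity flag, parental education, school
#'   status), `truthDaily` (one row per child-day: date, weekday, dayType
#'   and true minutes of LPA/MPA/VPA), and `truthWeekly` (per child weekly
#'   weighted and per-day-type band means).
#' @export
#' @examples
#' coh <- generateCohort(cohortSpec(nChildren = 6, seed = 2))
#' head(coh$participants)
generateCohort <- function(spec, startDate = as.Date("2019-11-04")) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nChildren
  emptyParts <- data.frame(
    id = character(), sex = character(), age = numeric(),
    waist = numeric(), weight = numeric(), height = numeric(),
    bmi = numeric(), whtr = numeric(), centralObesity = logical(),
    parentalEducation = character(), schoolStatus = character())
  if (n == 0L) {
    return(list(participants = emptyParts,
                truthDaily = data.frame(), truthWeekly = data.frame()))
  }
  ids <- sprintf("C%04d", seq_len(n))
  nBoys <- round(n * spec@sexRatio)
  sex <- c(rep("male", nBoys), rep("female", n - nBoys))

  dates <- startDate + seq_len(spec@nDays) - 1L
  wd <- weekdayIndex(dates)
  peWeekdays <- c(2L, 4L, 1L, 3L, 5L)[seq_len(spec@peDaysPerWeek)]
  dayType <- ifelse(wd >= 6L, "weekend",
                    ifelse(wd %in% peWeekdays, "schoolPE", "schoolNoPE"))

  at <- spec@activityTable
  key <- function(s, d, b) at$mean[at$sex == s & at$dayType == d & at$band == b]
  keySd <- function(s, d, b) at$sd[at$sex == s & at$dayType == d & at$band == b]

  z <- stats::rnorm(n)  # shared child latent level across bands / day types
  daily <- vector("list", n)
  weekly <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- expand.grid(date = dates, band = c("LPA", "MPA", "VPA"),
                        stringsAsFactors = FALSE)
    rows$dayType <- dayType[match(rows$date, dates)]
    mu <- mapply(key, sex[i], rows$dayType, rows$band)
    sdv <- mapply(keySd, sex[i], rows$dayType, rows$band)
    latent <- mu + z[i] * CHILD_LEVEL_SHARE * sdv
    within <- sqrt(1 - CHILD_LEVEL_SHARE^2) * sdv
    val <- pmax(0, stats::rnorm(nrow(rows), latent, within))
    wide <- data.frame(id = ids[i], date = rows$date[rows$band == "LPA"],
                       weekday = WEEKDAY_NAMES[wd],
                       dayType = dayType,
                       lpa = val[rows$band == "LPA"],
                       mpa = val[rows$band == "MPA"],
                       vpa = val[rows$band == "VPA"])
    # keep the day physically possible
    tot <- wide$lpa + wide$mpa + wide$vpa
    over <- tot > 1000
    if (any(over)) {
      f <- 1000 / tot[over]
      wide[over, c("lpa", "mpa", "vpa")] <-
        wide[over, c("lpa", "mpa", "vpa")] * f
    }
    daily[[i]] <- wide
    weekly[[i]] <- weeklyTruthRow(ids[i], sex[i], wide)
  }
  truthDaily <- do.call(rbind, daily)
  truthWeekly <- do.call(rbind, weekly)

  link <- spec@obesityLink
  # short protocols without a weekend leave the weekly weighted mean
  # undefined; the link then falls back to the mean over available days
  fallback <- function(col) {
    v <- truthWeekly[[paste0(col, "Weekly")]]
    miss <- is.na(v)
    if (any(miss)) {
      byChild <- tapply(truthDaily[[col]], truthDaily$id, mean)
      v[miss] <- byChild[truthWeekly$id[miss]]
    }
    v
  }
  vpaLink <- fallback("vpa")
  mvpaLink <- fallback("mpa") + vpaLink
  eta <- link$intercept[sex] + link$slopeVPA * vpaLink +
    link$slopeMVPA * mvpaLink
  obese <- stats::runif(n) < stats::plogis(eta)

  a <- spec@anthro
  height <- stats::rnorm(n, a$height[1], a$height[2])
  rho <- a$waistHeightCor
  waist <- a$waist[1] + rho * a$waist[2] / a$height[2] * (height - a$height[1]) +
    stats::rnorm(n, 0, a$waist[2] * sqrt(1 - rho^2))
  # shift waist so that the central-obesity flag agrees with the drawn label
  whtr <- waist / height
  fix <- obese & whtr < 0.5
  waist[fix] <- height[fix] * (0.5 + abs(stats::rnorm(sum(fix), 0, 0.03)))
  fix <- !obese & whtr >= 0.5
  waist[fix] <- height[fix] * (0.5 - abs(stats::rnorm(sum(fix), 0, 0.02)) -
                                 0.001)
  whtr <- waist / height
  bmi <- pmax(11, stats::rnorm(n, a$bmi[1], a$bmi[2]) +
                ifelse(obese, 1.5, -0.5))
  weight <- bmi * (height / 100)^2
  age <- pmin(9.99, pmax(8, stats::rnorm(n, a$age[1], a$age[2])))

  participants <- data.frame(
    id = ids, sex = sex, age = age, waist = waist, weight = weight,
    height = height, bmi = bmi, whtr = whtr, centralObesity = obese,
    parentalEducation = sample(c("non-university", "university"), n, TRUE,
                               prob = c(0.555, 0.445)),
    schoolStatus = sample(c("public", "private"), n, TRUE,
                          prob = c(0.736, 0.264)))
  list(participants = participants, truthDaily = truthDaily,
       truthWeekly = truthWeekly)
}

weeklyTruthRow <- function(id, sex, wide) {
  mt <- function(type, col) {
    v <- wide[[col]][wide$dayType %in% type]
    if (length(v)) mean(v) else NA_real_
  }
  out <- data.frame(id = id, sex = sex)
  for (col in c("lpa", "mpa", "vpa")) {
    schoolPE <- mt("schoolPE", col)
    schoolNoPE <- mt("schoolNoPE", col)
    school <- mt(c("schoolPE", "schoolNoPE"), col)
    weekend <- mt("weekend", col)
    out[[paste0(col, "SchoolPE")]] <- schoolPE
    out[[paste0(col, "SchoolNoPE")]] <- schoolNoPE
    out[[paste0(col, "Weekend")]] <- weekend
    out[[paste0(col, "Weekly")]] <- 5 / 7 * school + 2 / 7 * weekend
  }
  for (suf in c("SchoolPE", "SchoolNoPE", "Weekend", "Weekly")) {
    out[[paste0("mvpa", suf)]] <-
      out[[paste0("mpa", suf)]] + out[[paste0("vpa", suf)]]
    out[[paste0("lmvpa", suf)]] <-
      out[[paste0("lpa", suf)]] + out[[paste0("mvpa", suf)]]
  }
  out
}
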