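#' @include AllClasses.R utils.R
NULL

#' Published ENMO intensity cut-points
#'
#' Wrist-worn GENEActiv cut-points for children (non-dominant wrist, ENMO in
#' mg): sedentary below 56.3, light from 56.3 to 191.6, moderate from 191.6
#' to 695.8, vigorous above 695.8. Bands are half-open `[lo, hi)`: a value
#' exactly on a boundary is assigned to the upper band.
#'
#' @param sbUpper,lpaUpper,mpaUpper band boundaries in mg.
#' @return A named numeric vector of the three boundaries.
#' @export
#' @examples
#' intensityCutPoints()
intensityCutPoints <- function(sbUpper = 56.3, lpaUpper = 191.6,
                               mpaUpper = 695.8) {
  cuts <- c(sbUpper = sbUpper, lpaUpper = lpaUpper, mpaUpper = mpaUpper)
  if (any(cuts <= 0) || is.unsorted(cuts, strictly = TRUE))
    stop("cut-points must be positive and strictly increasing")
  cuts
}

BAND_LEVELS <- c("SB", "LPA", "MPA", "VPA")

#' Classify epoch intensity
#'
#' Assigns each epoch to an intensity band (SB / LPA / MPA / VPA) by the
#' published cut-points and counts minutes per band and per day. Only worn or
#' imputed epochs contribute to the per-day minutes; minutes are epoch counts
#' divided by 12 (5-s epochs).
#'
#' @param x an [EpochSeries-class] or a numeric vector of epoch ENMO in mg.
#' @param cuts cut-points from [intensityCutPoints()].
#' @return For a numeric vector, a factor of bands. For an `EpochSeries`, a
#'   list with `band` (per-epoch factor, NA where not recording) and
#'   `minutes` (data.frame per day: date, sb, lpa, mpa, vpa, mvpa, lmvpa,
#'   nonwear and recorded minutes).
#' @export
#' @examples
#' classifyIntensity(c(10, 60, 200, 700))
classifyIntensity <- function(x, cuts = intensityCutPoints()) {
  if (is.numeric(x)) {
    if (any(x < 0, na.rm = TRUE)) stop("negative ENMO values are invalid")
    idx <- findInterval(x, cuts) + 1L
    return(factor(BAND_LEVELS[idx], levels = BAND_LEVELS))
  }
  stopifnot(is(x, "EpochSeries"))
  band <- classifyIntensity(x@enmo, cuts)
  counted <- (x@wear | x@imputed) & !is.na(x@enmo)
  band[!counted] <- NA
  dates <- epochDates(x)
  perDay <- lapply(split(seq_along(band), dates), function(i) {
    b <- band[i]
    counts <- table(b)
    recorded <- sum(!is.na(x@enmo[i]))
    data.frame(sb = counts[["SB"]], lpa = counts[["LPA"]],
               mpa = counts[["MPA"]], vpa = counts[["VPA"]],
               nonwear = recorded - sum(counts),
               recorded = recorded) / EPOCHS_PER_MIN
  })
  minutes <- do.call(rbind, perDay)
  minutes$date <- as.Date(names(perDay))
  minutes$mvpa <- minutes$mpa + minutes$vpa
  minutes$lmvpa <- minutes$lpa + minutes$mvpa
  rownames(minutes) <- NULL
  list(band = band,
       minutes = minutes[c("date", "sb", "lpa", "mpa", "vpa", "mvpa",
                           "lmvpa", "nonwear", "recorded")])
}

# representative ENMO value inside each band, used when materializing
# imputed epochs: geometric mid-band for active bands, low value for SB
bandRepresentativeEnmo <- function(cuts = intensityCutPoints()) {
  c(SB = unname(cuts[1]) / 3,
    LPA = sqrt(cuts[[1]] * cuts[[2]]),
    MPA = sqrt(cuts[[2]] * cuts[[3]]),
    VPA = unname(cuts[3]) * 1.3)
}
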