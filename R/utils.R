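#' @include AllClasses.R
NULL

# naive local clock: all POSIXct in the package are UTC-backed wall time
asClock <- function(x, ...) as.POSIXct(x, tz = "UTC", ...)

# seconds since local midnight for each epoch of a series
epochClockSec <- function(es) {
  off <- as.numeric(es@start) %% 86400
  (off + (seq_along(es@enmo) - 1) * EPOCH_SECONDS) %% 86400
}

# calendar date of each epoch
epochDates <- function(es) {
  as.Date(floor((as.numeric(es@start) + (seq_along(es@enmo) - 1) * EPOCH_SECONDS) / 86400),
          origin = "1970-01-01")
}

# weekday 1 = Monday ... 7 = Sunday
weekdayIndex <- function(date) {
  (as.integer(as.Date(date)) + 3L) %% 7L + 1L
}

WEEKDAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

newEpochSeries <- function(participant, start, enmo, zangle,
                           wear = rep(TRUE, length(enmo)),
                           imputed = rep(FALSE, length(enmo)),
                           clipped = rep(FALSE, length(enmo)),
                           provenance = rep("", length(enmo))) {
  new("EpochSeries", participant = as.character(participant),
      start = asClock(start), enmo = as.numeric(enmo),
      zangle = as.numeric(zangle), wear = wear, imputed = imputed,
      clipped = clipped, provenance = provenance)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end) indices
trueRuns <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# largest-remainder apportionment of n into shares proportional to w
apportion <- function(n, w) {
  if (n == 0L || !length(w)) return(integer(length(w)))
  s <- sum(w)
  if (s <= 0) w <- rep(1, length(w)) else w <- w / s
  raw <- n * w / max(sum(w), 1e-12)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Construct a raw recording
#'
#' @param time numeric seconds since `startTime`, strictly increasing.
#' @param acc numeric matrix (n x 3) of x, y, z acceleration in g.
#' @param startTime start of the recording (naive local clock).
#' @param sampleRate nominal sampling frequency in Hz.
#' @param dynamicRange device dynamic range in g.
#' @return A [RawRecording-class].
#' @export
#' @examples
#' rawRecording(seq(0, 1, by = 1 / 40), matrix(c(0, 0, 1), 41, 3, byrow = TRUE))
rawRecording <- function(time, acc, startTime = "2019-11-04 00:00:00",
                         sampleRate = 40, dynamicRange = 8) {
  new("RawRecording", time = as.numeric(time),
      acc = as.matrix(acc), startTime = asClock(startTime),
      sampleRate = sampleRate, dynamicRange = dynamicRange)
}

#' Read and write epoch series CSV
#'
#' The epoch CSV interchange format has columns `participant_id`,
#' `epoch_start` (ISO-8601 local time), `enmo_mg`, `zangle_deg`, `wear`,
#' `imputed`, `provenance`.
#'
#' @param es an [EpochSeries-class].
#' @param path file path.
#' @return `readEpochCsv` returns an `EpochSeries`; `writeEpochCsv` returns
#'   `path` invisibly.
#' @export
#' @examples
#' es <- generateEpochSeries(
#'   data.frame(date = as.Date("2019-11-09"), dayType = "weekend",
#'              lpa = 150, mpa = 40, vpa = 8),
#'   schoolSchedule(), seed = 1)
#' p <- tempfile(fileext = ".csv")
#' writeEpochCsv(es, p)
#' es2 <- readEpochCsv(p)
#' stopifnot(identical(enmo(es), enmo(es2)))
writeEpochCsv <- function(es, path) {
  df <- data.frame(
    participant_id = es@participant,
    epoch_start = format(epochTimes(es), "%Y-%m-%dT%H:%M:%S"),
    enmo_mg = es@enmo, zangle_deg = es@zangle,
    wear = es@wear, imputed = es@imputed, provenance = es@provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochCsv
#' @export
readEpochCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$provenance[is.na(df$provenance)] <- ""
  newEpochSeries(df$participant_id[1],
                 asClock(df$epoch_start[1], format = "%Y-%m-%dT%H:%M:%S"),
                 df$enmo_mg, df$zangle_deg, wear = df$wear,
                 imputed = df$imputed, provenance = as.character(df$provenance))
}
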