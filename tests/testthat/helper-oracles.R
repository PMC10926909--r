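# Independent brute-force oracles used to check the implementation.

# AUC by exhaustive pairwise comparison: P(non-obese value > obese value),
# ties counted half
bruteAUC <- function(activity, obese) {
  x1 <- activity[as.logical(obese)]
  x0 <- activity[!as.logical(obese)]
  tot <- 0
  for (a in x1) for (b in x0) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(x1) * length(x0))
}

# Youden maximizer by exhaustive search over midpoint candidates,
# ties broken toward the higher threshold
bruteYouden <- function(activity, obese) {
  obese <- as.logical(obese)
  s <- sort(unique(activity))
  cand <- if (length(s) > 1) c(-Inf, (s[-length(s)] + s[-1]) / 2, Inf)
          else c(-Inf, Inf)
  J <- vapply(cand, function(t)
    mean(activity[obese] < t) + mean(activity[!obese] >= t) - 1, numeric(1))
  list(threshold = max(cand[J >= max(J) - 1e-12]), J = max(J))
}

# per-sample ENMO epoch means computed the slow, obvious way
bruteEnmoEpochs <- function(acc, samplesPerEpoch) {
  nEp <- floor(nrow(acc) / samplesPerEpoch)
  vapply(seq_len(nEp), function(i) {
    rows <- ((i - 1) * samplesPerEpoch + 1):(i * samplesPerEpoch)
    mean(pmax(0, sqrt(rowSums(acc[rows, , drop = FALSE]^2)) - 1)) * 1000
  }, numeric(1))
}

# Pearson chi-square by direct O/E summation
bruteChiSquare <- function(m) {
  n <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / n
  sum((m - E)^2 / E)
}

# phi as the product-moment correlation of indicator vectors
brutePhi <- function(m) {
  x <- rep(c(1, 1, 0, 0), c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
  y <- rep(c(1, 0, 1, 0), c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
  stats::cor(x, y)
}

# a valid week of day records with specified per-day mvpa (and proportional
# other bands), for weekly-summary tests
makeWeek <- function(mvpa = rep(80, 7), vpa = mvpa / 4,
                     types = c(rep("schoolNoPE", 5), "weekend", "weekend"),
                     weekdays = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                                  "Sun"),
                     valid = rep(TRUE, length(mvpa)),
                     id = "P1") {
  n <- length(mvpa)
  data.frame(id = id, date = as.Date("2019-11-04") + seq_len(n) - 1,
             weekday = weekdays, dayType = types, valid = valid,
             sb = 1440 - 200 - mvpa, lpa = 200, mpa = mvpa - vpa, vpa = vpa,
             mvpa = mvpa, lmvpa = 200 + mvpa)
}

# clock time h hours after the series start (series start at midnight)
asClockTest <- function(es, hours) epochTimes(es)[1] + hours * 3600

# shorthand for a one-day truth table
dayTruth <- function(date, dayType, lpa, mpa, vpa) {
  data.frame(date = as.Date(date), dayType = dayType, lpa = lpa, mpa = mpa,
             vpa = vpa)
}
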