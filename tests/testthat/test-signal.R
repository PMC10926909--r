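stillRec <- function(xyz, seconds = 10, fs = 40) {
  n <- seconds * fs
  rawRecording(seq_len(n) / fs, matrix(xyz, n, 3, byrow = TRUE))
}

test_that("ENMO epochs match closed forms and the per-sample oracle", {
  # gravity only -> 0 mg
  expect_equal(enmo(computeEnmoEpochs(stillRec(c(0, 0, 1)))),
               rep(0, 2))
  # constant (0.6, 0.8, 1.0): norm sqrt(2), ENMO 414.21 mg
  expect_equal(enmo(computeEnmoEpochs(stillRec(c(0.6, 0.8, 1)))),
               rep((sqrt(2) - 1) * 1000, 2), tolerance = 1e-9)
  # half an epoch at 1.2 g, half at 0.9 g: truncation before averaging
  acc <- matrix(0, 200, 3)
  acc[, 3] <- rep(c(1.2, 0.9), each = 100)
  rec <- rawRecording(seq_len(200) / 40, acc)
  expect_equal(enmo(computeEnmoEpochs(rec)), 100, tolerance = 1e-9)
  # random signal: equals the brute-force per-sample oracle
  set.seed(9)
  acc <- matrix(stats::rnorm(3 * 2000, 0, 0.8), ncol = 3)
  rec <- rawRecording(seq_len(2000) / 40, acc)
  expect_equal(enmo(computeEnmoEpochs(rec)), bruteEnmoEpochs(acc, 200),
               tolerance = 1e-9)
  expect_true(all(enmo(computeEnmoEpochs(rec)) >= 0))
  # epoch count = floor(samples / (fs * 5)); trailing partial dropped
  rec2 <- rawRecording(seq_len(450) / 40, matrix(0.5, 450, 3))
  expect_equal(nEpochs(computeEnmoEpochs(rec2)), 2L)
})

test_that("z-angle follows the arctangent convention", {
  expect_equal(computeZAngle(c(0, 0, 1)), 90)
  expect_equal(computeZAngle(c(1, 0, 0)), 0)
  expect_equal(computeZAngle(c(0.5, 0.5, 0.7071)), 45, tolerance = 1e-3)
  expect_equal(computeZAngle(c(0, 0, -1)), -90)
  expect_equal(computeZAngle(c(0, 0, 0)), 0)  # degenerate, flagged to 0
})

test_that("clipping detection follows the majority rule", {
  n <- 200
  high <- matrix(8, n, 3)
  rec <- rawRecording(seq_len(n) / 40, high)
  expect_true(all(detectClipping(rec)))
  normal <- matrix(3, n, 3)
  expect_false(any(detectClipping(rawRecording(seq_len(n) / 40, normal))))
  # a single clipped sample does not flag the epoch
  one <- matrix(0.5, n, 3)
  one[77, 1] <- 8
  expect_false(any(detectClipping(rawRecording(seq_len(n) / 40, one))))
  # epochs with > 50% clipped samples are flagged
  most <- matrix(0.5, n, 3)
  most[1:101, 2] <- -8
  expect_true(detectClipping(rawRecording(seq_len(n) / 40, most))[1])
})

test_that("auto-calibration is an identity on calibrated data and recovers
           injected errors", {
  prof <- stillProfile(hours = 2, segMin = 5)
  clean <- generateRawRecording(prof, seed = 2)
  cal0 <- autoCalibrate(clean)
  expect_true(cal0@converged)
  expect_equal(cal0@gain, c(1, 1, 1), tolerance = 5e-3)
  expect_equal(cal0@offset, c(0, 0, 0), tolerance = 5e-3)

  gains <- c(1.05, 0.97, 1.02); offs <- c(0.02, 0, -0.01)
  bad <- generateRawRecording(prof, gainError = gains, offsetError = offs,
                              seed = 2)
  cal <- autoCalibrate(bad)
  expect_equal(1 / cal@gain, gains, tolerance = 0.01)
  expect_lt(max(abs(-cal@offset / cal@gain - offs)), 0.005)
  # applying the model restores the unit sphere
  fixed <- applyCalibration(bad, cal)
  nrm <- sqrt(rowSums(fixed@acc[1:4000, ]^2))
  expect_lt(abs(mean(nrm) - 1), 0.005)
  # idempotence: recalibrating the corrected signal is near-identity
  cal2 <- autoCalibrate(fixed)
  expect_equal(cal2@gain, c(1, 1, 1), tolerance = 5e-3)
})

test_that("degenerate recordings fall back to the identity model", {
  # single orientation: under-determined
  one <- generateRawRecording(
    activityProfile(data.frame(durationSec = 3600, type = "still",
                               enmoTarget = 0, ox = 0, oy = 0, oz = 1)),
    seed = 1)
  cal <- autoCalibrate(one)
  expect_equal(cal@gain, c(1, 1, 1))
  expect_match(paste(cal@flags, collapse = " "), "under-determined")
  # too short: too few static windows
  short <- generateRawRecording(stillProfile(hours = 0.02, segMin = 1),
                                seed = 1)
  calS <- autoCalibrate(short)
  expect_equal(calS@gain, c(1, 1, 1))
  expect_match(paste(calS@flags, collapse = " "), "too few")
})

test_that("active segments hit their target mean ENMO", {
  prof <- activityProfile(data.frame(
    durationSec = 600, type = "active", enmoTarget = 300,
    ox = 0, oy = 0, oz = 1))
  rec <- generateRawRecording(prof, seed = 5)
  es <- computeEnmoEpochs(rec)
  expect_equal(mean(enmo(es)), 300, tolerance = 300 * 0.05)
})
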