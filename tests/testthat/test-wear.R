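test_that("the strict rule flags sustained constant-angle runs in-window", {
  truth <- dayTruth("2019-11-09", "weekend", 150, 40, 10)
  es <- generateEpochSeries(truth, seed = 6)
  # 35 min at 10:00 -> flagged as strict non-wear
  out <- injectNonwear(es, data.frame(start = "2019-11-09 10:00:00",
                                      end = "2019-11-09 10:35:00"))
  mask <- detectNonwear(out$series)
  flagged <- provenance(mask)[out$truth]
  expect_true(mean(flagged == "strict") > 0.9)
  # 25 min at 10:00 -> below the duration bound, stays wear
  out2 <- injectNonwear(es, data.frame(start = "2019-11-09 10:00:00",
                                       end = "2019-11-09 10:25:00"))
  mask2 <- detectNonwear(out2$series)
  expect_false(any(provenance(mask2)[out2$truth] == "strict"))
})

test_that("runs crossing the 22:00 edge only count their inside portion", {
  truth <- dayTruth("2019-11-09", "weekend", 150, 40, 10)
  es <- generateEpochSeries(truth, seed = 6)
  # 21:40-22:20: 20 min inside the window -> not flagged by the strict rule
  out <- injectNonwear(es, data.frame(start = "2019-11-09 21:40:00",
                                      end = "2019-11-09 22:20:00"))
  mask <- detectNonwear(out$series)
  expect_false(any(provenance(mask)[out$truth] == "strict"))
  # 21:00-22:30: 60 min inside -> the inside portion is flagged, the tail
  # after 22:00 is not
  out2 <- injectNonwear(es, data.frame(start = "2019-11-09 21:00:00",
                                       end = "2019-11-09 22:30:00"))
  mask2 <- detectNonwear(out2$series)
  clock <- (as.numeric(epochTimes(out2$series)) %% 86400)
  inside <- out2$truth & clock < 22 * 3600
  outside <- out2$truth & clock >= 22 * 3600
  expect_true(mean(provenance(mask2)[inside] == "strict") > 0.95)
  expect_false(any(provenance(mask2)[outside] == "strict"))
})

test_that("device-off epochs are non-wear with provenance 'off'", {
  es <- generateEpochSeries(dayTruth("2019-11-09", "weekend", 100, 30, 5),
                            seed = 2)
  out <- injectNonwear(es, data.frame(start = "2019-11-09 20:00:00",
                                      end = "2019-11-09 21:00:00"),
                       mode = "off")
  expect_true(all(is.na(enmo(out$series)[out$truth])))
  mask <- detectNonwear(out$series)
  expect_true(all(provenance(mask)[out$truth] == "off"))
})

test_that("imputation fills gaps from same-day-type donors and conserves
           the 24-h budget", {
  sched <- schoolSchedule()
  truth <- data.frame(date = as.Date("2019-11-04") + 0:7,
                      dayType = c("schoolNoPE", "schoolPE", "schoolNoPE",
                                  "schoolPE", "schoolNoPE", "weekend",
                                  "weekend", "schoolNoPE"),
                      lpa = 200, mpa = 70, vpa = 15)
  es <- generateEpochSeries(truth, sched, seed = 12)
  inj <- injectNonwear(es, data.frame(start = "2019-11-05 10:00:00",
                                      end = "2019-11-05 10:30:00"))
  es2 <- applyWearMask(inj$series, detectNonwear(inj$series))
  days <- dayRecords(es2, sched)
  expect_true(all(days$valid[days$dayType %in%
                               c("schoolPE", "schoolNoPE", "weekend")]))
  es3 <- imputeNonwear(es2, days)
  expect_true(any(imputedFlag(es3)))
  days3 <- dayRecords(es3, sched)
  expect_equal(days3$sb + days3$lpa + days3$mpa + days3$vpa + days3$nonwear,
               rep(1440, nrow(days3)))
  # the imputed day's residual non-wear shrank
  expect_lt(days3$nonwear[2], days$nonwear[2])
})

test_that("imputation is an identity when there is no non-wear", {
  es <- generateEpochSeries(dayTruth("2019-11-09", "weekend", 100, 30, 5),
                            seed = 2)
  es <- applyWearMask(es, detectNonwear(es))
  days <- dayRecords(es, schoolSchedule())
  es2 <- imputeNonwear(es, days)
  expect_identical(enmo(es2), enmo(es))
  expect_false(any(imputedFlag(es2)))
})

test_that("a gap on the only day of its type falls back to the weekly mean", {
  sched <- schoolSchedule(peWeekdays = 2)  # PE on Tuesdays only
  truth <- data.frame(date = as.Date("2019-11-04") + 0:7,
                      dayType = c("schoolNoPE", "schoolPE", "schoolNoPE",
                                  "schoolNoPE", "schoolNoPE", "weekend",
                                  "weekend", "schoolNoPE"),
                      lpa = 200, mpa = 70, vpa = 15)
  es <- generateEpochSeries(truth, sched, seed = 13)
  # gap on the only PE day (2019-11-05 is a Tuesday with PE scheduled)
  inj <- injectNonwear(es, data.frame(start = "2019-11-05 16:00:00",
                                      end = "2019-11-05 16:30:00"))
  es2 <- applyWearMask(inj$series, detectNonwear(inj$series))
  days <- dayRecords(es2, sched)
  expect_equal(sum(days$dayType == "schoolPE"), 1L)
  es3 <- imputeNonwear(es2, days)
  expect_true(any(imputedFlag(es3)[inj$truth]))
})

test_that("reported sport removals substitute only verified non-wear", {
  donors <- data.frame(sport = "football", slotOffsetMin = c(0, 30),
                       sb = c(2, 2), lpa = c(8, 8), mpa = c(12, 12),
                       vpa = c(8, 8))
  truth <- dayTruth("2019-11-09", "weekend", 100, 30, 5)
  es <- generateEpochSeries(truth, seed = 3)
  inj <- injectNonwear(es, data.frame(start = "2019-11-09 17:00:00",
                                      end = "2019-11-09 17:55:00"))
  es2 <- applyWearMask(inj$series, detectNonwear(inj$series))
  rep_ <- data.frame(start = "2019-11-09 17:00:00",
                     end = "2019-11-09 18:00:00", sport = "football")
  es3 <- substituteReportedSport(es2, rep_, donors)
  subbed <- provenance(es3) == "sport"
  expect_equal(sum(subbed) / 12, 55, tolerance = 1)
  # substituted epochs carry donor-like MVPA composition
  m <- classifyIntensity(enmo(es3)[subbed])
  expect_gt(mean(m %in% c("MPA", "VPA")), 0.5)
  # a fully worn report changes nothing
  es4 <- substituteReportedSport(es2, data.frame(
    start = "2019-11-09 12:00:00", end = "2019-11-09 13:00:00",
    sport = "football"), donors)
  expect_identical(enmo(es4), enmo(es2))
  # unknown sport: warning, no substitution
  expect_warning(
    es5 <- substituteReportedSport(es2, data.frame(
      start = "2019-11-09 17:00:00", end = "2019-11-09 18:00:00",
      sport = "curling"), donors),
    "no donor profile")
  expect_identical(enmo(es5), enmo(es2))
})

test_that("adding non-wear can never validate an invalid day (monotone)", {
  es <- generateEpochSeries(dayTruth("2019-11-09", "weekend", 100, 30, 5),
                            seed = 2)
  base <- injectNonwear(es, data.frame(start = "2019-11-09 09:00:00",
                                       end = "2019-11-09 11:05:00"))
  more <- injectNonwear(base$series,
                        data.frame(start = "2019-11-09 14:00:00",
                                   end = "2019-11-09 15:00:00"))
  d1 <- dayRecords(applyWearMask(base$series, detectNonwear(base$series)),
                   schoolSchedule())
  d2 <- dayRecords(applyWearMask(more$series, detectNonwear(more$series)),
                   schoolSchedule())
  expect_false(d1$valid[1])  # 125 min in-window non-wear already invalid
  expect_false(d2$valid[1])
  expect_gte(d2$nonwearWindowMin[1], d1$nonwearWindowMin[1])
})
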