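test_that("day, school-time and PE validity rules honour their boundaries", {
  expect_true(validateDay(24, 60))
  expect_false(validateDay(24, 121))
  expect_false(validateDay(19.9, 0))
  expect_true(validateDay(20, 120))  # inclusive bounds

  expect_true(validateSchoolTime(5, 10))
  expect_false(validateSchoolTime(3.5, 0))
  expect_false(validateSchoolTime(5, 61))
  expect_true(validateSchoolTime(4, 60))

  expect_true(validatePeClass(0, 20, 40))
  expect_false(validatePeClass(2, 20, 40))       # conjunctive reading
  expect_true(validatePeClass(0, 2, 25))         # sedentary clause
  expect_false(validatePeClass(0.99, 2, 35))
  expect_false(validatePeClass(0, 2, 35))
  expect_true(validatePeClass(2, 20, 40, rule = "disjunction"))
})

test_that("day types follow the calendar", {
  expect_equal(classifyDayType(2, FALSE, FALSE, TRUE, TRUE), "schoolPE")
  expect_equal(classifyDayType(2, FALSE, FALSE, TRUE, FALSE), "schoolNoPE")
  expect_equal(classifyDayType(6, FALSE, FALSE), "weekend")
  expect_equal(classifyDayType(1, TRUE, FALSE), "holiday")
  expect_equal(classifyDayType(3, FALSE, TRUE), "absence")
})

test_that("holidays and absences are excluded from analysis days", {
  sched <- schoolSchedule(holidays = as.Date("2019-11-04"),
                          absences = list(P1 = as.Date("2019-11-06")))
  truth <- data.frame(date = as.Date("2019-11-04") + 0:7,
                      dayType = c("schoolNoPE", "schoolPE", "schoolNoPE",
                                  "schoolPE", "schoolNoPE", "weekend",
                                  "weekend", "schoolNoPE"),
                      lpa = 200, mpa = 70, vpa = 15)
  es <- generateEpochSeries(truth, sched, participant = "P1", seed = 7)
  es <- applyWearMask(es, detectNonwear(es))
  days <- dayRecords(es, sched)
  expect_equal(days$dayType[1], "holiday")
  expect_equal(days$dayType[3], "absence")
  expect_false(any(days$valid[c(1, 3)]))
})

test_that("the weekly weighted mean follows the 5/7-2/7 arithmetic", {
  wk <- makeWeek(mvpa = c(rep(80, 5), 60, 60))
  out <- weeklySummary(wk)
  expect_equal(out$mvpaWeekly, 5 / 7 * 80 + 2 / 7 * 60)
  expect_true(out$validAssessment)
  # school mean == weekend mean == m gives exactly m
  out2 <- weeklySummary(makeWeek(mvpa = rep(66, 7)))
  expect_equal(out2$mvpaWeekly, 66)
})

test_that("duplicate weekdays are averaged before the school mean", {
  wk <- makeWeek(mvpa = c(70, 80, 80, 80, 80, 60, 60, 90),
                 types = c(rep("schoolNoPE", 5), "weekend", "weekend",
                           "schoolNoPE"),
                 weekdays = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                              "Sun", "Mon"))
  out <- weeklySummary(wk)
  # Monday contributes (70 + 90) / 2 = 80: school mean 80
  expect_equal(out$mvpaWeekly, 5 / 7 * 80 + 2 / 7 * 60)
})

test_that("the weekly mean is invariant to permuting days within a type", {
  set.seed(31)
  mv <- c(stats::runif(5, 40, 120), stats::runif(2, 30, 100))
  base <- weeklySummary(makeWeek(mvpa = mv))
  perm <- makeWeek(mvpa = c(mv[c(3, 1, 5, 2, 4)], mv[c(7, 6)]),
                   weekdays = c("Wed", "Mon", "Fri", "Tue", "Thu", "Sun",
                                "Sat"))
  expect_equal(weeklySummary(perm)$mvpaWeekly, base$mvpaWeekly)
})

test_that("assessment validity needs 4 weekdays incl. 2 school and 1 weekend", {
  few <- makeWeek(mvpa = rep(80, 3),
                  types = c("schoolNoPE", "schoolNoPE", "weekend"),
                  weekdays = c("Mon", "Tue", "Sat"))
  expect_false(weeklySummary(few)$validAssessment)
  ok <- makeWeek(mvpa = rep(80, 4),
                 types = c("schoolNoPE", "schoolNoPE", "schoolPE", "weekend"),
                 weekdays = c("Mon", "Tue", "Wed", "Sat"))
  expect_true(weeklySummary(ok)$validAssessment)
  # no valid weekend day: weighted mean undefined
  noWknd <- makeWeek(mvpa = rep(80, 5),
                     types = rep("schoolNoPE", 5),
                     weekdays = c("Mon", "Tue", "Wed", "Thu", "Fri"))
  out <- weeklySummary(noWknd)
  expect_false(out$validAssessment)
  expect_true(is.na(out$mvpaWeekly))
})
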