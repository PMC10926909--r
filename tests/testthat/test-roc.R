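test_that("ROC handles separation, nulls and degenerate input", {
  rc <- rocCurve(c(5, 8, 10, 12), c(1, 1, 0, 0))
  expect_equal(auc(rc), 1)
  y <- youdenThreshold(rc, granularity = 0)
  expect_equal(y$raw, 9)  # midpoint between the classes
  expect_equal(y$J, 1)
  expect_error(rocCurve(1:5, rep(TRUE, 5)), "both classes")
  # permuted labels: null AUC
  set.seed(77)
  act <- stats::rnorm(360, 15, 5)
  lab <- sample(rep(c(TRUE, FALSE), c(90, 270)))
  expect_lt(abs(auc(rocCurve(act, lab)) - 0.5), 0.05)
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  set.seed(14)
  for (r in 1:50) {
    n <- sample(5:20, 1)
    act <- round(stats::rnorm(n, 10, 4), sample(0:1, 1))  # force some ties
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc(rocCurve(act, lab)), bruteAUC(act, lab),
                 tolerance = 1e-12)
  }
})

test_that("the Youden maximizer matches exhaustive search with the
           high-threshold tie rule", {
  # the documented tie case: J ties at 0.5 for t in {6.5, 11.5} -> 11.5
  rc <- rocCurve(c(5, 11, 8, 12), c(1, 1, 0, 0))
  expect_equal(youdenThreshold(rc, granularity = 0)$raw, 11.5)
  set.seed(15)
  for (r in 1:50) {
    n <- sample(6:20, 1)
    act <- round(stats::runif(n, 0, 20), sample(0:1, 1))
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    got <- youdenThreshold(rocCurve(act, lab), granularity = 0)
    want <- bruteYouden(act, lab)
    expect_equal(got$raw, want$threshold)
    expect_equal(got$J, want$J, tolerance = 1e-12)
  }
})

test_that("the Youden index is sensitivity + specificity - 1", {
  rc <- new("RocCurve", thresholds = c(50, 76.4, 90),
            sensitivity = c(0.2, 0.77, 0.95),
            specificity = c(0.9, 0.46, 0.1),
            auc = 0.64, aucSe = 0.05, aucCI = c(0.54, 0.74), p = 0.008,
            nPos = 44L, nNeg = 112L)
  y <- youdenThreshold(rc, granularity = 0)
  expect_equal(y$J, 0.23, tolerance = 1e-9)
  expect_equal(y$raw, 76.4)
})

test_that("thresholds are rounded down to the half-minute", {
  rc <- rocCurve(c(8, 9.4, 10, 12), c(1, 1, 0, 0))
  y <- youdenThreshold(rc)  # raw maximizer 9.7
  expect_equal(y$raw, 9.7)
  expect_equal(y$threshold, 9.5)
})

test_that("MVPA thresholds pool only under a small relative gap", {
  expect_equal(poolThresholds(76.4, 73.8, 156, 168), 75)
  expect_true(is.na(poolThresholds(12.5, 9.7, 156, 168)))  # 25% gap
})

test_that("recommendations are derived per sex and recover the designed
           thresholds", {
  coh <- generateCohort(cohortSpec(seed = 11))
  s <- cbind(coh$truthWeekly,
             centralObesity = coh$participants$centralObesity)
  der <- deriveRecommendations(s)
  e <- recommendationEntries(der$recommendations)
  expect_setequal(e$name, c("RecMVPA-WHO", "RecVPA-15", "RecMVPA", "RecVPA"))
  vpa <- e[e$name == "RecVPA", ]
  expect_lt(abs(vpa$male - 12.5), 1.5)
  expect_lt(abs(vpa$female - 9.5), 1.5)
  expect_equal(e$pooled[e$name == "RecMVPA-WHO"], 60)
  expect_equal(e$pooled[e$name == "RecVPA-15"], 15)
  # single-sex cohort: pooling skipped with a notice
  expect_message(
    der1 <- deriveRecommendations(s[s$sex == "male", ]),
    "single-sex")
  e1 <- recommendationEntries(der1$recommendations)
  expect_true(is.na(e1$female[e1$name == "RecVPA"]))
  expect_error(deriveRecommendations(s[, setdiff(names(s), "sex")]),
               "sex")
})

test_that("AUC and its confidence bounds agree with an independent
           implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  act <- stats::rnorm(120, 15, 6)
  lab <- stats::runif(120) < stats::plogis(2 - 0.2 * act)
  if (length(unique(lab)) < 2) lab[1:2] <- c(TRUE, FALSE)
  rc <- rocCurve(act, lab)
  pr <- pROC::roc(response = lab, predictor = act, direction = ">",
                  quiet = TRUE)
  expect_equal(auc(rc), as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(rc@aucCI[1], ci[1], tolerance = 0.005)
  expect_equal(rc@aucCI[2], ci[3], tolerance = 0.005)
})
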