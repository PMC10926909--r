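test_that("phi matches the closed form and the correlation oracle", {
  m <- matrix(c(39, 45, 177, 65), 2, byrow = TRUE)
  expect_equal(phiCoefficient(m), -0.247, tolerance = 5e-4)
  expect_equal(phiCoefficient(matrix(c(10, 0, 0, 10), 2)), 1)
  set.seed(23)
  for (r in 1:100) {
    m <- matrix(stats::rpois(4, 20) + 1, 2)
    expect_equal(phiCoefficient(m), brutePhi(m), tolerance = 1e-12)
    expect_equal(cramersV(m), abs(phiCoefficient(m)), tolerance = 1e-12)
  }
  expect_error(phiCoefficient(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margins")
})

test_that("chi-square matches the O/E summation oracle", {
  m <- matrix(c(39, 45, 177, 65), 2, byrow = TRUE)
  got <- chiSquareTest(m)
  expect_equal(got$statistic, bruteChiSquare(m), tolerance = 1e-12)
  expect_equal(got$df, 1)
  # perfectly independent table: statistic 0, p 1
  ind <- outer(c(30, 70), c(40, 60)) / 100
  gi <- chiSquareTest(ind)
  expect_equal(gi$statistic, 0, tolerance = 1e-12)
  expect_equal(gi$p, 1)
  expect_equal(chiSquareTest(matrix(c(20, 10, 5, 5, 10, 20), 2,
                                    byrow = TRUE))$df, 2)
  # Cramer's V of an independent table is 0
  expect_equal(cramersV(ind), 0, tolerance = 1e-12)
  v <- cramersV(matrix(c(20, 10, 5, 5, 10, 20), 2, byrow = TRUE))
  expect_equal(v, sqrt(bruteChiSquare(matrix(c(20, 10, 5, 5, 10, 20), 2,
                                             byrow = TRUE)) / 70),
               tolerance = 1e-12)
})

test_that("McNemar switches between asymptotic and exact branches", {
  expect_equal(mcnemarTest(20, 10)$statistic, 100 / 30, tolerance = 1e-12)
  expect_equal(mcnemarTest(20, 10)$method, "asymptotic")
  expect_equal(mcnemarTest(5, 0)$p, 0.0625, tolerance = 1e-12)
  expect_equal(mcnemarTest(7, 7)$p, 1)
  expect_equal(mcnemarTest(0, 0)$p, 1)
  expect_equal(mcnemarTest(0, 0)$statistic, 0)
  # invariant to concordant cells by construction: only b and c enter
  expect_identical(mcnemarTest(12, 4), mcnemarTest(12, 4))
  # near the switch point the exact and asymptotic p agree reasonably
  pe <- stats::binom.test(17, 25, 0.5)$p.value
  pa <- mcnemarTest(17, 8)$p
  expect_lt(abs(pe - pa), 0.04)
})

test_that("rank tests match exhaustive pair counting", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mannWhitneyU(c(4, 5, 6), c(1, 2, 3))$U, 9)
  expect_equal(mannWhitneyU(1:4, 1:4)$U, 8)  # identical groups: n1 n2 / 2
  w <- wilcoxonSignedRank(c(1, -1))
  expect_equal(w$p, 1)
  expect_equal(wilcoxonSignedRank(c(0, 0, 0))$p, 1)
})

test_that("conditional logistic OR equals the discordant ratio for pairs", {
  set.seed(41)
  for (r in 1:5) {
    n <- 120
    pe <- stats::rbinom(n, 1, 0.6)
    noPe <- stats::rbinom(n, 1, 0.4)
    b <- sum(pe & !noPe); c_ <- sum(!pe & noPe)
    if (b == 0 || c_ == 0) next
    d <- data.frame(id = rep(seq_len(n), each = 2),
                    condition = factor(rep(c("noPE", "PE"), n),
                                       levels = c("noPE", "PE")),
                    outcome = as.vector(rbind(noPe, pe)))
    fit <- conditionalLogisticOR(d)
    expect_equal(fit$or, b / c_, tolerance = 1e-6)
    expect_equal(discordantOR(b, c_)$or, b / c_)
  }
  expect_error(conditionalLogisticOR(data.frame(
    id = rep(1:5, each = 2), condition = factor(rep(c("a", "b"), 5)),
    outcome = rep(1, 10))), "informative")
})

test_that("compliance evaluation uses sex-specific inclusive thresholds", {
  recs <- recommendationSet(data.frame(
    name = c("RecVPA", "RecMVPA-WHO"), band = c("vpa", "mvpa"),
    male = c(12.5, NA), female = c(9.5, NA), pooled = c(NA, 60),
    provenance = c("roc", "fixed")))
  s <- data.frame(id = c("A", "B", "C"),
                  sex = c("female", "male", "male"),
                  vpaWeekly = c(9.5, 12.4, 13),
                  mvpaWeekly = c(61, 59.9, 70))
  out <- evaluateCompliance(s, recs, "weekly")
  expect_equal(out$RecVPA, c(TRUE, FALSE, TRUE))       # 9.5 meets at boundary
  expect_equal(out$`RecMVPA-WHO`, c(TRUE, FALSE, TRUE))  # 59.9 fails
  # hand count on a known cohort
  set.seed(55)
  s2 <- data.frame(id = sprintf("K%02d", 1:10),
                   sex = rep(c("male", "female"), 5),
                   vpaWeekly = seq(5, 18.5, length.out = 10),
                   mvpaWeekly = seq(40, 100, length.out = 10))
  out2 <- evaluateCompliance(s2, recs, "weekly")
  thr <- ifelse(s2$sex == "male", 12.5, 9.5)
  expect_equal(sum(out2$RecVPA), sum(s2$vpaWeekly >= thr))
  # missing day-type column errors clearly
  expect_error(evaluateCompliance(s, recs, "weekend"), "vpaWeekend")
})
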