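#' @include AllClasses.R roc.R
#' @importFrom survival clogit strata coxph Surv
NULL

#' Evaluate recommendation compliance
#'
#' A child meets a recommendation when their average daily activity in the
#' scope is at or above the threshold (boundary inclusive), using the
#' child's sex-specific threshold where the entry is sex-specific. Weekly
#' scope uses the weekly weighted mean; a day-type scope uses the mean over
#' the child's valid days of that type, and children without such days get
#' an NA flag (denominators adjust downstream).
#'
#' @param summaries participant summary data.frame (columns `id`, `sex`,
#'   `mvpaWeekly`, `vpaWeekly`, `mvpaSchoolPE`, ... as produced by
#'   [weeklySummary()] / [generateCohort()]).
#' @param recs a [RecommendationSet-class].
#' @param scope `"weekly"`, `"schoolPE"`, `"schoolNoPE"` or `"weekend"`.
#' @return data.frame: `id`, `sex`, `scope`, one logical column per
#'   recommendation.
#' @export
evaluateCompliance <- function(summaries,
                               recs = recommendationSet(),
                               scope = c("weekly", "schoolPE", "schoolNoPE",
                                         "weekend")) {
  scope <- match.arg(scope)
  suffix <- c(weekly = "Weekly", schoolPE = "SchoolPE",
              schoolNoPE = "SchoolNoPE", weekend = "Weekend")[[scope]]
  entries <- recommendationEntries(recs)
  out <- data.frame(id = summaries$id, sex = summaries$sex, scope = scope)
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    col <- paste0(e$band, suffix)
    if (!col %in% names(summaries))
      stop(sprintf("summaries lack column '%s'", col))
    thr <- recommendationThreshold(recs, e$name, summaries$sex)
    out[[e$name]] <- summaries[[col]] >= thr
  }
  out
}

as2x2 <- function(x) {
  m <- as.matrix(x)
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required")
  storage.mode(m) <- "double"
  m
}

checkMargins <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all table margins must be positive")
}

#' Phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` with cells `(a, b, c, d)` read
#' row-wise; equals the product-moment correlation of the two binary
#' indicators.
#'
#' @param tab 2x2 table or matrix of counts.
#' @return Phi in \[-1, 1\].
#' @export
#' @examples
#' phiCoefficient(matrix(c(39, 45, 177, 65), 2, byrow = TRUE))
phiCoefficient <- function(tab) {
  m <- as2x2(tab)
  checkMargins(m)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  (a * d - b * c_) /
    sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; expected counts from the margins.
#'
#' @param tab r x c table or matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chiSquareTest(matrix(c(20, 10, 5, 5, 10, 20), 2, byrow = TRUE))
chiSquareTest <- function(tab) {
  m <- as.matrix(tab)
  checkMargins(m)
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Cramer's V
#'
#' `sqrt(chi2 / (n (min(r, c) - 1)))` with the uncorrected Pearson
#' chi-square; equals |phi| on a 2x2 table.
#'
#' @param tab r x c table or matrix of counts.
#' @return V in \[0, 1\].
#' @export
#' @examples
#' cramersV(matrix(c(20, 10, 5, 5, 10, 20), 2, byrow = TRUE))
cramersV <- function(tab) {
  m <- as.matrix(tab)
  chi2 <- chiSquareTest(m)$statistic
  sqrt(chi2 / (sum(m) * (min(dim(m)) - 1)))
}

#' McNemar test for paired binary outcomes
#'
#' With discordant counts b (yes -> no) and c (no -> yes): when
#' `b + c >= exactLimit` the asymptotic chi-square `(b - c)^2 / (b + c)` on
#' 1 df (no continuity correction); otherwise the exact two-sided binomial
#' test of b successes in b + c trials at p = 0.5. `b = c = 0` gives
#' statistic 0 and p = 1.
#'
#' @param b,c discordant pair counts.
#' @param exactLimit switch point between the exact and asymptotic method.
#' @return list with `statistic`, `p`, `method`.
#' @export
#' @examples
#' mcnemarTest(20, 10)$statistic  # 100/30
#' mcnemarTest(5, 0)$p            # 0.0625
mcnemarTest <- function(b, c, exactLimit = 25) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0)
    return(list(statistic = 0, p = 1, method = "exact"))
  stat <- (b - c)^2 / (b + c)
  if (b + c >= exactLimit) {
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         method = "asymptotic")
  } else {
    p <- min(1, stats::binom.test(b, b + c, 0.5)$p.value)
    list(statistic = stat, p = p, method = "exact")
  }
}

#' Rank tests
#'
#' `mannWhitneyU` compares two independent samples (U statistic of the
#' first group: the number of pairs where x exceeds y, ties counted half);
#' `wilcoxonSignedRank` compares paired samples. Both use midranks for
#' ties, the exact distribution for small samples without ties and the
#' normal approximation with tie correction otherwise (as implemented in
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric samples (paired and equal-length for the signed-rank
#'   test).
#' @return list with the statistic (`U` or `W`) and `p`.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$U  # 0
mannWhitneyU <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' @rdname mannWhitneyU
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (all(d == 0)) return(list(W = 0, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(d))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Conditional logistic odds ratios for within-child contrasts
#'
#' Fits a conditional logistic regression of a binary outcome (meets a
#' recommendation) on a condition factor (day type), stratified by
#' participant, maximizing the likelihood conditional on each stratum's
#' outcome total (strata without outcome variation contribute nothing). In
#' the two-condition paired-binary special case the estimate equals the
#' discordant-pair ratio b/c. Confidence intervals come from the
#' observed-information standard error.
#'
#' @param data data.frame with columns `id`, `condition` (factor; first
#'   level is the reference), `outcome` (0/1 or logical).
#' @return data.frame per non-reference condition level: `contrast`, `or`,
#'   `lo`, `hi` (95% CI), `p`.
#' @export
#' @examples
#' d <- data.frame(id = rep(1:30, each = 2),
#'                 condition = factor(rep(c("ref", "alt"), 30),
#'                                    levels = c("ref", "alt")),
#'                 outcome = rep(c(0, 1), 30))
conditionalLogisticOR <- function(data) {
  stopifnot(all(c("id", "condition", "outcome") %in% names(data)))
  data$outcome <- as.integer(data$outcome)
  data$condition <- droplevels(as.factor(data$condition))
  informative <- tapply(data$outcome, data$id, function(o)
    length(unique(o)) > 1)
  if (!any(informative))
    stop("no informative strata (no within-participant outcome variation)")
  fit <- survival::clogit(outcome ~ condition + strata(id), data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  data.frame(contrast = sub("^condition", "", rownames(co)),
             or = unname(co[, "exp(coef)"]),
             lo = unname(ci[, 3]), hi = unname(ci[, 4]),
             p = unname(co[, "Pr(>|z|)"]), row.names = NULL)
}

#' Discordant-pair odds ratio
#'
#' Closed form of the paired conditional-logistic estimate: b/c, with an
#' exact flag when a discordant cell is empty.
#'
#' @param b,c discordant pair counts (condition-positive-only and
#'   reference-positive-only).
#' @return list with `or` and `degenerate` flag.
#' @export
#' @examples
#' discordantOR(20, 10)$or  # 2
discordantOR <- function(b, c) {
  if (c == 0 && b == 0) return(list(or = NA_real_, degenerate = TRUE))
  list(or = b / c, degenerate = (b == 0 || c == 0))
}
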