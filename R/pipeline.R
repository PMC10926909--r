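#' @include AllClasses.R synth-cohort.R synth-epochs.R wear.R day-typing.R
#' @include summaries.R roc.R assoc.R
NULL

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate-process-summarize-thresholds-stats
#' pipeline. Defaults equal the study constants: 5-s epochs, cut-points
#' 56.3 / 191.6 / 695.8 mg, the 20-h / 2-h day rule, 4-h / 1-h school-time
#' rule, strict 30-min / 2-degree non-wear rule in 8:00-22:00, 30-min
#' imputation slots and half-minute threshold rounding.
#'
#' @param nChildren cohort size to simulate.
#' @param nDays protocol days.
#' @param peDaysPerWeek PE days per week.
#' @param seed master seed; every downstream draw derives from it.
#' @param epochSeconds epoch length (s).
#' @param cutPoints [intensityCutPoints()].
#' @param slotMin imputation slot width (min).
#' @param granularity threshold rounding granularity (min).
#' @param peRule PE-class validity reading (see [validatePeClass()]).
#' @param fullProtocol enforce the 8-day protocol invariant.
#' @return list of class `PipelineConfig`.
#' @export
#' @examples
#' cfg <- pipelineConfig(nChildren = 4, seed = 7)
pipelineConfig <- function(nChildren = 40, nDays = 8, peDaysPerWeek = 2,
                           seed = 1, epochSeconds = 5,
                           cutPoints = intensityCutPoints(),
                           slotMin = 30, granularity = 0.5,
                           peRule = "conjunction",
                           fullProtocol = nDays >= 8) {
  cfg <- list(nChildren = nChildren, nDays = nDays,
              peDaysPerWeek = peDaysPerWeek, seed = as.integer(seed),
              epochSeconds = epochSeconds, cutPoints = as.list(cutPoints),
              slotMin = slotMin, granularity = granularity, peRule = peRule,
              fullProtocol = fullProtocol)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize, parse and hash a pipeline configuration
#'
#' @param cfg a [pipelineConfig()].
#' @param path YAML file path.
#' @return `writeConfig` returns `path`; `readConfig` a `PipelineConfig`;
#'   `configHash` an md5 string recorded in all pipeline outputs.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname writeConfig
#' @export
configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

drawNonwearIntervals <- function(dates, rate, durPar) {
  out <- NULL
  for (d in dates) {
    k <- stats::rpois(1, rate)
    if (k == 0) next
    startH <- stats::runif(k, 8, 21)
    durMin <- pmin(exp(stats::rnorm(k, durPar[["meanlog"]],
                                    durPar[["sdlog"]])), 180)
    out <- rbind(out, data.frame(
      start = asClock(as.Date(d, origin = "1970-01-01")) + startH * 3600,
      end = asClock(as.Date(d, origin = "1970-01-01")) +
        pmin(startH * 3600 + durMin * 60, 86395)))
  }
  if (is.null(out)) data.frame(start = asClock(character()),
                               end = asClock(character())) else out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort at the epoch level, detects non-wear, classifies and
#' validates days, imputes residual non-wear, builds weekly weighted
#' participant summaries, derives the ROC-based recommendations and
#' computes compliance and association statistics. Every exclusion (invalid
#' day, invalid assessment, holiday or absence) is logged with participant,
#' date and reason; outputs are written to `outDir` and are byte-identical
#' for a fixed config.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param schedule a [schoolSchedule()].
#' @return Invisibly, a list with `participants`, `days` (per-child day
#'   records), `summaries`, `recommendations`, `roc`, `compliance`,
#'   `stats`, `flow` and `log`.
#' @export
runPipeline <- function(cfg, outDir = tempfile("actikids_run_"),
                        schedule = schoolSchedule()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg)
  logs <- list()
  note <- function(...) logs[[length(logs) + 1L]] <<- list(...)

  spec <- cohortSpec(nChildren = cfg$nChildren, nDays = cfg$nDays,
                     peDaysPerWeek = cfg$peDaysPerWeek,
                     fullProtocol = cfg$fullProtocol, seed = cfg$seed)
  cohort <- generateCohort(spec)
  note(stage = "simulate", nChildren = cfg$nChildren, configHash = hash)

  cuts <- do.call(intensityCutPoints, cfg$cutPoints)
  ids <- cohort$participants$id
  set.seed(cfg$seed)
  childSeeds <- sample.int(.Machine$integer.max %/% 2, length(ids))
  dayList <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    truth <- cohort$truthDaily[cohort$truthDaily$id == id, ]
    es <- generateEpochSeries(truth, schedule, participant = id,
                              seed = childSeeds[i])
    set.seed(childSeeds[i] + 1L)
    iv <- drawNonwearIntervals(truth$date, spec@nonwearRate,
                               spec@nonwearDuration)
    if (nrow(iv)) es <- injectNonwear(es, iv)$series
    es <- applyWearMask(es, detectNonwear(es))
    days <- dayRecords(es, schedule, participant = id, peRule = cfg$peRule,
                       cuts = cuts)
    es <- suppressWarnings(imputeNonwear(es, days, slotMin = cfg$slotMin,
                                         cuts = cuts))
    days <- dayRecords(es, schedule, participant = id, peRule = cfg$peRule,
                       cuts = cuts)
    for (j in which(!days$valid))
      note(stage = "validity", participant = id,
           date = as.character(days$date[j]),
           reason = if (days$dayType[j] %in% c("holiday", "absence"))
             days$dayType[j] else "invalid day")
    dayList[[id]] <- days
  }

  summaries <- withCallingHandlers(
    summarizeCohort(dayList, cohort$participants),
    message = function(m) {
      note(stage = "assessment", reason = conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  flow <- list(simulated = length(ids),
               assessmentValid = nrow(summaries),
               excludedAssessments = length(ids) - nrow(summaries))
  note(stage = "flow", counts = flow)

  recs <- recommendationSet(granularity = cfg$granularity)
  rocTables <- NULL
  bothClassesPerSex <- nrow(summaries) &&
    all(c("male", "female") %in% summaries$sex) &&
    all(vapply(c("male", "female"), function(sx)
      length(unique(summaries$centralObesity[summaries$sex == sx])) == 2L,
      logical(1)))
  if (bothClassesPerSex) {
    der <- deriveRecommendations(summaries, granularity = cfg$granularity)
    recs <- der$recommendations
    rocTables <- der$roc
  } else {
    note(stage = "thresholds",
         reason = "cohort too small or single-class: fixed recommendations only")
  }

  compliance <- NULL
  statsTab <- NULL
  if (nrow(summaries)) {
    compliance <- do.call(rbind, lapply(
      c("weekly", "schoolPE", "schoolNoPE", "weekend"),
      function(sc) evaluateCompliance(summaries, recs, sc)))
    statsTab <- complianceStats(summaries, compliance, recs, note)
  }

  results <- list(participants = cohort$participants, days = dayList,
                  summaries = summaries, recommendations = recs,
                  roc = rocTables, compliance = compliance,
                  stats = statsTab, flow = flow, log = logs,
                  configHash = hash)
  writePipelineOutputs(results, cfg, outDir)
  invisible(results)
}

complianceStats <- function(summaries, compliance, recs, note) {
  recNames <- recommendationEntries(recs)$name
  weekly <- compliance[compliance$scope == "weekly", ]
  rows <- NULL
  ob <- summaries$centralObesity[match(weekly$id, summaries$id)]
  for (rn in recNames) {
    meets <- weekly[[rn]]
    keep <- !is.na(meets) & !is.na(ob)
    tab <- table(factor(meets[keep], c(TRUE, FALSE)),
                 factor(ob[keep], c(TRUE, FALSE)))
    row <- tryCatch({
      chi <- chiSquareTest(tab)
      data.frame(recommendation = rn, test = "chi-square vs central obesity",
                 statistic = chi$statistic, p = chi$p,
                 estimate = phiCoefficient(t(tab)))
    }, error = function(e) {
      note(stage = "stats", recommendation = rn,
           reason = conditionMessage(e))
      NULL
    })
    rows <- rbind(rows, row)
  }
  # paired day-type contrasts
  for (rn in recNames) {
    for (pair in list(c("schoolPE", "schoolNoPE"),
                      c("schoolPE", "weekend"),
                      c("schoolNoPE", "weekend"))) {
      f1 <- compliance[compliance$scope == pair[1], rn]
      f2 <- compliance[compliance$scope == pair[2], rn]
      keep <- !is.na(f1) & !is.na(f2)
      b <- sum(f1[keep] & !f2[keep]); c_ <- sum(!f1[keep] & f2[keep])
      mt <- mcnemarTest(b, c_)
      rows <- rbind(rows, data.frame(
        recommendation = rn,
        test = sprintf("McNemar %s vs %s", pair[1], pair[2]),
        statistic = mt$statistic, p = mt$p,
        estimate = discordantOR(b, c_)$or))
    }
  }
  rows
}

writePipelineOutputs <- function(results, cfg, outDir) {
  fp <- function(x) file.path(outDir, x)
  utils::write.csv(results$participants, fp("participants.csv"),
                   row.names = FALSE)
  days <- do.call(rbind, results$days)
  if (!is.null(days))
    utils::write.table(days, fp("days.tsv"), sep = "\t", row.names = FALSE)
  if (nrow(results$summaries))
    utils::write.table(results$summaries, fp("summaries.tsv"), sep = "\t",
                       row.names = FALSE)
  yaml::write_yaml(list(
    configHash = results$configHash,
    granularity = results$recommendations@granularity,
    entries = lapply(seq_len(nrow(recommendationEntries(results$recommendations))),
                     function(i) as.list(recommendationEntries(results$recommendations)[i, ]))),
    fp("recommendations.yaml"))
  if (!is.null(results$compliance))
    utils::write.table(results$compliance, fp("compliance.tsv"), sep = "\t",
                       row.names = FALSE)
  if (!is.null(results$stats))
    utils::write.table(results$stats, fp("stats.tsv"), sep = "\t",
                       row.names = FALSE)
  writeConfig(cfg, fp("config.yaml"))
  con <- file(fp("log.jsonl"), "w")
  for (l in results$log)
    writeLines(jsonlite::toJSON(l, auto_unbox = TRUE), con)
  close(con)
  invisible(outDir)
}

#' Human-readable pipeline report
#'
#' Renders the run's tables for eyeball comparison: valid-day statistics by
#' day type (participants, min, max, total, mean, SD), weekly activity
#' means by sex, ROC threshold results and compliance percentages. Missing
#' sections are skipped with a notice.
#'
#' @param results the list returned by [runPipeline()].
#' @return The report lines, invisibly; also printed.
#' @export
generateReport <- function(results) {
  out <- c("== actikids pipeline report ==",
           sprintf("config hash: %s", results$configHash), "")
  days <- do.call(rbind, results$days)
  if (!is.null(days) && nrow(days)) {
    out <- c(out, "Valid days by type (participants, min, max, total, mean, SD):")
    v <- days[days$valid | days$dayType %in% c("holiday", "absence"), ]
    types <- c(all = NA, schoolPE = "schoolPE", schoolNoPE = "schoolNoPE",
               weekend = "weekend", holiday = "holiday", absence = "absence")
    for (ty in names(types)) {
      sel <- if (ty == "all") v[v$valid, ] else v[v$dayType == types[[ty]], ]
      if (!nrow(sel)) next
      perChild <- table(sel$id)
      out <- c(out, sprintf(
        "  %-11s n=%3d min=%d max=%d total=%d mean=%.1f sd=%.1f", ty,
        length(perChild), min(perChild), max(perChild), sum(perChild),
        mean(perChild), stats::sd(perChild)))
    }
    out <- c(out, "")
  } else out <- c(out, "[no day records]", "")
  s <- results$summaries
  if (!is.null(s) && nrow(s)) {
    sexes <- intersect(c("male", "female"), unique(s$sex))
    out <- c(out, "Weekly physical activity (min/day, mean (SD)):")
    for (b in BANDS6) {
      line <- sprintf("  %-6s", toupper(b))
      for (sx in sexes) {
        v <- s[[paste0(b, "Weekly")]][s$sex == sx]
        line <- paste0(line, sprintf(" %s %.1f (%.1f)", sx, mean(v),
                                     stats::sd(v)))
      }
      out <- c(out, line)
    }
    out <- c(out, "")
  } else out <- c(out, "[no participant summaries]", "")
  if (!is.null(results$roc)) {
    out <- c(out, "ROC thresholds (Youden):")
    for (nm in names(results$roc)) {
      r <- results$roc[[nm]]
      out <- c(out, sprintf(
        "  %-12s AUC %.2f (%.2f-%.2f) J %.3f threshold %.1f sens %.0f%% spec %.0f%%",
        nm, auc(r$curve), r$curve@aucCI[1], r$curve@aucCI[2], r$youden$J,
        r$youden$threshold, 100 * r$youden$sensitivity,
        100 * r$youden$specificity))
    }
    out <- c(out, "")
  } else out <- c(out, "[no ROC section]", "")
  if (!is.null(results$compliance)) {
    recNames <- recommendationEntries(results$recommendations)$name
    out <- c(out, "Compliance (% meeting, by scope):")
    for (rn in recNames) {
      line <- sprintf("  %-12s", rn)
      for (sc in unique(results$compliance$scope)) {
        f <- results$compliance[results$compliance$scope == sc, rn]
        line <- paste0(line, sprintf(" %s %.0f%% (n=%d)", sc,
                                     100 * mean(f, na.rm = TRUE),
                                     sum(!is.na(f))))
      }
      out <- c(out, line)
    }
  } else out <- c(out, "[no compliance section]")
  cat(out, sep = "\n")
  invisible(out)
}
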