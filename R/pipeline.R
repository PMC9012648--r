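#' @include AllClasses.R simulate.R preprocess.R rereference.R metrics.R edf.R
NULL

#' Default experiment configuration
#'
#' One seeded configuration reproducing the full study grid: 10 subjects,
#' a rate series (10/25/50/100 per s at 75 dB nHL) and a level series
#' (45-80 dB nHL in 5 dB steps at 25/s), 4000 clicks per trial, two trials
#' per condition, all three reference methods scored at Cz.
#'
#' @param seed master RNG seed.
#' @param ... named overrides of any default field.
#' @return a list of class `runConfig`.
#' @export
defaultRunConfig <- function(seed = 20220408, ...) {
  cfg <- list(
    seed = as.integer(seed),
    nSubjects = 10L,
    rateGrid = c(10, 25, 50, 100), rateGridLevel = 75,
    levelGrid = seq(45, 80, by = 5), levelGridRate = 25,
    conditions = NULL,            # data.frame(rate, level) overrides grids
    nStimuli = 4000L, trials = 2L,
    methods = c("AR", "REST", "MM"),
    channel = "Cz",
    fsHz = 20000, nSources = 500L, nNoiseDipoles = 16L,
    noise = TRUE, subjectJitter = TRUE,
    bandpassHz = c(100, 1500), filterOrder = 3L,
    fastPipeline = TRUE)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (is.null(cfg$conditions)) {
    cfg$conditions <- unique(rbind(
      data.frame(rate = cfg$rateGrid, level = cfg$rateGridLevel),
      data.frame(rate = cfg$levelGridRate, level = cfg$levelGrid)))
  }
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Any field of [defaultRunConfig()] may appear in the file; missing
#' fields take their defaults. A `conditions` entry may be given as a list
#' of `{rate, level}` pairs.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$conditions))
    y$conditions <- do.call(rbind, lapply(y$conditions, as.data.frame))
  if (!is.null(seed)) y$seed <- seed
  do.call(defaultRunConfig, c(list(seed = if (!is.null(y$seed)) y$seed
                                   else 20220408),
                              y[setdiff(names(y), "seed")]))
}

# process one acquired recording into per-method measurements; the
# filter / epoch / average steps run once (they commute with the purely
# spatial re-referencing, which is applied to the short averaged
# waveform; equivalence is covered by the test suite)
.processRecording <- function(rec, info, config, restTransform, midline) {
  base <- if (isTRUE(config$fastPipeline)) {
    .filteredEpochAverage(rec, config$bandpassHz[1], config$bandpassHz[2],
                          config$filterOrder)
  } else {
    filt <- bandpassFilter(rec, config$bandpassHz[1], config$bandpassHz[2],
                           config$filterOrder)
    averageEpochs(extractEpochs(filt))
  }
  out <- list(peaks = list(), waveforms = list(), nEpochs = NA_integer_)
  for (m in config$methods) {
    avg <- tryCatch(
      applyReference(base, m, restTransform = restTransform),
      error = function(e) {
        warning("method ", m, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(avg)) next
    out$nEpochs <- avg@nAveraged
    wp <- detectWaves(avg, config$channel, info$rate, info$level)
    out$peaks[[m]] <- cbind(
      data.frame(subject = info$subject, rate = info$rate,
                 level = info$level, trial = info$trial, method = m),
      wp@peaks)
    keep <- intersect(c(midline, config$channel), avg@channelNames)
    out$waveforms[[m]] <- avg@data[keep, , drop = FALSE]
  }
  out
}

#' Run the full synthetic experiment
#'
#' Orchestrates simulate, filter, epoch, average, re-reference (AR / REST /
#' MM) and wave scoring over the configured condition grid, and assembles
#' the cross-subject summary tables, duplicate-trial repeatability and the
#' ground-truth-vs-measured comparison. With `outDir` set, writes CSV
#' reports (midline grand-average waveforms per condition and method,
#' amplitude and interwave summary tables, per-waveform peaks), a JSON
#' ground-truth comparison, advisory PNG plots, the resolved configuration
#' and a run log. Subjects are processed independently; a failing condition
#' is logged and skipped, not fatal.
#'
#' @param config a `runConfig` list from [defaultRunConfig()].
#' @param outDir optional output directory.
#' @param template an [AbrTemplate-class].
#' @param montage a [Montage-class].
#' @param head a [HeadModel-class].
#' @param verbose print progress to stderr.
#' @return a list of class `abrExperiment` with elements `peaks`
#'   (data.frame), `summaries` (per-condition [AbrSummary-class]),
#'   `repeatability` (data.frame), `groundTruth`, `comparison` (measured
#'   minus true latencies), `waveforms`, `config`, `log`.
#' @export
runExperiment <- function(config = defaultRunConfig(), outDir = NULL,
                          template = defaultAbrTemplate(),
                          montage = standardMontage(), head = headModel(),
                          verbose = interactive()) {
  t0 <- Sys.time()
  logLines <- c(sprintf("seed: %d", config$seed),
                sprintf("R version: %s", getRversion()),
                sprintf("start: %s", format(t0, "%Y-%m-%d %H:%M:%S")))
  say <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    if (verbose) message(msg)
  }
  lf <- computeLeadField(montage, head, sourceLayer(head, config$nSources))
  rt <- buildRestTransform(lf)
  midline <- midlineChannels(montage)
  peaks <- list(); waveforms <- list(); gt <- NULL
  say("lead field ready (%d channels, %d sources)", length(lf@channels),
      nrow(lf@layer@locations))

  for (ci in seq_len(nrow(config$conditions))) {
    rate <- config$conditions$rate[ci]
    level <- config$conditions$level[ci]
    condKey <- sprintf("r%g_l%g", rate, level)
    res <- tryCatch({
      scfg <- sessionConfig(
        seed = config$seed, nSubjects = config$nSubjects,
        conditions = data.frame(rate = rate, level = level),
        nStimuli = config$nStimuli, trials = config$trials,
        noise = config$noise, fsHz = config$fsHz,
        nSources = config$nSources, nNoiseDipoles = config$nNoiseDipoles,
        subjectJitter = config$subjectJitter)
      ses <- simulateSession(
        scfg, template = template, montage = montage, head = head,
        leadfield = lf,
        process = function(rec, info)
          .processRecording(rec, info, config, rt, midline))
      ses
    }, error = function(e) {
      say("condition %s FAILED: %s", condKey, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    gt <- rbind(gt, res$groundTruth)
    for (s in seq_len(config$nSubjects)) {
      for (tr in seq_len(config$trials)) {
        pr <- res$recordings[[condKey]][[s]][[tr]]
        peaks <- c(peaks, pr$peaks)
        waveforms[[sprintf("%s_s%d_t%d", condKey, s, tr)]] <- pr$waveforms
      }
    }
    say("condition %s done (%.1f s elapsed)", condKey,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL

  # per-condition cross-subject summaries (first trial of each subject)
  summaries <- list()
  for (ci in seq_len(nrow(config$conditions))) {
    rate <- config$conditions$rate[ci]; level <- config$conditions$level[ci]
    sel <- peaks[peaks$rate == rate & peaks$level == level &
                 peaks$trial == 1L, ]
    if (nrow(sel) > 0 && length(unique(sel$subject)) >= 2)
      summaries[[sprintf("r%g_l%g", rate, level)]] <- summarizePeaks(sel)
  }

  # duplicate-trial repeatability from stored waveforms
  repeatRows <- list()
  if (config$trials >= 2) {
    for (ci in seq_len(nrow(config$conditions))) {
      rate <- config$conditions$rate[ci]; level <- config$conditions$level[ci]
      for (s in seq_len(config$nSubjects)) {
        k1 <- sprintf("r%g_l%g_s%d_t1", rate, level, s)
        k2 <- sprintf("r%g_l%g_s%d_t2", rate, level, s)
        if (is.null(waveforms[[k1]]) || is.null(waveforms[[k2]])) next
        for (m in names(waveforms[[k1]])) {
          w1 <- waveforms[[k1]][[m]]; w2 <- waveforms[[k2]][[m]]
          repeatRows[[length(repeatRows) + 1L]] <- data.frame(
            subject = s, rate = rate, level = level, method = m,
            correlation = stats::cor(w1[config$channel, ],
                                     w2[config$channel, ]))
        }
      }
    }
  }
  repeatability <- if (length(repeatRows)) do.call(rbind, repeatRows)
    else data.frame()

  # measured vs ground-truth latency comparison
  comparison <- NULL
  if (!is.null(gt) && nrow(peaks)) {
    mp <- merge(peaks[peaks$found, ],
                stats::setNames(gt, c("subject", "rate", "level", "wave",
                                      "true_latency_ms")),
                by = c("subject", "rate", "level", "wave"))
    mp$latency_error_ms <- mp$latency_ms - mp$true_latency_ms
    comparison <- mp[order(mp$rate, mp$level, mp$subject, mp$method,
                           mp$wave), ]
    rownames(comparison) <- NULL
  }

  say("total runtime: %.1f s", as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  result <- list(peaks = peaks, summaries = summaries,
                 repeatability = repeatability, groundTruth = gt,
                 comparison = comparison, waveforms = waveforms,
                 config = config, log = logLines)
  class(result) <- "abrExperiment"
  if (!is.null(outDir)) .writeReport(result, outDir)
  result
}

# round for stable 6-significant-digit CSV output
.sig6 <- function(d) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], 6)
  d
}

.writeReport <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  utils::write.csv(.sig6(result$peaks), file.path(outDir, "peaks.csv"),
                   row.names = FALSE)
  if (!is.null(result$comparison))
    jsonlite::write_json(.sig6(result$comparison),
                         file.path(outDir, "ground_truth_comparison.json"),
                         digits = NA, auto_unbox = TRUE)
  amp <- list(); iw <- list()
  for (key in names(result$summaries)) {
    s <- result$summaries[[key]]
    a <- s@amplitudes; a$condition <- key
    i <- s@interwave; i$condition <- key
    amp[[key]] <- a; iw[[key]] <- i
  }
  if (length(amp)) {
    utils::write.csv(.sig6(do.call(rbind, amp)),
                     file.path(outDir, "summary_amplitudes.csv"),
                     row.names = FALSE)
    utils::write.csv(.sig6(do.call(rbind, iw)),
                     file.path(outDir, "summary_interwave.csv"),
                     row.names = FALSE)
  }
  if (nrow(result$repeatability))
    utils::write.csv(.sig6(result$repeatability),
                     file.path(outDir, "repeatability.csv"),
                     row.names = FALSE)
  # grand-average midline waveforms per condition x method
  wfDir <- file.path(outDir, "waveforms")
  dir.create(wfDir, showWarnings = FALSE)
  conds <- unique(sub("_s[0-9]+_t[0-9]+$", "", names(result$waveforms)))
  for (cond in conds) {
    sel <- result$waveforms[grep(paste0("^", cond, "_s[0-9]+_t"),
                                 names(result$waveforms))]
    if (!length(sel)) next
    methods <- names(sel[[1]])
    for (m in methods) {
      mats <- lapply(sel, `[[`, m)
      mats <- mats[!vapply(mats, is.null, TRUE)]
      if (!length(mats)) next
      ga <- Reduce(`+`, mats) / length(mats)
      df <- data.frame(time_ms = (seq_len(ncol(ga)) - 1) / cfg$fsHz * 1000)
      for (ch in rownames(ga)) df[[ch]] <- ga[ch, ]
      utils::write.csv(.sig6(df),
                       file.path(wfDir, sprintf("%s_%s.csv", cond, m)),
                       row.names = FALSE)
    }
    # advisory plot: Cz by method
    suppressWarnings(tryCatch({
      grDevices::png(file.path(wfDir, sprintf("%s_Cz.png", cond)),
                     width = 800, height = 500)
      first <- TRUE
      cols <- c(AR = "black", REST = "red", MM = "blue")
      for (m in methods) {
        mats <- lapply(sel, `[[`, m)
        mats <- mats[!vapply(mats, is.null, TRUE)]
        ga <- Reduce(`+`, mats) / length(mats)
        tms <- (seq_len(ncol(ga)) - 1) / cfg$fsHz * 1000
        if (first) {
          graphics::plot(tms, ga[cfg$channel, ], type = "l",
                         col = cols[[m]], xlab = "time (ms)",
                         ylab = "amplitude (uV)",
                         main = sprintf("%s at %s", cond, cfg$channel))
          first <- FALSE
        } else graphics::lines(tms, ga[cfg$channel, ], col = cols[[m]])
      }
      graphics::legend("topright", legend = methods,
                       col = unname(cols[methods]), lty = 1)
      grDevices::dev.off()
    }, error = function(e) try(grDevices::dev.off(), silent = TRUE)))
  }
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "conditions")],
                   file.path(outDir, "config.yaml"))
  writeLines(result$log, file.path(outDir, "log.txt"))
  invisible(outDir)
}

#' Run the pipeline on a real EDF recording
#'
#' The same filter / re-reference / epoch / average / score chain as
#' [runExperiment()], applied to a continuous EDF recording with stimulus
#' annotations and an electrode-position file. Ground-truth comparisons do
#' not apply. If the positions file lacks mastoids, the MM method is
#' skipped with a warning; AR and REST are still produced.
#'
#' @param edfPath EDF file with stimulus annotations.
#' @param positionsPath electrode position file (label x y z per line);
#'   must cover every data channel used.
#' @param config a `runConfig`; `rate` and `level` of the single condition
#'   are taken from `config$conditions[1, ]`.
#' @param outDir optional report directory.
#' @param head a [HeadModel-class].
#' @return a list of class `abrExperiment` (single subject, no ground
#'   truth).
#' @export
runRealData <- function(edfPath, positionsPath, config = defaultRunConfig(),
                        outDir = NULL, head = headModel()) {
  rec <- readEdf(edfPath)
  if (!length(rec@events))
    stop("empty-epochs error: no stimulus annotations in ", edfPath,
         "; the EDF must carry one annotation per click onset")
  montage <- readMontageFile(positionsPath)
  missing <- setdiff(rec@channelNames, montage@labels)
  # channels without positions cannot enter the forward model
  if (length(missing)) {
    warning("channel(s) without electrode positions dropped: ",
            paste(missing, collapse = ", "))
    keep <- match(setdiff(rec@channelNames, missing), rec@channelNames)
    rec <- Recording(rec@data[keep, , drop = FALSE], rec@fsHz, rec@events,
                     rec@reference, rec@channelNames[keep])
  }
  montage <- subsetMontage(montage, rec@channelNames)
  methods <- config$methods
  roles <- electrodeRoles(montage)
  if (!all(c("mastoid_left", "mastoid_right") %in% roles) &&
      "MM" %in% methods) {
    warning("mastoid channel(s) missing: MM method skipped")
    methods <- setdiff(methods, "MM")
  }
  lf <- computeLeadField(montage, head, sourceLayer(head, config$nSources))
  rt <- buildRestTransform(lf, channels = rec@channelNames)
  cfg <- config
  cfg$methods <- methods
  rate <- config$conditions$rate[1]; level <- config$conditions$level[1]
  pr <- .processRecording(rec, list(subject = 1L, rate = rate, level = level,
                                    trial = 1L),
                          cfg, rt, midlineChannels(montage))
  peaks <- do.call(rbind, pr$peaks)
  result <- list(peaks = peaks, summaries = list(),
                 repeatability = data.frame(), groundTruth = NULL,
                 comparison = NULL,
                 waveforms = stats::setNames(
                   list(pr$waveforms), sprintf("r%g_l%g_s1_t1", rate, level)),
                 config = cfg,
                 log = sprintf("real-data run on %s (%d events, %d epochs)",
                               edfPath, length(rec@events), pr$nEpochs))
  class(result) <- "abrExperiment"
  if (!is.null(outDir)) .writeReport(result, outDir)
  result
}
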