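#' @include AllClasses.R constructors.R session-io.R behavior.R spiking.R decoding.R stats.R utils.R
NULL

## Orchestration: sessions -> behaviour fits -> rate tensors -> per-region
## early/late decoding -> jackknife. One global seed fans out to per-stage
## seeds through a fixed counter scheme (.deriveSeed), so any stage can be
## rerun in isolation with the same result.

.SEED_OFFSETS <- c(decode_mPFC_early = 11L, decode_mPFC_late = 12L,
                   decode_STR_early = 21L, decode_STR_late = 22L,
                   jackknife = 31L)

#' Run the full analysis pipeline
#'
#' Loads the listed session manifests, fits the double-Gaussian duration
#' model and early/late behaviour summary per animal, builds reinforced-trial
#' rate tensors per region, decodes elapsed time early and late in the
#' session for each region present, runs the jackknife early-vs-late
#' comparison per region when at least 3 animals contribute units, and
#' writes all results as JSON/CSV into a run directory together with a
#' machine-readable log carrying the config hash and seed. Rerunning with
#' the same inputs and seed reproduces the outputs byte for byte.
#'
#' @param manifests character vector of session-manifest paths (all for the
#'   same training day); checked before any computation starts.
#' @param outDir run directory (created; existing files overwritten).
#' @param task a [TaskConfig-class]
#' @param decoder a [DecoderConfig-class]; its seed is ignored in favour of
#'   per-stage seeds derived from `seed`.
#' @param seed global integer seed.
#' @return `outDir`, invisibly; side effect: the artifact files.
#' @export
runPipeline <- function(manifests, outDir, task = TaskConfig(),
                        decoder = DecoderConfig(), seed = 1) {
  missing <- manifests[!file.exists(manifests)]
  if (length(missing) > 0)
    .stopf("pre-flight check failed: missing manifest '%s'", missing[1])
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  res <- tryCatch({
    sessions <- lapply(manifests, readSessionManifest)
    names(sessions) <- vapply(sessions, function(s) as.character(s$animal),
                              character(1))
    ## behaviour
    stage <- "behavior"
    behav <- lapply(sessions, function(s) {
      fit <- tryCatch(fitDoubleGaussian(durations(s$trials)),
                      error = function(e) NULL)
      sp <- splitEarlyLate(s$trials)
      list(animal = s$animal,
           n_trials = nTrials(s$trials),
           mean_early = mean(durations(sp$early)),
           mean_late = mean(durations(sp$late)),
           params = if (!is.null(fit)) list(
             gamma = fit$params@gamma, mu1 = fit$params@mu1,
             sigma1 = fit$params@sigma1, mu2 = fit$params@mu2,
             sigma2 = fit$params@sigma2,
             residual_norm = fit$residualNorm, n = fit$n) else NULL)
    })
    jsonlite::write_json(unname(behav), file.path(outDir, "behavior.json"),
                         auto_unbox = TRUE, digits = NA)
    ## rate tensors per animal x region over reinforced trials
    stage <- "rates"
    window <- c(0, task@criterion)
    tensors <- list(mPFC = list(), STR = list())
    climbing <- NULL
    for (a in names(sessions)) {
      s <- sessions[[a]]
      reinforced <- selectReinforced(s$trials, s$task)
      if (nTrials(reinforced) < 2) next
      stages <- splitEarlyLate(reinforced)
      for (region in .VALID_REGIONS) {
        sel <- s$spikes@units$region == region
        if (!any(sel)) next
        sub <- SpikeTrainSet(s$spikes@units[sel, , drop = FALSE],
                             s$spikes@spikes[sel])
        ep <- epochTrials(sub, reinforced, alignment = "onset", task = task)
        tensors[[region]][[a]] <- rateTensor(ep, window, task = task)
        taskUnsmoothed <- task
        taskUnsmoothed@kernelSigma <- 0  # independent bins for the slope test
        for (st in c("early", "late")) {
          eps <- epochTrials(sub, stages[[st]], alignment = "onset",
                             task = task)
          cl <- detectClimbing(rateTensor(eps, window, task = taskUnsmoothed))
          cl$stage <- st
          climbing <- rbind(climbing, cl)
        }
      }
    }
    if (!is.null(climbing))
      utils::write.csv(climbing, file.path(outDir, "climbing.csv"),
                       row.names = FALSE)
    ## decoding + jackknife per region
    stage <- "decode"
    for (region in .VALID_REGIONS) {
      rts <- tensors[[region]]
      if (length(rts) == 0) next
      pop <- buildPseudoPopulation(rts, decoder)
      for (st in c("early", "late")) {
        cfg <- decoder
        cfg@seed <- .deriveSeed(seed, .SEED_OFFSETS[[paste("decode", region,
                                                           st, sep = "_")]])
        dr <- decodeStage(pop, st, cfg)
        out <- list(region = region, stage = st, mean_R = dr@meanR,
                    sd_R = dr@sdR, ci_mean = dr@ciMean,
                    n_folds = dr@nFolds, n_trials = dr@nTrials,
                    n_units = dr@nUnits)
        jsonlite::write_json(out, file.path(outDir,
                                            sprintf("decode_%s_%s.json",
                                                    region, st)),
                             auto_unbox = TRUE, digits = NA)
        utils::write.csv(confusionMatrix(dr),
                         file.path(outDir, sprintf("confusion_%s_%s.csv",
                                                   region, st)),
                         row.names = FALSE)
      }
      stage <- "jackknife"
      if (length(rts) >= 3) {
        statFn <- function(subset, condition, sd) {
          cfg <- decoder
          cfg@seed <- .deriveSeed(sd, .SEED_OFFSETS[["jackknife"]])
          subPop <- buildPseudoPopulation(rts[subset], cfg)
          meanR(decodeStage(subPop, condition, cfg))
        }
        jk <- tryCatch(jackknifeCompare(statFn, names(rts), "early", "late",
                                        seed = seed),
                       error = function(e) NULL)
        if (!is.null(jk))
          jsonlite::write_json(
            list(region = region, raw_t = jk@rawT, corrected_t = jk@correctedT,
                 df = jk@df, p = jk@p, values = jk@values),
            file.path(outDir, sprintf("jackknife_%s.json", region)),
            auto_unbox = TRUE, digits = NA)
      }
    }
    TRUE
  }, error = function(e) {
    .stopf("pipeline failed at stage '%s' (inputs: %s): %s", stage,
           paste(basename(manifests), collapse = ", "), conditionMessage(e))
  })
  ## run log with config hash
  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(
    list(manifests = basename(manifests), seed = seed,
         task = list(criterion = task@criterion, upper_cap = task@upperCap,
                     pre_onset = task@preOnset, bin_width = task@binWidth,
                     kernel_sigma = task@kernelSigma),
         decoder = list(n_folds = decoder@nFolds,
                        train_fraction = decoder@trainFraction,
                        n_classes = decoder@nClasses,
                        drop_first = decoder@dropFirst,
                        drop_last = decoder@dropLast)),
    cfgFile, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed, config_hash = unname(tools::md5sum(cfgFile)),
         artifacts = sort(setdiff(list.files(outDir), "run_log.json"))),
    file.path(outDir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Summarise a completed pipeline run
#'
#' Pure function of the run directory (no RNG): collects the decoder
#' performance per region and stage, the per-animal double-Gaussian
#' parameters and the climbing-unit counts into CSV tables and a markdown
#' summary. Missing artifacts are listed rather than raising an error.
#'
#' @param runDir directory produced by [runPipeline()].
#' @return list with `decode` (data.frame or NULL), `behavior`, `climbing`,
#'   `missing` (character); side effect: `report.md` and `report_*.csv` in
#'   `runDir`.
#' @export
reportRun <- function(runDir) {
  if (!dir.exists(runDir)) .stopf("run directory '%s' does not exist", runDir)
  missing <- character(0)
  decode <- NULL
  for (region in .VALID_REGIONS) for (st in c("early", "late")) {
    f <- file.path(runDir, sprintf("decode_%s_%s.json", region, st))
    if (file.exists(f)) {
      d <- jsonlite::read_json(f, simplifyVector = TRUE)
      decode <- rbind(decode, data.frame(region = region, stage = st,
                                         mean_R = d$mean_R, sd_R = d$sd_R,
                                         ci_lo = d$ci_mean[1],
                                         ci_hi = d$ci_mean[2]))
    } else missing <- c(missing, basename(f))
  }
  behavior <- NULL
  bf <- file.path(runDir, "behavior.json")
  if (file.exists(bf)) {
    b <- jsonlite::read_json(bf)
    behavior <- do.call(rbind, lapply(b, function(x)
      data.frame(animal = x$animal, n_trials = x$n_trials,
                 mean_early = x$mean_early, mean_late = x$mean_late,
                 gamma = x$params$gamma %||% NA, mu1 = x$params$mu1 %||% NA,
                 sigma1 = x$params$sigma1 %||% NA,
                 mu2 = x$params$mu2 %||% NA,
                 sigma2 = x$params$sigma2 %||% NA)))
  } else missing <- c(missing, "behavior.json")
  climbing <- NULL
  cf <- file.path(runDir, "climbing.csv")
  if (file.exists(cf)) {
    cl <- utils::read.csv(cf)
    climbing <- stats::aggregate(flagged ~ animal + region + stage,
                                 data = cl, FUN = sum)
  } else missing <- c(missing, "climbing.csv")
  lines <- c("# Pipeline run report", "")
  if (length(missing) > 0)
    lines <- c(lines, "## Missing artifacts", "",
               paste0("- ", missing), "")
  if (!is.null(decode)) {
    utils::write.csv(decode, file.path(runDir, "report_decode.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Decoder performance (mean Pearson R)", "",
               "| region | stage | mean R | SD | 95% CI |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3f | [%.3f, %.3f] |",
                       decode$region, decode$stage, decode$mean_R,
                       decode$sd_R, decode$ci_lo, decode$ci_hi), "")
  }
  if (!is.null(behavior)) {
    utils::write.csv(behavior, file.path(runDir, "report_behavior.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Behaviour per animal", "",
               "| animal | trials | mean early (s) | mean late (s) | gamma | mu2 (s) |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d | %.3f | %.3f | %.3f | %.3f |",
                       behavior$animal, behavior$n_trials,
                       behavior$mean_early, behavior$mean_late,
                       behavior$gamma, behavior$mu2), "")
  }
  if (!is.null(climbing)) {
    utils::write.csv(climbing, file.path(runDir, "report_climbing.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Climbing units (flagged count)", "",
               "| animal | region | stage | n |", "|---|---|---|---|",
               sprintf("| %s | %s | %s | %d |", climbing$animal,
                       climbing$region, climbing$stage, climbing$flagged), "")
  }
  if (is.null(decode) && is.null(behavior) && is.null(climbing))
    lines <- c(lines, "No artifacts found.")
  writeLines(lines, file.path(runDir, "report.md"))
  list(decode = decode, behavior = behavior, climbing = climbing,
       missing = missing)
}
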