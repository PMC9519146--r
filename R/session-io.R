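#' @include AllClasses.R constructors.R utils.R
NULL

## On-disk layout: one CSV per session for trials
## (trial_id,onset,offset,rewarded) and one for spikes
## (unit_id,region,animal,spike_time), linked by a small JSON manifest.
## Floating-point fields are written with %.17g so that write -> read ->
## write is byte-identical.

.fmt <- function(x) sprintf("%.17g", x)

#' Read a behavioural trial table from CSV
#'
#' Expects a header with columns `trial_id`, `onset`, `offset`, `rewarded`
#' (0/1). `duration` is always recomputed as `offset - onset`; if the file
#' carries a `duration` column disagreeing by more than 1 ms, that is a
#' validation error.
#'
#' @param path CSV file path.
#' @return a [TrialTable-class]
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) .stopf("trials file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("trial_id", "onset", "offset", "rewarded"), path)
  bad <- which(df$offset <= df$onset)
  if (length(bad) > 0)
    .stopf("offset <= onset for trial %d in '%s'", df$trial_id[bad[1]], path)
  if ("duration" %in% names(df)) {
    dev <- abs(df$duration - (df$offset - df$onset))
    if (any(dev > 1e-3))
      .stopf("stored duration deviates from offset - onset by > 1 ms at trial %d",
             df$trial_id[which(dev > 1e-3)[1]])
  }
  TrialTable(trial_id = df$trial_id, onset = df$onset, offset = df$offset,
             rewarded = as.logical(as.integer(df$rewarded)))
}

#' Write a trial table to CSV
#'
#' Inverse of [readTrials()]; numeric fields keep full precision so the
#' round trip is lossless.
#'
#' @param table a [TrialTable-class]
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrials <- function(table, path) {
  stopifnot(is(table, "TrialTable"))
  validObject(table)
  tr <- table@trials
  lines <- c("trial_id,onset,offset,rewarded",
             if (nrow(tr) > 0)
               sprintf("%d,%s,%s,%d", tr$trial_id, .fmt(tr$onset),
                       .fmt(tr$offset), as.integer(tr$rewarded)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("cannot write trials file '%s'", path)
  invisible(path)
}

#' Read sorted spike trains from CSV
#'
#' Expects columns `unit_id`, `region`, `animal`, `spike_time` (one row per
#' spike). The result is invariant to the row order of the file: units are
#' keyed by (animal, unit_id) and sorted, and spike times within a unit are
#' sorted ascending (a warning is issued if the file was unsorted).
#'
#' @param path CSV file path.
#' @return a [SpikeTrainSet-class]
#' @export
readSpikes <- function(path) {
  if (!file.exists(path)) .stopf("spikes file not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("unit_id", "region", "animal", "spike_time"), path)
  bad <- setdiff(unique(df$region), .VALID_REGIONS)
  if (length(bad) > 0)
    .stopf("unknown region label(s) in '%s': %s (expected %s)", path,
           paste(bad, collapse = ", "), paste(.VALID_REGIONS, collapse = "/"))
  if (nrow(df) == 0)
    return(SpikeTrainSet(data.frame(unit_id = integer(0),
                                    region = character(0),
                                    animal = character(0)), list()))
  df$animal <- as.character(df$animal)
  key <- paste(df$animal, df$unit_id, sep = "\r")
  ord <- order(df$animal, df$unit_id)
  ukey <- unique(key[ord])
  spikes <- vector("list", length(ukey))
  units <- data.frame(unit_id = integer(length(ukey)),
                      region = character(length(ukey)),
                      animal = character(length(ukey)),
                      stringsAsFactors = FALSE)
  unsorted <- FALSE
  idx <- split(seq_len(nrow(df)), factor(key, levels = ukey))
  for (j in seq_along(ukey)) {
    rows <- idx[[j]]
    st <- df$spike_time[rows]
    if (is.unsorted(st)) { unsorted <- TRUE; st <- sort(st) }
    spikes[[j]] <- st
    units$unit_id[j] <- df$unit_id[rows[1]]
    units$region[j] <- df$region[rows[1]]
    units$animal[j] <- df$animal[rows[1]]
  }
  if (unsorted)
    .warnf("spike times in '%s' were not sorted within units; sorted on load",
           path)
  SpikeTrainSet(units, spikes)
}

#' Write spike trains to CSV
#'
#' Inverse of [readSpikes()].
#'
#' @param spikes a [SpikeTrainSet-class]
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpikes <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeTrainSet"))
  validObject(spikes)
  u <- spikes@units
  lines <- "unit_id,region,animal,spike_time"
  for (j in seq_len(nrow(u))) {
    st <- spikes@spikes[[j]]
    if (length(st) > 0)
      lines <- c(lines, sprintf("%s,%s,%s,%s", u$unit_id[j], u$region[j],
                                u$animal[j], .fmt(st)))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("cannot write spikes file '%s'", path)
  invisible(path)
}

#' Write a session manifest
#'
#' Small JSON file linking a session's trials and spikes CSVs with animal,
#' day and task metadata.
#'
#' @param path output JSON path.
#' @param animal animal id label.
#' @param day session day (integer).
#' @param trialsFile,spikesFile file names relative to the manifest.
#' @param task a [TaskConfig-class]
#' @return `path`, invisibly.
#' @export
writeSessionManifest <- function(path, animal, day, trialsFile, spikesFile,
                                 task = TaskConfig()) {
  m <- list(animal = animal, day = as.integer(day),
            session_files = list(trials = trialsFile, spikes = spikesFile),
            task = list(criterion = task@criterion, upper_cap = task@upperCap))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session manifest and its linked files
#'
#' @param path manifest JSON path; the trials/spikes files it names are
#'   resolved relative to the manifest's directory.
#' @return list with elements `animal`, `day`, `trials` ([TrialTable-class]),
#'   `spikes` ([SpikeTrainSet-class]) and `task` ([TaskConfig-class]).
#' @export
readSessionManifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest not found: '%s'", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  task <- TaskConfig(criterion = m$task$criterion, upperCap = m$task$upper_cap)
  list(animal = m$animal, day = m$day,
       trials = readTrials(file.path(dir, m$session_files$trials)),
       spikes = readSpikes(file.path(dir, m$session_files$spikes)),
       task = task)
}

#' Validate a loaded session
#'
#' Report-only consistency check of a behavioural table against its spike
#' trains: trial and unit counts, units per region, and the fraction of
#' spikes falling inside the session span
#' \[first onset - preOnset, last offset\].
#'
#' @param trials a [TrialTable-class]
#' @param spikes a [SpikeTrainSet-class]
#' @param task a [TaskConfig-class]
#' @return list with `n_trials`, `units_per_region`, `fraction_in_session`,
#'   `issues` (character vector; empty when clean).
#' @export
validateSession <- function(trials, spikes, task = TaskConfig()) {
  stopifnot(is(trials, "TrialTable"), is(spikes, "SpikeTrainSet"))
  tr <- trials@trials
  allSpikes <- unlist(spikes@spikes, use.names = FALSE)
  issues <- character(0)
  perRegion <- table(factor(spikes@units$region, levels = .VALID_REGIONS))
  frac <- NA_real_
  if (nrow(tr) > 0 && length(allSpikes) > 0) {
    lo <- tr$onset[1] - task@preOnset
    hi <- tr$offset[nrow(tr)]
    frac <- mean(allSpikes >= lo & allSpikes <= hi)
    if (frac == 0)
      issues <- c(issues, "no spikes inside the session span")
    else if (frac < 0.5)
      issues <- c(issues, sprintf(
        "only %.1f%% of spikes inside the session span", 100 * frac))
    rw <- which(tr$rewarded & tr$duration < task@criterion)
    if (length(rw) > 0)
      issues <- c(issues, sprintf(
        "trial %d rewarded but shorter than the %.2f s criterion",
        tr$trial_id[rw[1]], task@criterion))
  }
  if (nrow(spikes@units) == 0)
    issues <- c(issues, "spike set contains no units")
  list(n_trials = nrow(tr),
       units_per_region = as.list(as.integer(perRegion)) |>
         stats::setNames(names(perRegion)),
       fraction_in_session = frac,
       issues = issues)
}
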