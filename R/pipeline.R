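# Pipeline orchestration: one configuration object drives simulate ->
# preprocess -> bin -> CMPT (-> NM -> Monte Carlo), with every output file
# carrying the configuration and seed for provenance.

#' Pipeline run configuration
#'
#' @param seed integer; every random stage draws from it.
#' @param outDir output directory (created if absent).
#' @param tasks tasks to analyze at single-participant level.
#' @param sim a \code{\link{simConfig}}.
#' @param nPerm permutations for the single-level CMPTs.
#' @param writeRecording write the synthesized recording as EDF (default
#'   FALSE; the file is large).
#' @param computeNM also compute the participant's NM table using the AT
#'   CMPT's selected region.
#' @param monteCarlo optional \code{\link{mcConfig}} to run on the AT pools.
#' @param filterBand band-pass edges in Hz.
#' @param artifacts \code{\link{artifactCriteria}}, or NULL to skip
#'   rejection.
#' @param gap_s inter-stream gap in the synthesized recording (seconds).
#' @return list of class "RunConfig".
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("battery_run_"),
                      tasks = c("AT", "WM", "AR"), sim = simConfig(),
                      nPerm = 500, writeRecording = FALSE,
                      computeNM = FALSE, monteCarlo = NULL,
                      filterBand = c(0.5, 10),
                      artifacts = artifactCriteria(), gap_s = 1) {
  if (!length(tasks)) stop("at least one task must be selected")
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(list(seed = as.integer(seed), outDir = outDir, tasks = tasks,
                 sim = sim, nPerm = nPerm, writeRecording = writeRecording,
                 computeNM = computeNM, monteCarlo = monteCarlo,
                 filterBand = filterBand, artifacts = artifacts,
                 gap_s = gap_s),
            class = "RunConfig")
}

#' Serialize a CMPT result to JSON
#'
#' Clusters are reported with electrode names and time ranges in
#' milliseconds, with mass, permutation p, threshold, permutation count and
#' seed.
#'
#' @param result a \linkS4class{CMPTResult}.
#' @param path output path.
#' @param seed seed recorded for provenance.
#' @return \code{path}, invisibly.
#' @export
writeCMPTResult <- function(result, path, seed = NA_integer_) {
  cl <- clusterTable(result)
  clusters <- lapply(seq_len(nrow(cl)), function(i) {
    memb <- result@membership == cl$id[i]
    list(mass = cl$mass[i], sign = cl$sign[i], p = cl$p[i],
         size = cl$size[i],
         time_ms = c(1000 * cl$t_start[i], 1000 * cl$t_end[i]),
         electrodes = result@channels[apply(memb, 1, any)])
  })
  doc <- list(level = result@level, p = pValue(result),
              threshold = result@threshold, n_perm = result@nPerm,
              alpha = result@alpha, seed = seed, clusters = clusters)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Simulates one participant under the configuration, preprocesses the
#' recording (band-pass, epoch, baseline, optional artifact rejection), bins
#' each selected task and runs its single-level CMPT, then optionally
#' computes the NM table (region = the AT CMPT's selected region) and the
#' Monte Carlo sensitivity curve. All outputs and a manifest land in
#' \code{cfg$outDir}; identical configurations and seeds reproduce them
#' byte-identically.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with the in-memory results (schedule, behavior, epochs,
#'   cmpt per task, nm, mc) and \code{outDir}.
#' @export
runPipeline <- function(cfg = runConfig()) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)

  schedule <- buildSchedule(seed = cfg$seed)
  writeSchedule(schedule, out("schedule.json"))
  ev <- scheduleEvents(schedule, gap_s = cfg$gap_s)
  writeEvents(ev, out("events.tsv"))

  set.seed(cfg$seed)
  agent <- simulateAgent(schedule, cfg$sim)
  utils::write.table(agent, out("behavior.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rec <- synthesizeRecording(schedule, agent, cfg$sim, gap_s = cfg$gap_s)
  if (cfg$writeRecording) writeEDF(rec, out("recording.edf"))

  rec <- bandpassFilter(rec, cfg$filterBand[1], cfg$filterBand[2])
  epochs <- baselineCorrect(epochRecording(rec))
  rejection <- NULL
  if (!is.null(cfg$artifacts)) {
    rj <- rejectArtifacts(epochs, cfg$artifacts)
    epochs <- rj$epochs
    rejection <- rj$report
    jsonlite::write_json(rejection[c("n_input", "n_retained", "n_rejected",
                                     "by_criterion")],
                         out("rejection_report.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  adjacency <- buildAdjacency()
  results <- list()
  for (task in cfg$tasks) {
    b <- binSession(epochs, schedule, task)
    set.seed(cfg$seed + match(task, c("AT", "WM", "AR")))
    res <- cmptSingle(epochs, b$positive, b$negative, adjacency,
                      nPerm = cfg$nPerm)
    writeCMPTResult(res, out(paste0("cmpt_", tolower(task), ".json")),
                    seed = cfg$seed)
    results[[task]] <- res
  }

  nm <- NULL
  if (cfg$computeNM) {
    if (is.null(results$AT) || !any(selectedRegion(results$AT)))
      warning("no significant AT region; NM skipped")
    else {
      nm <- computeNM(epochs, schedule, agent, selectedRegion(results$AT))
      utils::write.table(nm, out("nm.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  mc <- NULL
  if (!is.null(cfg$monteCarlo)) {
    pools <- binAttendedByBehavior(epochs, agent)
    set.seed(cfg$seed + 100L)
    mc <- mcCurve(epochs, pools$attended, pools$unattended, cfg$monteCarlo,
                  adjacency)
    utils::write.table(mc, out("mc_curve.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  manifest <- list(
    package = "p300battery",
    version = as.character(utils::packageVersion("p300battery")),
    seed = cfg$seed, tasks = cfg$tasks,
    filter_band_hz = cfg$filterBand, n_perm = cfg$nPerm,
    gap_s = cfg$gap_s,
    sim = cfg$sim[c("p300Amplitude", "p300Latency_s", "p300Width_s",
                    "noiseSD", "noiseModel", "ar1Coef", "accuracyAR",
                    "countAccuracy", "samplingRate")],
    p_values = lapply(results, pValue)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  list(schedule = schedule, behavior = agent, epochs = epochs,
       cmpt = results, nm = nm, mc = mc, rejection = rejection,
       outDir = cfg$outDir)
}
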