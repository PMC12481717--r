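#' Default run configuration
#'
#' A fully serializable list of every pipeline parameter. One global seed fans
#' out deterministically to per-stage seeds (hash of stage name + seed), so a
#' run's config + seed reproduces its outputs.
#'
#' @param seed global seed.
#' @param outDir output directory.
#' @param nPerGroup,trialsPerLevel cohort size knobs (defaults 8 and 20 give a
#'   demonstration-scale run; the full study design is 36 and 80).
#' @param electrodes analysis electrodes.
#' @param cvElectrodes electrodes for the CV analysis.
#' @param ... overrides for any other field.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L, outDir = tempfile("tactileERP_run_"),
                      nPerGroup = 8, trialsPerLevel = 20,
                      electrodes = ANALYSIS_ELECTRODES,
                      cvElectrodes = c("FP2", "F3", "C4"), ...) {
  cfg <- list(
    seed = as.integer(seed), outDir = outDir,
    nPerGroup = nPerGroup, trialsPerLevel = trialsPerLevel,
    writeEDF = FALSE,
    preprocessing = list(low = 0.01, high = 12, order = 3,
                         tmin = -500, tmax = 1000,
                         baselineWindow = c(-500, 0), peakToPeakMax = 200,
                         zThreshold = 3.5),
    electrodes = electrodes,
    cvElectrodes = cvElectrodes,
    cv = list(windowWidth = 10, step = 1, span = c(0, 400),
              classifierSpan = c(200, 400)),
    statsComponent = "N200", statsElectrode = "F3",
    classifiers = c("SVM", "LDA", "ANN"),
    nFolds = 10)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> ERP quantification -> group statistics
#' and topographies -> sliding-window CV -> ICC reliability -> classification,
#' writing CSV tables, a YAML copy of the configuration and a JSON run
#' manifest (with parameters, kept/rejected trial counts and output file
#' hashes) to \code{config$outDir}.
#'
#' @param config a [runConfig()] (or path to a YAML file containing one).
#' @return list with all stage outputs and \code{manifest} (paths + md5 hashes),
#'   invisibly.
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    class(cfg) <- "RunConfig"
    config <- cfg
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$outDir)) stop("stage simulate: cannot create outDir")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  spec <- stage("simulate", cohortSpec(
    nPerGroup = config$nPerGroup, trialsPerLevel = config$trialsPerLevel,
    seed = deriveSeed(config$seed, "simulate")))
  templates <- componentTemplates(spec$montage)
  effects <- groupEffectSpec()
  cohort <- stage("simulate", simulateCohort(spec, templates, effects))
  if (isTRUE(config$writeEDF))
    stage("write", writeDataset(cohort, file.path(config$outDir, "edf")))

  pp <- config$preprocessing
  kept <- integer(0); rejected <- integer(0)
  evoked <- stage("preprocess+erp", {
    lapply(cohort$recordings, function(r) {
      ep <- preprocessRecording(r, low = pp$low, high = pp$high,
                                order = pp$order, tmin = pp$tmin,
                                tmax = pp$tmax,
                                baselineWindow = pp$baselineWindow,
                                peakToPeakMax = pp$peakToPeakMax,
                                zThreshold = pp$zThreshold,
                                montage = spec$montage)
      kept[r@subjectMeta$id] <<- sum(ep@keptMask)
      rejected[r@subjectMeta$id] <<- sum(!ep@keptMask)
      averageEvoked(ep)
    })
  })
  compTable <- stage("erp", buildComponentTable(
    evoked, electrodes = union(config$electrodes, config$cvElectrodes)))
  anc <- stage("stats", ancovaComponent(compTable, config$statsElectrode,
                                        config$statsComponent))
  topoDiff <- stage("stats", groupDifferenceTopomap(
    compTable, config$statsComponent, montage = spec$montage))
  cvTable <- stage("cv", cohortTotalCV(
    evoked, config$cvElectrodes, windowWidth = config$cv$windowWidth,
    step = config$cv$step, span = config$cv$span))
  cvCompare <- stage("cv", compareCVGroups(cvTable))
  icc <- stage("icc", rbind(
    featureReliabilityReport(compTable, cvTable, "ASD"),
    featureReliabilityReport(compTable, cvTable, "TD")))
  cvClassifier <- stage("cv", cohortTotalCV(
    evoked, config$cvElectrodes, windowWidth = config$cv$windowWidth,
    step = config$cv$step, span = config$cv$classifierSpan))
  sets <- list(
    erp_key_sites = c("FP2:P200:L3", "F3:N200:L3", "C4:P300:L3"),
    cv_200_400 = paste0("CV:", config$cvElectrodes))
  sweep <- stage("classify", featureSetSweep(
    compTable, cvClassifier, sets, classifiers = config$classifiers,
    nFolds = min(config$nFolds, config$nPerGroup),
    seed = deriveSeed(config$seed, "classify")))

  out <- list(config = config, manifestTable = cohort$manifest,
              componentTable = compTable, ancova = anc$results,
              topoDiff = topoDiff, cvTable = cvTable, cvCompare = cvCompare,
              icc = icc, classification = sweep,
              trialCounts = data.frame(subject = names(kept), kept = kept,
                                       rejected = rejected, row.names = NULL))
  paths <- c(
    components = "components.csv", ancova = "ancova.csv",
    topo_diff = "topo_group_difference.csv", cv = "cv_totals.csv",
    cv_compare = "cv_group_tests.csv", icc = "icc.csv",
    classification = "classification.csv", trials = "trial_counts.csv")
  tabs <- list(compTable, anc$results, topoDiff, cvTable, cvCompare, icc,
               sweep, out$trialCounts)
  for (i in seq_along(paths))
    utils::write.csv(tabs[[i]], file.path(config$outDir, paths[i]),
                     row.names = FALSE)
  cfgPath <- file.path(config$outDir, "config.yaml")
  yaml::write_yaml(unclass(config), cfgPath)
  files <- file.path(config$outDir, paths)
  manifest <- data.frame(
    output = names(paths), path = files,
    md5 = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    stringsAsFactors = FALSE)
  manifestAll <- list(seed = config$seed,
                      config_md5 = unname(tools::md5sum(cfgPath)),
                      trials_kept = sum(kept), trials_rejected = sum(rejected),
                      outputs = manifest)
  jsonlite::write_json(manifestAll, file.path(config$outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifestAll
  invisible(out)
}
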