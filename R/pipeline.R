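# End-to-end orchestration: simulate -> detect -> classify -> TCF ->
# CNV re-call -> agreement, with a config object that round-trips through
# YAML and a manifest that records seeds and versions.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated,
#' YAML-serializable list: scene geometry and resolution, detector
#' parameters, the annotation budget, the adequacy thresholds (100 cells /
#' 20 percent), the CNV gate (5 of 6 criteria, call threshold at 4
#' corrected copies), observer models and agreement settings.
#'
#' @param nCases number of synthetic cases in a report run.
#' @param widthPx,heightPx,mpp scene tile geometry and resolution.
#' @param totalCells nuclei per scene (tumor + non-neoplastic).
#' @param nArtifact artifact objects per scene.
#' @param tumorFracRange range the per-case true tumor fraction is drawn
#'   from.
#' @param odThreshold,minAreaUm2,maxAreaUm2,splitMinDistancePx detector
#'   parameters, see [detectParams()].
#' @param nAnnotations per-class annotation budget for training.
#' @param minCells,minTcf adequacy thresholds.
#' @param minCriteria,callThreshold CNV confidence-gate and primary-call
#'   settings.
#' @param observerBias,observerNoiseSD,nObservers simulated observer panel.
#' @param binWidth,nPerm agreement settings.
#' @return a validated config list of class `quantTCFConfig`.
#' @export
pipelineConfig <- function(nCases = 8L,
                           widthPx = 512L, heightPx = 512L, mpp = 0.4416,
                           totalCells = 90L, nArtifact = 6L,
                           tumorFracRange = c(0.15, 0.50),
                           odThreshold = 0.25, minAreaUm2 = 8,
                           maxAreaUm2 = 400, splitMinDistancePx = 3,
                           nAnnotations = 5L,
                           minCells = 100, minTcf = 0.20,
                           minCriteria = 5L, callThreshold = 4,
                           observerBias = c(18, 22, 20),
                           observerNoiseSD = c(10, 10, 12),
                           nObservers = 3L,
                           binWidth = 10, nPerm = 500L) {
  cfg <- list(version = 1L,
              nCases = as.integer(nCases),
              scene = list(widthPx = as.integer(widthPx),
                           heightPx = as.integer(heightPx),
                           mpp = mpp, totalCells = as.integer(totalCells),
                           nArtifact = as.integer(nArtifact),
                           tumorFracRange = tumorFracRange),
              detect = list(odThreshold = odThreshold, minAreaUm2 = minAreaUm2,
                            maxAreaUm2 = maxAreaUm2,
                            splitMinDistancePx = splitMinDistancePx),
              classify = list(nAnnotations = as.integer(nAnnotations)),
              adequacy = list(minCells = minCells, minTcf = minTcf),
              cnv = list(minCriteria = as.integer(minCriteria),
                         callThreshold = callThreshold),
              observers = list(bias = observerBias, noiseSD = observerNoiseSD,
                               n = as.integer(nObservers)),
              agreement = list(binWidth = binWidth, nPerm = as.integer(nPerm)))
  .validateConfig(cfg)
  class(cfg) <- c("quantTCFConfig", "list")
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$nCases >= 1L, cfg$scene$mpp > 0,
            cfg$scene$totalCells >= 2L,
            all(cfg$scene$tumorFracRange >= 0),
            all(cfg$scene$tumorFracRange <= 1),
            cfg$adequacy$minTcf >= 0, cfg$adequacy$minTcf <= 1,
            cfg$adequacy$minCells >= 0,
            cfg$cnv$minCriteria >= 0L, cfg$cnv$minCriteria <= 6L,
            cfg$observers$n >= 1L,
            cfg$agreement$binWidth > 0)
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' The config round-trips losslessly.
#'
#' @param path YAML file path.
#' @param cfg a config from [pipelineConfig()].
#' @return `readPipelineConfig`: the config; `writePipelineConfig`: `path`,
#'   invisibly.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$nCases <- as.integer(cfg$nCases)
  .validateConfig(cfg)
  class(cfg) <- c("quantTCFConfig", "list")
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# deterministic per-stage seed derivation from one master seed; kept well
# below 2^31
.stageSeed <- function(seed, stage, case = 0L) {
  offsets <- c(scene = 11L, observers = 29L, cnv = 47L, classify = 83L,
               agreement = 101L)
  (as.integer(seed) * 127L + offsets[[stage]] + 7L * as.integer(case)) %% 2147480000L
}

#' Match detections to scene ground truth
#'
#' Greedy one-to-one assignment by centroid distance: detections are paired
#' with the nearest unclaimed ground-truth object within `maxDistPx`.
#' Artifact truth maps to the classifier's `Ignore` label.
#'
#' @param det a [DetectionSet-class].
#' @param scene the generating [HEScene-class].
#' @param maxDistPx maximum pairing distance (default: the mean ground-truth
#'   semi-major axis).
#' @return data.frame with `id`, `truthId`, `trueLabel` (`NA` for unmatched
#'   detections) and `distPx`.
#' @export
matchDetections <- function(det, scene, maxDistPx = NULL) {
  gt <- scene@cells
  if (is.null(maxDistPx)) maxDistPx <- mean(gt$semiMajorPx)
  d <- det@data
  out <- data.frame(id = d$id, truthId = NA_character_,
                    trueLabel = NA_character_, distPx = NA_real_,
                    stringsAsFactors = FALSE)
  if (!nrow(d) || !nrow(gt)) return(out)
  dist <- outer(d$x, gt$x, "-")^2 + outer(d$y, gt$y, "-")^2
  dist <- sqrt(dist)
  labMap <- c(Tumor = "Tumor", NonNeoplastic = "NonNeoplastic",
              Artifact = "Ignore")
  taken <- logical(nrow(gt))
  ord <- order(apply(dist, 1L, min))
  for (i in ord) {
    j <- which.min(ifelse(taken, Inf, dist[i, ]))
    if (!is.finite(dist[i, j]) || dist[i, j] > maxDistPx || taken[j]) next
    taken[j] <- TRUE
    out$truthId[i] <- gt$id[j]
    out$trueLabel[i] <- unname(labMap[gt$trueClass[j]])
    out$distPx[i] <- dist[i, j]
  }
  out
}

# one case: scene -> detect -> annotate from truth -> classify -> TCF
.runCase <- function(caseId, trueFrac, cfg, seed) {
  nTum <- max(1L, round(cfg$scene$totalCells * trueFrac))
  spec <- sceneSpec(widthPx = cfg$scene$widthPx, heightPx = cfg$scene$heightPx,
                    mpp = cfg$scene$mpp, nTumor = nTum,
                    nNonneo = cfg$scene$totalCells - nTum,
                    nArtifact = cfg$scene$nArtifact,
                    seed = .stageSeed(seed, "scene", caseId))
  scene <- generateScene(spec)
  params <- detectParams(cfg$detect$odThreshold, cfg$detect$minAreaUm2,
                         cfg$detect$maxAreaUm2, cfg$detect$splitMinDistancePx)
  det <- detectNuclei(sceneImage(scene), sceneROI(scene), params,
                      mpp = cfg$scene$mpp)
  feats <- extractFeatures(sceneImage(scene), det)
  matched <- matchDetections(det, scene)
  clfSeed <- .stageSeed(seed, "classify", caseId)
  set.seed(clfSeed)
  nAnn <- cfg$classify$nAnnotations
  annIdx <- unlist(lapply(.CLASS_LEVELS, function(cl) {
    cand <- which(matched$trueLabel == cl)
    if (length(cand) < nAnn)
      stop("not enough matched '", cl, "' cells to annotate")
    sample(cand, nAnn)
  }))
  ann <- annotationSet(matched$id[annIdx], matched$trueLabel[annIdx])
  clf <- trainClassifier(feats, ann, seed = clfSeed)
  labeled <- classifyDetections(clf, feats)
  det <- setDetectionLabels(det, labeled)
  res <- computeCTCF(det, minCells = cfg$adequacy$minCells,
                     minTcf = cfg$adequacy$minTcf)
  list(scene = scene, detections = det, result = res,
       trueFrac = trueTCF(scene))
}

#' Run the full synthetic-cohort report
#'
#' Chains every stage on a simulated cohort: per case, a synthetic H&E
#' scene is generated, nuclei are detected and classified (annotations
#' drawn from the scene's ground truth under the balanced few-shot
#' protocol), and the cTCF with adequacy flags is computed. Observer panels
#' are simulated on the true per-case TCFs, compared against the cTCF
#' (direction counts), and the observer/computational agreement matrix is
#' computed. A synthetic CNV table is re-called with the pipeline's cTCF
#' and the before/after call sets compared. When `outDir` is given, all
#' tables plus a JSON report and a run manifest (versions, seeds, config
#' hash) are written; identical config and seed reproduce every output
#' bit-identically.
#'
#' @param cfg a [pipelineConfig()].
#' @param seed master seed; all per-stage seeds derive from it.
#' @param outDir optional output directory.
#' @return list with `tcf` (per-case data.frame), `adequacy` (2 x 2
#'   below/at-or-above threshold table for cTCF and observer mean, plus the
#'   chi-square comparison), `scoreComparison` (from [compareScores()]),
#'   `agreement` (from [agreementMatrix()]), `cnv` (from
#'   [compareCallSets()]) and `manifest`.
#' @export
runReport <- function(cfg = pipelineConfig(), seed = 1L, outDir = NULL) {
  .validateConfig(cfg)
  set.seed(.stageSeed(seed, "scene"))
  fr <- cfg$scene$tumorFracRange
  trueFracs <- stats::runif(cfg$nCases, fr[1L], fr[2L])
  cases <- vector("list", cfg$nCases)
  for (i in seq_len(cfg$nCases)) {
    cases[[i]] <- tryCatch(.runCase(i, trueFracs[i], cfg, seed),
                           error = function(e)
                             stop("stage 'case-pipeline' failed for case ", i,
                                  ": ", conditionMessage(e), call. = FALSE))
  }
  caseIds <- sprintf("case-%03d", seq_len(cfg$nCases))
  tcfTab <- data.frame(
    case_id = caseIds,
    trueTCF = vapply(cases, `[[`, numeric(1), "trueFrac"),
    ctcf = vapply(cases, function(cs) ctcfValue(cs$result), numeric(1)),
    nTumor = vapply(cases, function(cs) cs$result@nTumor, integer(1)),
    nNonneo = vapply(cases, function(cs) cs$result@nNonneo, integer(1)),
    nIgnore = vapply(cases, function(cs) cs$result@nIgnore, integer(1)),
    adequate = vapply(cases, function(cs) isAdequate(cs$result), logical(1)),
    stringsAsFactors = FALSE)

  models <- lapply(seq_len(cfg$observers$n), function(j) {
    observerModel(bias = cfg$observers$bias[[j]],
                  noiseSD = cfg$observers$noiseSD[[j]],
                  seed = .stageSeed(seed, "observers", j))
  })
  ratings <- simulateObservers(100 * tcfTab$trueTCF, models, caseIds = caseIds)
  cmp <- tryCatch(
    compareScores(stats::setNames(100 * tcfTab$ctcf, caseIds), ratings),
    error = function(e) stop("stage 'compare-scores' failed: ",
                             conditionMessage(e), call. = FALSE))

  cut <- 100 * cfg$adequacy$minTcf
  below <- function(v) c(sum(v < cut), sum(v >= cut))
  adq <- rbind(cTCF = below(100 * tcfTab$ctcf),
               observerMean = below(cmp$perCase$observerMean))
  colnames(adq) <- c("below", "atOrAbove")
  # small synthetic cohorts routinely trip the chi-square small-count warning
  adqTest <- suppressWarnings(
    compareGroups(adq["cTCF", ], adq["observerMean", ], test = "chi2"))

  agree <- agreementMatrix(ratings, truth = 100 * tcfTab$trueTCF,
                           binWidth = cfg$agreement$binWidth,
                           nPerm = cfg$agreement$nPerm,
                           seed = .stageSeed(seed, "agreement"))

  cnvBefore <- generateCNVTable(cfg$nCases, "pathologist",
                                seed = .stageSeed(seed, "cnv"))
  cnvBefore$case_id <- caseIds
  cnvBefore$f <- pmin(0.95, pmax(0.05, cmp$perCase$observerMean / 100))
  newF <- stats::setNames(pmin(0.95, pmax(0.05, tcfTab$ctcf)), caseIds)
  cnvAfter <- recallWithTCF(cnvBefore, newF,
                            minCriteria = cfg$cnv$minCriteria)
  cnvCmp <- compareCallSets(cnvBefore, cnvAfter,
                            callThreshold = cfg$cnv$callThreshold,
                            minCriteria = cfg$cnv$minCriteria)

  manifest <- list(package = "quantTCF",
                   version = as.character(utils::packageVersion("quantTCF")),
                   rVersion = paste(R.version$major, R.version$minor, sep = "."),
                   seed = as.integer(seed),
                   stageSeeds = list(
                     scene = .stageSeed(seed, "scene"),
                     observers = .stageSeed(seed, "observers"),
                     cnv = .stageSeed(seed, "cnv"),
                     agreement = .stageSeed(seed, "agreement")),
                   configHash = .configHash(cfg))

  report <- list(tcf = tcfTab,
                 adequacy = list(table = adq, chi2 = adqTest),
                 scoreComparison = cmp,
                 agreement = agree,
                 cnv = cnvCmp,
                 manifest = manifest)
  if (!is.null(outDir)) .writeReportBundle(report, outDir)
  report
}

.configHash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

.writeReportBundle <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$tcf, file.path(outDir, "tcf_per_case.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$adequacy$table),
                   file.path(outDir, "adequacy_table.csv"))
  utils::write.csv(report$scoreComparison$perCase,
                   file.path(outDir, "score_comparison.csv"), row.names = FALSE)
  utils::write.csv(report$agreement, file.path(outDir, "agreement.csv"),
                   row.names = FALSE)
  writeCNVTable(report$cnv$before, file.path(outDir, "cnv_before.csv"))
  writeCNVTable(report$cnv$after, file.path(outDir, "cnv_after.csv"))
  summary <- list(
    directionCounts = as.list(report$scoreComparison$counts),
    scoreSummary = report$scoreComparison$summary,
    adequacy = list(table = report$adequacy$table,
                    chi2 = report$adequacy$chi2),
    cnv = report$cnv[c("softwareBefore", "softwareAfter", "softwarePctChange",
                       "confidentBefore", "confidentAfter",
                       "confidentPctChange", "discrepantN", "discrepancyPct")],
    manifest = report$manifest)
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
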