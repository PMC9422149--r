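#' Run the full analysis pipeline into an output directory
#'
#' Orchestrates the end-to-end flow: load (or simulate) a thickness
#' matrix, clean it, derive group windows, select ROI and essential-ROI
#' vertices, fit the score-matrix classifier, run the self-recognition
#' test, compute the training severity table, optionally cross-validate,
#' and write every artifact (TSV tables, the serialized model, JSON
#' reports and a manifest capturing the configuration and seed).
#'
#' @param outDir Output directory, created if needed.
#' @param preset Optional [simulationPreset()] name; mutually exclusive
#'   with `thicknessPath`.
#' @param thicknessPath,metadataPath Paths to delimited input tables (see
#'   [readThicknessMatrix()], [readImageMetadata()]).
#' @param orientation Orientation of the thickness table on disk.
#' @param seed Integer seed (simulation and fold plan).
#' @param nGroups,trimFraction,boundaries,trim Grouping parameters; when
#'   `boundaries` is given, explicit windows are used.
#' @param roiCutoff,essentialCutoffs,combine ROI selection parameters.
#' @param kernel Kernel mode name.
#' @param cap Score cap.
#' @param crossval Run stratified k-fold cross-validation.
#' @param k,unit Cross-validation parameters.
#' @return Invisibly, a list with `model`, `selfRecognition`, `severity`,
#'   `crossval` (or `NULL`), `outDir`.
#' @export
runPipeline <- function(outDir,
                        preset = NULL,
                        thicknessPath = NULL, metadataPath = NULL,
                        orientation = "vertices",
                        seed = 1,
                        nGroups = 4, trimFraction = 0.004,
                        boundaries = NULL, trim = NULL,
                        roiCutoff = 1.5, essentialCutoffs = 3,
                        combine = "union",
                        kernel = "integer-ratio", cap = 50,
                        crossval = TRUE, k = 3, unit = "subject") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(preset)) {
    sim <- simulateCohortStudy(simulationPreset(preset, seed = seed))
    x <- sim$experiment
    truth <- sim$truth
  } else {
    if (is.null(thicknessPath) || is.null(metadataPath))
      stop("either 'preset' or both 'thicknessPath' and 'metadataPath' ",
           "are required")
    m <- readThicknessMatrix(thicknessPath, orientation)
    x <- ThicknessExperiment(m, readImageMetadata(metadataPath))
  }
  x <- dropIncompleteVertices(x)

  groupMode <- if (is.null(boundaries)) "quantile" else "explicit"
  model <- fitScoreModel(x, nGroups = nGroups, groupMode = groupMode,
                         boundaries = boundaries, trim = trim,
                         trimFraction = trimFraction,
                         roiCutoff = roiCutoff,
                         essentialCutoffs = essentialCutoffs,
                         combine = combine, kernel = kernel, cap = cap)

  assign <- assignGroups(meanThickness(x), model@windows)
  utils::write.table(assign, file.path(outDir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in model@groups) {
    tab <- data.frame(vertex_id = g$z[[1]]$vertex_id,
                      Z_cn_mci = g$z[["CN-MCI"]]$z,
                      Z_cn_ad = g$z[["CN-AD"]]$z,
                      Z_mci_ad = g$z[["MCI-AD"]]$z,
                      roi_flag = g$z[[1]]$vertex_id %in% g$roi$vertexIds,
                      essential_flag =
                        g$z[[1]]$vertex_id %in% g$essential$vertexIds,
                      category = g$categories$category)
    utils::write.table(tab,
                       file.path(outDir, sprintf("roi_group%s.tsv",
                                                 g$label)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  saveScoreModel(model, file.path(outDir, "model"))

  self <- selfRecognition(model, x)
  sev <- trainingSeverity(model, x)
  utils::write.table(sev, file.path(outDir, "severity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = as.data.frame.matrix(self$aggregate),
         perCohort = self$perCohort, excluded = self$excluded),
    file.path(outDir, "self_recognition.json"), auto_unbox = TRUE,
    digits = NA)

  cv <- NULL
  if (crossval) {
    cv <- crossValidate(x, k = k, unit = unit, seed = seed,
                        nGroups = nGroups, trimFraction = trimFraction,
                        boundaries = boundaries, trim = trim,
                        roiCutoff = roiCutoff,
                        essentialCutoffs = essentialCutoffs,
                        combine = combine, kernel = kernel, cap = cap)
    jsonlite::write_json(
      list(pooled = as.data.frame.matrix(cv$pooled$aggregate),
           perCohort = cv$pooled$perCohort,
           excluded = cv$pooled$excluded),
      file.path(outDir, "crossval.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "CorticalScore",
    version = as.character(utils::packageVersion("CorticalScore")),
    seed = seed, preset = preset,
    inputs = list(thickness = thicknessPath, metadata = metadataPath),
    grouping = list(nGroups = nGroups, mode = groupMode,
                    trimFraction = trimFraction,
                    boundaries = boundaries, trim = trim),
    roi = list(cutoff = roiCutoff, essentialCutoffs = essentialCutoffs,
               combine = combine),
    binning = model@binning,
    kernel = kernel, cap = cap,
    crossval = if (crossval) list(k = k, unit = unit) else NULL)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, selfRecognition = self, severity = sev,
                 crossval = cv, truth = truth, outDir = outDir))
}
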