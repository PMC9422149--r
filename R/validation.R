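.confusion <- function(clinical, predicted) {
  table(Exp = factor(clinical, levels = .COHORTS),
        Score = factor(predicted, levels = .COHORTS))
}

#' Build a confusion report from classification results
#'
#' Per thickness group and in aggregate: the 3x3 table of clinical cohort
#' (rows, "Exp") versus predicted cohort (columns, "Score"), together with
#' per-cohort correct counts and percentages. Images outside every group
#' window (or in an unfitted group) are counted separately as excluded.
#'
#' @param results data.frame from [classifyImages()] (columns `cohort`,
#'   `predicted`, `group`).
#' @return List with `groups` (named list of tables), `aggregate`,
#'   `perCohort` (data.frame with `cohort`, `n`, `correct`, `pct`),
#'   `excluded` (count).
#' @export
confusionReport <- function(results) {
  scored <- !is.na(results$predicted) & results$cohort %in% .COHORTS
  excluded <- sum(!scored & results$cohort %in% .COHORTS)
  sc <- results[scored, , drop = FALSE]
  groups <- lapply(split(sc, sc$group),
                   function(d) .confusion(d$cohort, d$predicted))
  agg <- .confusion(sc$cohort, sc$predicted)
  per <- data.frame(cohort = .COHORTS,
                    n = as.integer(rowSums(agg)),
                    correct = as.integer(diag(agg)))
  per$pct <- ifelse(per$n > 0, 100 * per$correct / per$n, NA_real_)
  list(groups = groups, aggregate = agg, perCohort = per,
       excluded = excluded)
}

#' Self-recognition test
#'
#' Classifies the training images with the model trained on them and
#' reports the confusion counts.
#'
#' @param model A [ScoreModel-class] trained on `x`.
#' @param x The training [ThicknessExperiment-class].
#' @return A confusion report (see [confusionReport()]).
#' @export
selfRecognition <- function(model, x) {
  confusionReport(classifyImages(model, x))
}

#' Stratified k-fold plan
#'
#' Partitions images into `k` folds stratified by thickness group x
#' clinical cohort. With `unit = "subject"` (the default) all images of a
#' subject share a fold, so twin acquisitions of one subject can never
#' straddle the train/test split; `unit = "image"` stratifies single
#' images. Deterministic given `seed`.
#'
#' @param x A [ThicknessExperiment-class].
#' @param assignment Group assignment data.frame from [assignGroups()].
#' @param k Number of folds (default 3).
#' @param unit `"subject"` or `"image"`.
#' @param seed Integer seed.
#' @return List with `folds` (list of image-id vectors), `unit`, `seed`.
#' @export
stratifiedKFold <- function(x, assignment, k = 3,
                            unit = c("subject", "image"), seed = 1) {
  unit <- match.arg(unit)
  md <- data.frame(image_id = imageIds(x),
                   subject_id = unname(subjectIds(x)),
                   cohort = unname(cohorts(x)),
                   stringsAsFactors = FALSE)
  md$group <- assignment$group[match(md$image_id, assignment$image_id)]
  md <- md[md$group != "EXCLUDED", , drop = FALSE]
  if (unit == "subject") {
    # a subject's stratum comes from its first image
    units <- md[!duplicated(md$subject_id), , drop = FALSE]
    units$id <- units$subject_id
  } else {
    units <- md
    units$id <- units$image_id
  }
  if (k == nrow(units)) {
    # leave-one-out degenerate case: every unit is its own fold
    folds <- as.list(units$id)
  } else {
  folds <- rep(list(character()), k)
  withLocalSeed(seed, {
    for (s in split(units, list(units$group, units$cohort), drop = TRUE)) {
      if (nrow(s) < k)
        stop("stratum group ", s$group[1], " x cohort ", s$cohort[1],
             " has only ", nrow(s), " ", unit, "(s); need at least ", k)
      perm <- sample(s$id)
      f <- rep_len(seq_len(k), length(perm))
      for (i in seq_len(k))
        folds[[i]] <- c(folds[[i]], perm[f == i])
    }
  })
  }
  if (unit == "subject")
    folds <- lapply(folds, function(su)
      md$image_id[md$subject_id %in% su])
  list(folds = folds, unit = unit, seed = seed)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For every fold, the complete training chain (group windows, ROI and
#' essential-ROI selection, probability and score matrices) is re-fitted
#' on the training images only and applied to the held-out images; the
#' pooled confusion aggregates all folds. Groups whose training portion
#' lacks a cohort are skipped for that fold with a warning.
#'
#' @param x A cleaned [ThicknessExperiment-class].
#' @param k Number of folds (default 3).
#' @param unit Stratification unit, `"subject"` (default) or `"image"`.
#' @param seed Integer seed for the fold plan.
#' @param ... Passed to [fitScoreModel()] (cutoffs, kernel, windows, ...).
#' @return List with `folds` (per-fold confusion reports), `pooled`
#'   (pooled report), `plan`, `results` (pooled per-image data.frame).
#' @export
crossValidate <- function(x, k = 3, unit = c("subject", "image"),
                          seed = 1, ...) {
  unit <- match.arg(unit)
  dots <- list(...)
  means <- meanThickness(x)
  planWindows <- dots$windows %||%
    makeGroupWindows(means,
                     nGroups = dots$nGroups %||% 4,
                     mode = dots$groupMode %||% "quantile",
                     boundaries = dots$boundaries, trim = dots$trim,
                     trimFraction = dots$trimFraction %||% 0.004)
  plan <- stratifiedKFold(x, assignGroups(means, planWindows),
                          k = k, unit = unit, seed = seed)
  all <- imageIds(x)
  res <- list()
  reports <- list()
  for (i in seq_len(k)) {
    test <- plan$folds[[i]]
    train <- setdiff(all, test)
    model <- fitScoreModel(x[, train], onMissingCohort = "skip", ...)
    cls <- classifyImages(model, x[, test])
    cls$fold <- i
    res[[i]] <- cls
    reports[[i]] <- confusionReport(cls)
  }
  pooledResults <- do.call(rbind, res)
  list(folds = reports, pooled = confusionReport(pooledResults),
       plan = plan, results = pooledResults)
}
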