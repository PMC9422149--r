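#' Thickness binning specification
#'
#' The thickness axis 0-6 mm is partitioned into `nBins` half-open bins of
#' width `delta`: bin `m` covers `[(m-1)*delta, m*delta)`, `m = 1..nBins`.
#' `delta * nBins` must equal 6 mm so that every representable thickness
#' has a bin.
#'
#' @param delta Bin width in mm (default 0.2).
#' @param nBins Number of bins (default 30).
#' @return List with `delta`, `nBins`.
#' @export
binningSpec <- function(delta = 0.2, nBins = 30) {
  if (abs(delta * nBins - 6) > 1e-9)
    stop("delta * nBins must equal 6 mm (the representable thickness range)")
  list(delta = delta, nBins = as.integer(nBins))
}

#' Bin index of a thickness value
#'
#' Lower-inclusive, upper-exclusive convention: `m = floor(t/delta) + 1`,
#' so a value exactly on a boundary belongs to the upper bin.
#'
#' @param t Thickness value(s) in `[0, 6)` mm.
#' @param binning A [binningSpec()].
#' @return Integer bin index / indices in `1..nBins`.
#' @examples
#' binIndex(2.5)            # 13
#' binIndex(c(0, 0.2))      # 1, 2
#' @export
binIndex <- function(t, binning = binningSpec()) {
  if (any(is.na(t)) || any(t < 0) || any(t >= 6))
    stop("thickness values must lie in [0, 6) mm")
  m <- as.integer(floor(t / binning$delta)) + 1L
  pmin(m, binning$nBins)
}

#' Discrete smoothing-kernel coefficients
#'
#' Coefficients `a_l`, `l = -4..4`, of the nine-point discrete kernel that
#' replaces each image's point mass when estimating bin probabilities
#' (kernel density estimation on the binned axis):
#' \describe{
#'   \item{`integer-ratio`}{weights proportional to 56:43:21:7:1 at offsets
#'     0, +/-1, ..., +/-4, normalized to sum exactly 1. Standard deviation
#'     `sqrt(412/200) = 1.4353` bin widths.}
#'   \item{`erf-recursion`}{`a_0 = erf(0.25)`, then
#'     `a_l = 0.5*erf(0.25 + 0.5*l) + a_0/2 - sum_{l' < l} a_{l'}`; total
#'     mass about 0.9987.}
#'   \item{`delta`}{the unsmoothed unit point mass.}
#' }
#'
#' @param mode Kernel mode.
#' @return List with `mode`, integer `offsets` and numeric `weights`.
#' @examples
#' k <- kernelWeights("integer-ratio")
#' sum(k$weights)                                   # exactly 1
#' sqrt(sum(k$weights * k$offsets^2))               # ~1.435 bin widths
#' @export
kernelWeights <- function(mode = c("integer-ratio", "erf-recursion",
                                   "delta")) {
  mode <- match.arg(mode)
  if (mode == "delta")
    return(list(mode = mode, offsets = 0L, weights = 1))
  if (mode == "integer-ratio") {
    half <- c(56, 43, 21, 7, 1) / 200
  } else {
    a <- numeric(5)                      # a_0 .. a_4
    a[1] <- erf(0.25)
    for (l in 1:4)
      a[l + 1] <- 0.5 * erf(0.25 + 0.5 * l) + a[1] / 2 - sum(a[1:l])
    half <- a
  }
  list(mode = mode, offsets = -4:4,
       weights = c(rev(half[-1]), half))
}

#' Per-cohort probability matrix over thickness bins
#'
#' For each vertex, every image of the cohort deposits the kernel mass into
#' the bins around its own bin index (`a_l` into bin `m + l`); the result
#' is divided by the cohort image count. Kernel mass falling outside bins
#' `1..nBins` is truncated (not renormalized) and reported per vertex in
#' `attr(, "truncated")`.
#'
#' @param values Numeric matrix, ROI vertices x cohort images.
#' @param binning A [binningSpec()].
#' @param kernel A [kernelWeights()].
#' @return Matrix vertices x bins with attributes `truncated` (per-vertex
#'   truncated mass) and `cohortSize`.
#' @export
probabilityMatrix <- function(values, binning = binningSpec(),
                              kernel = kernelWeights()) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (n == 0) stop("empty cohort: no images to estimate probabilities from")
  if (nrow(values) == 0) stop("empty ROI: no vertices")
  nv <- nrow(values)
  nb <- binning$nBins
  M <- matrix(binIndex(values, binning), nv, n)
  P <- matrix(0, nv, nb)
  trunc <- numeric(nv)
  rows <- row(M)
  for (j in seq_along(kernel$offsets)) {
    B <- M + kernel$offsets[j]
    ok <- B >= 1L & B <= nb
    if (any(ok)) {
      lin <- (B[ok] - 1L) * nv + rows[ok]
      P <- P + kernel$weights[j] * matrix(tabulate(lin, nbins = nv * nb),
                                          nv, nb)
    }
    if (any(!ok))
      trunc <- trunc + kernel$weights[j] * tabulate(rows[!ok], nbins = nv)
  }
  P <- P / n
  dimnames(P) <- list(rownames(values), paste0("m", seq_len(nb)))
  attr(P, "truncated") <- setNames(trunc / n, rownames(values))
  attr(P, "cohortSize") <- n
  P
}

#' Statistical score matrix from a probability matrix
#'
#' \deqn{S_{p,m} = -\ln(Q_{p,m} / Q_p), \quad
#'       Q_{p,m} = P_{p,m} / \sum_m P_{p,m}, \quad
#'       Q_p = \sum_m P_{p,m} / \sum_p \sum_m P_{p,m}.}
#' The smaller the score, the larger the underlying probability. Bins with
#' zero probability get the configured cap instead of `+Inf`.
#'
#' @param P A [probabilityMatrix()].
#' @param cap Score assigned to zero-probability bins (default 50).
#' @return Matrix of scores, same shape as `P`, with `attr(, "cap")`.
#' @export
scoreMatrix <- function(P, cap = 50) {
  rs <- rowSums(P)
  if (any(rs == 0))
    stop("all-zero probability row at vertex ",
         rownames(P)[which(rs == 0)[1]])
  Q <- P / rs
  Qp <- rs / sum(P)
  S <- -log(Q / Qp)
  S[Q == 0] <- cap
  attr(S, "cap") <- cap
  S
}

#' Total score of one thickness profile against per-cohort score matrices
#'
#' Sums, over the essential ROI vertices, the score of the bin the
#' subject's thickness falls into: `S'_(k) = sum_p S_{p, m'(p)}^{(k)}`.
#' The predicted cohort attains the minimum total score; ties break in the
#' order CN < MCI < AD.
#'
#' @param profile Named numeric vector of thickness (mm) covering every
#'   vertex in the score matrices.
#' @param scores Named list of score matrices, in cohort order
#'   (`CN`, `MCI`, `AD`).
#' @param binning A [binningSpec()].
#' @return One-row data.frame with per-cohort totals and `predicted`.
#' @export
totalScore <- function(profile, scores, binning = binningSpec()) {
  verts <- rownames(scores[[1]])
  if (!all(verts %in% names(profile)))
    stop("profile is missing thickness at ",
         sum(!(verts %in% names(profile))), " essential ROI vertices")
  mprime <- binIndex(profile[verts], binning)
  idx <- cbind(seq_along(verts), mprime)
  tot <- vapply(scores, function(S) sum(S[idx]), numeric(1))
  out <- as.data.frame(as.list(setNames(tot, paste0("S_", names(scores)))))
  out$predicted <- names(scores)[which.min(tot)]
  out
}

.fitGroup <- function(x, imgs, label, roiCutoff, essentialCutoffs, combine,
                      binning, kernel, cap, includeSelf,
                      onMissingCohort = c("error", "skip")) {
  onMissingCohort <- match.arg(onMissingCohort)
  coh <- cohorts(x)[imgs]
  sizes <- table(factor(coh, levels = .COHORTS))
  if (any(sizes < 2)) {
    msg <- paste0("group ", label, " has fewer than 2 images for cohort ",
                  paste(names(sizes)[sizes < 2], collapse = ", "))
    if (onMissingCohort == "error") stop(msg)
    warning(msg, "; group skipped")
    return(NULL)
  }
  zp <- lapply(.PAIRS, function(p) pairwiseZ(x, p, images = imgs))
  names(zp) <- .PAIRS
  roi <- selectROI(zp, roiCutoff)
  ess <- selectEssentialROI(zp, essentialCutoffs, roiCutoff, combine)
  fit <- list(label = label, images = imgs,
              cohortSizes = as.integer(sizes) |> setNames(names(sizes)),
              z = zp, roi = roi, essential = ess,
              categories = categorizeVertices(zp, roiCutoff))
  if (length(ess$vertexIds) == 0) {
    fit$P <- fit$S <- setNames(vector("list", 3), .COHORTS)
    return(fit)
  }
  tm <- thickness(x)[ess$vertexIds, imgs, drop = FALSE]
  fit$P <- lapply(setNames(.COHORTS, .COHORTS), function(k)
    probabilityMatrix(tm[, coh == k, drop = FALSE], binning, kernel))
  fit$S <- lapply(fit$P, scoreMatrix, cap = cap)
  # normalization statistics reused by the severity predictor
  np <- normalizeProfiles(tm)
  C <- covarianceCorrelation(np)
  sev <- severityDegree(C, coh, includeSelf = includeSelf)
  sev$group <- label
  fit$vertexMean <- attr(np, "center")
  fit$vertexSD <- attr(np, "scale")
  fit$tprime <- np
  fit$maxT2 <- attr(C, "maxT2")
  fit$cbarCN <- attr(sev, "cbarCN")
  fit$cbarAD <- attr(sev, "cbarAD")
  fit$severity <- sev
  fit
}

#' Fit the score-matrix classifier (and severity normalization)
#'
#' Runs the full training chain on a cleaned thickness experiment:
#' thickness-group windows, per-group pairwise Z profiles, ROI and
#' essential-ROI selection, per-cohort probability and score matrices over
#' the thickness bins, and the per-group normalization statistics needed by
#' the covariance-correlation severity degree.
#'
#' @param x A cleaned [ThicknessExperiment-class] with CN, MCI and AD
#'   images.
#' @param windows Optional [GroupWindows-class]; when `NULL`, windows are
#'   derived from the training means via [makeGroupWindows()].
#' @param nGroups,groupMode,boundaries,trim,trimFraction Passed to
#'   [makeGroupWindows()] when `windows` is `NULL`.
#' @param roiCutoff Absolute Z cutoff for ROI vertices (default 1.5).
#' @param essentialCutoffs Per-pair cutoffs for essential ROI vertices
#'   (default 3 for every pair).
#' @param combine `"union"` or `"intersection"` of the pair criteria.
#' @param binning A [binningSpec()].
#' @param kernel A [kernelWeights()] or a kernel mode name.
#' @param cap Score cap for zero-probability bins.
#' @param includeSelf Whether severity reference averages include the
#'   self term (see [severityDegree()]).
#' @param onMissingCohort `"error"` (default) or `"skip"`: what to do when
#'   a group lacks a cohort (used by cross-validation).
#' @return A [ScoreModel-class].
#' @examples
#' sim <- simulateCohortStudy(simulationPreset("separated"))
#' model <- fitScoreModel(sim$experiment)
#' model
#' @export
fitScoreModel <- function(x, windows = NULL, nGroups = 4,
                          groupMode = c("quantile", "explicit"),
                          boundaries = NULL, trim = NULL,
                          trimFraction = 0.004,
                          roiCutoff = 1.5, essentialCutoffs = 3,
                          combine = c("union", "intersection"),
                          binning = binningSpec(),
                          kernel = kernelWeights("integer-ratio"),
                          cap = 50, includeSelf = TRUE,
                          onMissingCohort = c("error", "skip")) {
  groupMode <- match.arg(groupMode)
  combine <- match.arg(combine)
  if (is.character(kernel)) kernel <- kernelWeights(kernel)
  means <- meanThickness(x)
  if (is.null(windows))
    windows <- makeGroupWindows(means, nGroups, groupMode,
                                boundaries, trim, trimFraction)
  assign <- assignGroups(means, windows)
  fits <- list()
  for (lab in groupLabels(windows)) {
    imgs <- assign$image_id[assign$group == lab]
    fit <- .fitGroup(x, imgs, lab, roiCutoff, essentialCutoffs, combine,
                     binning, kernel, cap, includeSelf,
                     onMissingCohort = match.arg(onMissingCohort))
    if (!is.null(fit)) fits[[lab]] <- fit
  }
  if (length(fits) == 0) stop("no group could be fitted")
  if (length(essentialCutoffs) == 1)
    essentialCutoffs <- setNames(rep(essentialCutoffs, 3), .PAIRS)
  new("ScoreModel", windows = windows, binning = binning, kernel = kernel,
      cap = cap, roiCutoff = roiCutoff,
      essentialCutoffs = essentialCutoffs, combine = combine,
      includeSelf = includeSelf, groups = fits, vertexIds = vertexIds(x))
}

#' Classify images with a fitted score model
#'
#' Each image is assigned to the thickness group containing its mean
#' thickness; its total score per cohort is the sum of score-matrix entries
#' at the bins of its thickness at the group's essential ROI vertices, and
#' the predicted cohort minimizes the total. Images whose mean falls
#' outside every window are labelled `EXCLUDED` (predicted `NA`); images in
#' a group the model could not fit are labelled `UNSCORED`.
#'
#' @param model A [ScoreModel-class].
#' @param x A cleaned [ThicknessExperiment-class] sharing the model's
#'   vertex universe.
#' @return data.frame with `image_id`, `mean_thickness`, `group`,
#'   `cohort` (clinical), `S_CN`, `S_MCI`, `S_AD`, `predicted`.
#' @export
classifyImages <- function(model, x) {
  stopifnot(is(model, "ScoreModel"))
  means <- meanThickness(x)
  assign <- assignGroups(means, model@windows)
  out <- data.frame(image_id = assign$image_id,
                    mean_thickness = assign$mean_thickness,
                    group = assign$group,
                    cohort = unname(cohorts(x)[assign$image_id]),
                    S_CN = NA_real_, S_MCI = NA_real_, S_AD = NA_real_,
                    predicted = NA_character_,
                    stringsAsFactors = FALSE)
  tm <- thickness(x)
  for (lab in unique(assign$group)) {
    if (lab == "EXCLUDED") next
    rows <- which(assign$group == lab)
    fit <- model@groups[[lab]]
    if (is.null(fit) || length(fit$essential$vertexIds) == 0) {
      out$group[rows] <- ifelse(is.null(fit), "UNSCORED", lab)
      next
    }
    verts <- fit$essential$vertexIds
    sub <- tm[verts, assign$image_id[rows], drop = FALSE]
    Mp <- matrix(binIndex(sub, model@binning), length(verts))
    for (k in .COHORTS) {
      S <- fit$S[[k]]
      picked <- matrix(S[cbind(rep(seq_along(verts), ncol(Mp)),
                               as.vector(Mp))],
                       length(verts), ncol(Mp))
      out[[paste0("S_", k)]][rows] <- colSums(picked)
    }
    tots <- as.matrix(out[rows, paste0("S_", .COHORTS), drop = FALSE])
    out$predicted[rows] <- .COHORTS[apply(tots, 1, which.min)]
  }
  out
}

#' Save / load a fitted ScoreModel as a directory of delimited text
#'
#' The model is written as a JSON manifest plus per-group TSV matrices with
#' full floating-point precision, so a load reproduces the stored numbers
#' bit-identically. The manifest records the windows, binning, kernel,
#' cutoffs, cap and package version.
#'
#' @param model A [ScoreModel-class].
#' @param dir Output directory (created if needed).
#' @return `saveScoreModel` invisibly returns `dir`; `readScoreModel`
#'   returns the reloaded [ScoreModel-class].
#' @export
saveScoreModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    df <- data.frame(id = rownames(m),
                     apply(m, 2, function(x) sprintf("%.17g", x)),
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    package = "CorticalScore",
    version = as.character(utils::packageVersion("CorticalScore")),
    windows = list(label = model@windows@label,
                   lower = sprintf("%.17g", model@windows@lower),
                   upper = sprintf("%.17g", model@windows@upper)),
    binning = model@binning,
    kernel = list(mode = model@kernel$mode,
                  offsets = model@kernel$offsets,
                  weights = sprintf("%.17g", model@kernel$weights)),
    cap = model@cap, roiCutoff = model@roiCutoff,
    essentialCutoffs = as.list(model@essentialCutoffs),
    combine = model@combine, includeSelf = model@includeSelf,
    vertexIds = model@vertexIds,
    groups = lapply(model@groups, function(g) list(
      label = g$label, images = g$images,
      cohortSizes = as.list(g$cohortSizes),
      essential = g$essential$vertexIds,
      maxT2 = sprintf("%.17g", g$maxT2),
      cbarCN = sprintf("%.17g", g$cbarCN),
      cbarAD = sprintf("%.17g", g$cbarAD))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (g in model@groups) {
    if (length(g$essential$vertexIds) == 0) next
    for (k in .COHORTS) {
      wm(g$P[[k]], sprintf("group%s_P_%s.tsv", g$label, k))
      wm(g$S[[k]], sprintf("group%s_S_%s.tsv", g$label, k))
    }
    wm(cbind(mean = g$vertexMean, sd = g$vertexSD),
       sprintf("group%s_norm.tsv", g$label))
    wm(g$tprime, sprintf("group%s_tprime.tsv", g$label))
    utils::write.table(
      data.frame(image_id = g$severity$image_id,
                 cohort = g$severity$cohort,
                 cbar = sprintf("%.17g", g$severity$cbar),
                 sd = sprintf("%.17g", g$severity$sd)),
      file.path(dir, sprintf("group%s_severity.tsv", g$label)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname saveScoreModel
#' @export
readScoreModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    m <- vapply(df[-1], as.numeric, numeric(nrow(df)))
    if (nrow(df) == 1)
      m <- matrix(m, 1, dimnames = list(NULL, colnames(df)[-1]))
    rownames(m) <- df[[1]]
    m
  }
  windows <- new("GroupWindows", label = man$windows$label,
                 lower = as.numeric(man$windows$lower),
                 upper = as.numeric(man$windows$upper))
  kernel <- list(mode = man$kernel$mode,
                 offsets = as.integer(man$kernel$offsets),
                 weights = as.numeric(man$kernel$weights))
  groups <- list()
  for (nm in names(man$groups)) {
    g <- man$groups[[nm]]
    fit <- list(label = g$label, images = g$images,
                cohortSizes = unlist(g$cohortSizes),
                roi = list(vertexIds = character(), cutoff = man$roiCutoff,
                           essential = FALSE),
                essential = list(vertexIds = as.character(g$essential),
                                 cutoffs = unlist(man$essentialCutoffs),
                                 essential = TRUE, combine = man$combine))
    if (length(fit$essential$vertexIds)) {
      fit$P <- lapply(setNames(.COHORTS, .COHORTS), function(k)
        rm_(sprintf("group%s_P_%s.tsv", g$label, k)))
      fit$S <- lapply(setNames(.COHORTS, .COHORTS), function(k) {
        S <- rm_(sprintf("group%s_S_%s.tsv", g$label, k))
        attr(S, "cap") <- as.numeric(man$cap)
        S
      })
      norm <- rm_(sprintf("group%s_norm.tsv", g$label))
      fit$vertexMean <- setNames(norm[, "mean"], rownames(norm))
      fit$vertexSD <- setNames(norm[, "sd"], rownames(norm))
      fit$tprime <- rm_(sprintf("group%s_tprime.tsv", g$label))
      fit$maxT2 <- as.numeric(g$maxT2)
      fit$cbarCN <- as.numeric(g$cbarCN)
      fit$cbarAD <- as.numeric(g$cbarAD)
      sv <- utils::read.table(
        file.path(dir, sprintf("group%s_severity.tsv", g$label)),
        header = TRUE, sep = "\t", colClasses = "character")
      fit$severity <- data.frame(image_id = sv$image_id,
                                 cohort = sv$cohort,
                                 cbar = as.numeric(sv$cbar),
                                 sd = as.numeric(sv$sd),
                                 group = g$label,
                                 stringsAsFactors = FALSE)
    }
    groups[[nm]] <- fit
  }
  new("ScoreModel", windows = windows,
      binning = list(delta = man$binning$delta,
                     nBins = as.integer(man$binning$nBins)),
      kernel = kernel, cap = as.numeric(man$cap),
      roiCutoff = as.numeric(man$roiCutoff),
      essentialCutoffs = unlist(man$essentialCutoffs),
      combine = man$combine, includeSelf = man$includeSelf,
      groups = groups, vertexIds = as.character(man$vertexIds))
}
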