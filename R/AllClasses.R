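#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.COHORTS <- c("CN", "MCI", "AD")
.COHORT_LEVELS <- c("CN", "MCI", "AD", "UNKNOWN")
.PAIRS <- c("CN-MCI", "CN-AD", "MCI-AD")

#' ThicknessExperiment: vertex x image cortical thickness with image metadata
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' subclass holding one assay, `"thickness"`: cortical thickness in mm at
#' each (vertex, image) pair, with the image metadata (subject, clinical
#' cohort, sex, age, acquisition label) in `colData`. Rows are vertices,
#' columns are MR images; a subject typically contributes two images
#' (e.g. MPRAGE and MPRAGE_SENSE2 acquisitions).
#'
#' Missing values are allowed only before cleaning with
#' [dropIncompleteVertices()]. All non-missing values must lie in
#' `[0, 6)` mm, the range representable by the 0.2 mm thickness binning.
#'
#' @param values Numeric matrix, vertices x images, dimnames required
#'   (vertex ids, image ids).
#' @param metadata A data.frame with columns `image_id`, `subject_id`,
#'   `cohort` (one of CN, MCI, AD, UNKNOWN) and optionally `sex`, `age`,
#'   `acquisition_label`; exactly one row per image.
#' @return A `ThicknessExperiment`.
#' @examples
#' te <- exampleThicknessExperiment()
#' thickness(te)[1:3, 1:2]
#' cohorts(te)
#' @aliases ThicknessExperiment
#' @export ThicknessExperiment
#' @exportClass ThicknessExperiment
setClass("ThicknessExperiment", contains = "SummarizedExperiment")

setValidity("ThicknessExperiment", function(object) {
  msg <- character()
  if (!("thickness" %in% assayNames(object)))
    msg <- c(msg, "assay 'thickness' is required")
  else {
    v <- assay(object, "thickness")
    if (!is.numeric(v))
      msg <- c(msg, "thickness values must be numeric")
    bad <- v[!is.na(v)]
    if (length(bad) && (any(bad < 0) || any(bad >= 6)))
      msg <- c(msg, "thickness values must lie in [0, 6) mm")
  }
  cd <- colData(object)
  need <- c("image_id", "subject_id", "cohort")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):",
                        paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(cd$image_id))
      msg <- c(msg, "duplicated image ids")
    if (!all(as.character(cd$cohort) %in% .COHORT_LEVELS))
      msg <- c(msg, "cohort must be one of CN, MCI, AD, UNKNOWN")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated vertex ids")
  if (length(msg)) msg else TRUE
})

ThicknessExperiment <- function(values, metadata) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("v%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("'values' must carry image ids as column names")
  metadata <- as.data.frame(metadata)
  if (!("image_id" %in% colnames(metadata)))
    stop("'metadata' must contain an image_id column")
  if (anyDuplicated(metadata$image_id))
    stop("duplicated image_id in metadata")
  idx <- match(colnames(values), metadata$image_id)
  if (anyNA(idx))
    stop("every image in the matrix needs exactly one metadata row; missing: ",
         paste(head(colnames(values)[is.na(idx)]), collapse = ", "))
  metadata <- metadata[idx, , drop = FALSE]
  for (col in c("sex", "age", "acquisition_label"))
    if (!(col %in% colnames(metadata))) metadata[[col]] <- NA
  metadata$cohort <- as.character(metadata$cohort)
  cd <- DataFrame(metadata, row.names = metadata$image_id)
  se <- SummarizedExperiment(assays = list(thickness = values), colData = cd)
  new("ThicknessExperiment", se)
}

#' @rdname thickness
#' @export
setMethod("thickness", "ThicknessExperiment",
          function(x) assay(x, "thickness"))

#' @rdname thickness
#' @export
setMethod("vertexIds", "ThicknessExperiment", function(x) rownames(x))

#' @rdname thickness
#' @export
setMethod("imageIds", "ThicknessExperiment", function(x) colnames(x))

#' @rdname thickness
#' @export
setMethod("subjectIds", "ThicknessExperiment",
          function(x) setNames(colData(x)$subject_id, colnames(x)))

#' @rdname thickness
#' @export
setMethod("cohorts", "ThicknessExperiment",
          function(x) setNames(as.character(colData(x)$cohort), colnames(x)))

setMethod("show", "ThicknessExperiment", function(object) {
  callNextMethod()
  co <- table(factor(cohorts(object), levels = .COHORT_LEVELS))
  nmiss <- sum(is.na(assay(object, "thickness")))
  cat("cohorts:", paste(names(co), co, sep = "=", collapse = " "), "\n")
  cat("missing entries:", nmiss, "\n")
})

#' GroupWindows: thickness-group windows over mean cortical thickness
#'
#' Ordered, contiguous, disjoint half-open windows `[lower, upper)` in mm of
#' per-image mean cortical thickness, labelled from the thickest window
#' (`A`) down to the thinnest (`D` for the default four groups). Means that
#' fall outside the extreme bounds are excluded from the analysis
#' (out-of-bounds trimming).
#'
#' @slot label character, window labels ordered thickest first.
#' @slot lower,upper numeric, window bounds in mm (lower inclusive, upper
#'   exclusive).
#' @seealso [makeGroupWindows()], [assignGroups()]
#' @aliases groupLabels trimBounds
#' @exportClass GroupWindows
setClass("GroupWindows",
         representation(label = "character",
                        lower = "numeric",
                        upper = "numeric"))

setValidity("GroupWindows", function(object) {
  n <- length(object@label)
  if (length(object@lower) != n || length(object@upper) != n)
    return("label, lower, upper must have equal length")
  if (n == 0) return("at least one window required")
  if (any(object@upper <= object@lower))
    return("each window needs upper > lower")
  if (n > 1 && any(abs(object@lower[-n] - object@upper[-1]) > 1e-12))
    return("windows must be contiguous and ordered thickest (A) first")
  if (anyDuplicated(object@label))
    return("duplicated window labels")
  TRUE
})

#' @rdname GroupWindows-class
#' @export
setMethod("groupLabels", "GroupWindows", function(x) x@label)

#' @rdname GroupWindows-class
#' @export
setMethod("trimBounds", "GroupWindows",
          function(x) c(lower = min(x@lower), upper = max(x@upper)))

setMethod("show", "GroupWindows", function(object) {
  cat("GroupWindows with", length(object@label), "windows (mm):\n")
  for (i in seq_along(object@label))
    cat(sprintf("  %s: [%.4f, %.4f)\n",
                object@label[i], object@lower[i], object@upper[i]))
})

#' ScoreModel: fitted score-matrix classifier and severity predictor
#'
#' The trained object produced by [fitScoreModel()]. Per thickness group it
#' stores the pairwise Z profiles, the ROI and essential-ROI vertex sets,
#' the per-cohort probability matrices `P` and score matrices `S` over the
#' thickness bins, and the normalization statistics (per-vertex mean/sd,
#' reference standardized profiles, covariance-correlation constants)
#' needed to compute the severity degree of new images.
#'
#' @slot windows A [GroupWindows-class].
#' @slot binning List from [binningSpec()].
#' @slot kernel List from [kernelWeights()].
#' @slot cap Numeric score assigned to zero-probability bins.
#' @slot roiCutoff,essentialCutoffs Z cutoffs used for vertex selection.
#' @slot combine How the three pairwise essential criteria are combined.
#' @slot includeSelf Whether cohort reference averages include the i = j term.
#' @slot groups Named list of per-group fits.
#' @slot vertexIds Vertex universe of the training matrix.
#' @seealso [fitScoreModel()], [classifyImages()], [trainingSeverity()]
#' @exportClass ScoreModel
setClass("ScoreModel",
         representation(windows = "GroupWindows",
                        binning = "list",
                        kernel = "list",
                        cap = "numeric",
                        roiCutoff = "numeric",
                        essentialCutoffs = "numeric",
                        combine = "character",
                        includeSelf = "logical",
                        groups = "list",
                        vertexIds = "character"))

setValidity("ScoreModel", function(object) {
  if (length(object@groups) == 0)
    return("no fitted groups")
  ok <- vapply(object@groups, function(g) {
    is.list(g) && all(c("label", "essential", "S") %in% names(g))
  }, logical(1))
  if (!all(ok)) return("malformed group fit")
  TRUE
})

setMethod("show", "ScoreModel", function(object) {
  cat("ScoreModel (", object@kernel$mode, " kernel, Δ = ",
      object@binning$delta, " mm, ", object@binning$nBins, " bins, cap ",
      object@cap, ")\n", sep = "")
  show(object@windows)
  for (g in object@groups) {
    co <- paste(names(g$cohortSizes), g$cohortSizes, sep = "=",
                collapse = " ")
    cat(sprintf("  group %s: %d images [%s], %d ROI / %d essential vertices\n",
                g$label, length(g$images), co,
                length(g$roi$vertexIds), length(g$essential$vertexIds)))
  }
})
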