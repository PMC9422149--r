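#' Read a delimited cortical-thickness matrix
#'
#' Reads a TSV or CSV table (ids in the first row and first column) into the
#' canonical vertex x image orientation. Cells that do not parse as numbers
#' become missing entries and survive until [dropIncompleteVertices()].
#' Values outside `[0, 6)` mm are rejected with an error of class
#' `"thicknessRangeError"`, since the 0-6 mm binning cannot represent them.
#'
#' @param path Path to a delimited text file. The delimiter is taken from
#'   the extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param orientation `"vertices"` if rows are vertices (the canonical
#'   layout) or `"images"` if rows are images (the table is transposed).
#' @param sep Optional field separator override.
#' @return Numeric matrix, vertices x images, with dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeThicknessMatrix(exampleThicknessExperiment(), f)
#' m <- readThicknessMatrix(f)
#' dim(m)
#' @export
readThicknessMatrix <- function(path, orientation = c("vertices", "images"),
                                sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("empty or malformed thickness table: ", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated row ids in ", path)
  if (anyDuplicated(colnames(raw)[-1]))
    stop("duplicated column ids in ", path)
  m <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) m <- matrix(m, nrow = 1,
                                  dimnames = list(NULL, colnames(raw)[-1]))
  rownames(m) <- ids
  if (orientation == "images") m <- t(m)
  bad <- m[!is.na(m)]
  if (length(bad) && (any(bad < 0) || any(bad >= 6)))
    stop(errorCondition(
      paste0("thickness values outside [0, 6) mm in ", path),
      class = c("thicknessRangeError", "error", "condition")))
  m
}

#' Read an image metadata table
#'
#' Expects columns `image_id`, `subject_id`, `cohort` and optionally `sex`,
#' `age`, `acquisition_label`. Cohort labels are validated against
#' CN / MCI / AD / UNKNOWN.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Optional field separator override.
#' @return A data.frame, one row per image.
#' @export
readImageMetadata <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("image_id", "subject_id", "cohort")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$image_id))
    stop("duplicated image_id in ", path)
  if (!all(md$cohort %in% .COHORT_LEVELS))
    stop("cohort labels must be one of ",
         paste(.COHORT_LEVELS, collapse = ", "))
  if ("age" %in% colnames(md)) md$age <- as.numeric(md$age)
  md
}

#' Write a thickness matrix (and optionally metadata) to delimited text
#'
#' @param x A [ThicknessExperiment-class] or a vertex x image matrix.
#' @param path Output file for the matrix (tab separated, vertices in rows).
#' @param metadataPath Optional output file for the image metadata.
#' @param digits Decimal digits kept for the thickness values.
#' @return Invisibly, `path`.
#' @export
writeThicknessMatrix <- function(x, path, metadataPath = NULL, digits = 6) {
  m <- if (is(x, "ThicknessExperiment")) thickness(x) else as.matrix(x)
  df <- data.frame(vertex_id = rownames(m),
                   signif(m, digits = digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath) && is(x, "ThicknessExperiment"))
    utils::write.table(as.data.frame(colData(x)), metadataPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dropIncompleteVertices
#' @export
setMethod("dropIncompleteVertices", "ThicknessExperiment", function(x) {
  keep <- rowSums(is.na(thickness(x))) == 0
  if (!any(keep))
    stop("all vertices have missing values; nothing left after cleaning")
  if (any(!keep))
    message("dropped ", sum(!keep), " of ", length(keep),
            " vertices with incomplete thickness; ", sum(keep), " remain")
  x[keep, ]
})

#' Small built-in example ThicknessExperiment
#'
#' Six vertices by six images (two images for each of three subjects, one
#' subject per cohort), used in documentation examples.
#'
#' @return A [ThicknessExperiment-class].
#' @export
exampleThicknessExperiment <- function() {
  set.seed(42)
  v <- matrix(round(2.5 + stats::rnorm(36, 0, 0.1), 3), 6, 6,
              dimnames = list(sprintf("v%05d", 1:6),
                              paste0("S", rep(1:3, each = 2), "_I", 1:2)))
  md <- data.frame(
    image_id = colnames(v),
    subject_id = paste0("S", rep(1:3, each = 2)),
    cohort = rep(c("CN", "MCI", "AD"), each = 2),
    sex = rep(c("F", "M", "F"), each = 2),
    age = rep(c(72, 75, 78), each = 2),
    acquisition_label = rep(c("MPRAGE", "MPRAGE_SENSE2"), 3))
  ThicknessExperiment(v, md)
}
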