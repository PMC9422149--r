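#' @import methods
NULL

#' Thickness values of a ThicknessExperiment
#'
#' Accessor for the vertex x image cortical-thickness matrix (mm).
#'
#' @param x A [ThicknessExperiment-class] object.
#' @return A numeric matrix, vertices in rows, images in columns.
#' @export
setGeneric("thickness", function(x) standardGeneric("thickness"))

#' @rdname thickness
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' @rdname thickness
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname thickness
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname thickness
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' Drop vertices with incomplete thickness information
#'
#' Restricts a thickness matrix to the vertices that carry a value for every
#' image, the cleaning step that turns a raw vertex set into the common
#' vertices usable by all downstream statistics. Vertex order is preserved
#' and the number of dropped vertices is reported via a message.
#'
#' @param x A [ThicknessExperiment-class], possibly with missing entries.
#' @return A [ThicknessExperiment-class] without missing entries.
#' @examples
#' te <- exampleThicknessExperiment()
#' dropIncompleteVertices(te)
#' @export
setGeneric("dropIncompleteVertices",
           function(x) standardGeneric("dropIncompleteVertices"))

#' Per-image mean cortical thickness
#'
#' Arithmetic mean thickness over all vertices, per image; the quantity used
#' to partition images into thickness groups.
#'
#' @param x A cleaned [ThicknessExperiment-class] (no missing entries).
#' @return Named numeric vector of means (mm), one per image.
#' @export
setGeneric("meanThickness", function(x) standardGeneric("meanThickness"))

#' @rdname GroupWindows-class
#' @param x A `GroupWindows` object.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname GroupWindows-class
#' @export
setGeneric("trimBounds", function(x) standardGeneric("trimBounds"))
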