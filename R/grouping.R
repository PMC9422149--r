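#' @rdname meanThickness
#' @export
setMethod("meanThickness", "ThicknessExperiment", function(x) {
  m <- thickness(x)
  if (nrow(m) == 0) stop("zero vertices; cannot compute mean thickness")
  if (anyNA(m)) stop("matrix has missing entries; clean it first with ",
                     "dropIncompleteVertices()")
  colMeans(m)
})

#' Build thickness-group windows
#'
#' Partitions the range of per-image mean cortical thickness into `nGroups`
#' contiguous windows labelled `A` (thickest) downwards. In `"quantile"`
#' mode a configured fraction of images is trimmed at the extremes (the
#' out-of-bounds exclusion) and the remaining means are split into
#' equal-count windows; in `"explicit"` mode the supplied boundaries are
#' used verbatim.
#'
#' @param means Numeric vector of per-image mean thickness (mm).
#' @param nGroups Number of windows (default 4, labels A-D).
#' @param mode `"quantile"` or `"explicit"`.
#' @param boundaries For explicit mode: interior boundaries in decreasing
#'   order (mm), length `nGroups - 1`.
#' @param trim For explicit mode: `c(lower, upper)` global bounds (mm).
#' @param trimFraction For quantile mode: total fraction of images trimmed,
#'   split evenly between the two extremes. Default 0.004, emulating an
#'   out-of-bounds exclusion of roughly 6 in 1500 images.
#' @return A [GroupWindows-class].
#' @examples
#' w <- makeGroupWindows(NULL, mode = "explicit",
#'                       boundaries = c(2.41, 2.31, 2.21),
#'                       trim = c(2.06, 2.55))
#' w
#' @export
makeGroupWindows <- function(means, nGroups = 4,
                             mode = c("quantile", "explicit"),
                             boundaries = NULL, trim = NULL,
                             trimFraction = 0.004) {
  mode <- match.arg(mode)
  labels <- LETTERS[seq_len(nGroups)]
  if (mode == "explicit") {
    if (is.null(boundaries) || is.null(trim))
      stop("explicit mode needs 'boundaries' and 'trim'")
    if (length(boundaries) != nGroups - 1)
      stop("need ", nGroups - 1, " interior boundaries")
    if (is.unsorted(rev(boundaries), strictly = TRUE))
      stop("boundaries must be strictly decreasing (thickest first)")
    edges <- c(trim[2], boundaries, trim[1])
    if (is.unsorted(rev(edges), strictly = TRUE))
      stop("trim bounds must bracket the boundaries")
  } else {
    means <- means[!is.na(means)]
    if (length(unique(means)) < nGroups)
      stop("need at least ", nGroups, " distinct mean values")
    lo <- unname(stats::quantile(means, trimFraction / 2, type = 7))
    hi <- unname(stats::quantile(means, 1 - trimFraction / 2, type = 7))
    kept <- means[means >= lo & means <= hi]
    qs <- unname(stats::quantile(kept, seq_len(nGroups - 1) / nGroups,
                                 type = 7))
    # windows are upper-exclusive: bump the top bound so the largest kept
    # mean is inside window A
    hi <- hi + max(1e-9, abs(hi) * 1e-9)
    edges <- c(hi, rev(qs), lo)
  }
  new("GroupWindows", label = labels,
      lower = edges[-1], upper = edges[-length(edges)])
}

#' Assign images to thickness groups
#'
#' Each image is labelled by the window containing its mean thickness
#' (lower-inclusive, upper-exclusive); means outside every window are
#' labelled `"EXCLUDED"`.
#'
#' @param means Named numeric vector of per-image mean thickness (mm).
#' @param windows A [GroupWindows-class].
#' @return data.frame with columns `image_id`, `mean_thickness`, `group`.
#' @export
assignGroups <- function(means, windows) {
  stopifnot(is(windows, "GroupWindows"))
  grp <- rep("EXCLUDED", length(means))
  for (i in seq_along(windows@label)) {
    hit <- means >= windows@lower[i] & means < windows@upper[i]
    grp[hit] <- windows@label[i]
  }
  data.frame(image_id = if (is.null(names(means)))
               as.character(seq_along(means)) else names(means),
             mean_thickness = unname(means),
             group = grp,
             stringsAsFactors = FALSE)
}
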