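.pairCohorts <- function(pair) strsplit(pair, "-", fixed = TRUE)[[1]]

#' Pairwise cohort-separation Z profile
#'
#' For every vertex, the Welch-type statistic
#' \deqn{Z_p = (\langle t_{p,1}\rangle - \langle t_{p,2}\rangle) /
#'       \sqrt{\sigma_1^2/n_1 + \sigma_2^2/n_2}}
#' between two cohorts, where the means, standard deviations (unbiased
#' sample convention) and counts are taken over the MR images of each
#' cohort. A positive Z means the first cohort of the pair is thicker at
#' that vertex. Vertices where both cohort variances vanish get a
#' `+Inf`/`-Inf` sentinel (or 0 when the means also agree), with a warning.
#'
#' @param x A cleaned [ThicknessExperiment-class].
#' @param pair One of `"CN-MCI"`, `"CN-AD"`, `"MCI-AD"`.
#' @param images Optional subset of image ids (e.g. one thickness group).
#' @return data.frame with columns `vertex_id`, `z`, `mean1`, `mean2`,
#'   `sd1`, `sd2`, `n1`, `n2`; the pair is kept in `attr(, "pair")`.
#' @examples
#' te <- exampleThicknessExperiment()
#' head(pairwiseZ(te, "CN-AD"))
#' @export
pairwiseZ <- function(x, pair = c("CN-MCI", "CN-AD", "MCI-AD"),
                      images = NULL) {
  pair <- match.arg(pair)
  ks <- .pairCohorts(pair)
  if (is.null(images)) images <- imageIds(x)
  coh <- cohorts(x)[images]
  g1 <- images[coh == ks[1]]
  g2 <- images[coh == ks[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("cohort ", ks[which(c(length(g1), length(g2)) < 2)[1]],
         " has fewer than 2 images; cannot compute Z for pair ", pair)
  m <- thickness(x)
  v1 <- m[, g1, drop = FALSE]
  v2 <- m[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  mu1 <- rowMeans(v1); mu2 <- rowMeans(v2)
  s1 <- sqrt(rowSums((v1 - mu1)^2) / (n1 - 1))
  s2 <- sqrt(rowSums((v2 - mu2)^2) / (n2 - 1))
  den <- sqrt(s1^2 / n1 + s2^2 / n2)
  dif <- mu1 - mu2
  z <- dif / den
  zero <- den == 0
  if (any(zero)) {
    z[zero] <- sign(dif[zero]) * Inf
    z[zero & dif == 0] <- 0
    warning(sum(zero), " vertex/vertices with zero pooled variance; ",
            "Z set to +/-Inf sentinel (0 where means agree)")
  }
  out <- data.frame(vertex_id = rownames(m), z = unname(z),
                    mean1 = unname(mu1), mean2 = unname(mu2),
                    sd1 = unname(s1), sd2 = unname(s2),
                    n1 = n1, n2 = n2, stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  out
}

.zprofileList <- function(zprofiles) {
  if (is.data.frame(zprofiles)) zprofiles <- list(zprofiles)
  nm <- vapply(zprofiles, function(p) attr(p, "pair") %||% NA_character_,
               character(1))
  if (!anyNA(nm)) names(zprofiles) <- nm
  zprofiles
}

#' Select ROI vertices by |Z| cutoff
#'
#' A vertex is a region-of-interest (ROI) vertex when its absolute Z score
#' exceeds the cutoff in any of the supplied pairwise profiles.
#'
#' @param zprofiles A [pairwiseZ()] data.frame or a list of them (same
#'   group, different cohort pairs).
#' @param cutoff Absolute Z cutoff; default 1.5.
#' @return List with elements `vertexIds`, `cutoff`, `essential = FALSE`.
#' @export
selectROI <- function(zprofiles, cutoff = 1.5) {
  zprofiles <- .zprofileList(zprofiles)
  verts <- zprofiles[[1]]$vertex_id
  hit <- rep(FALSE, length(verts))
  for (p in zprofiles) {
    stopifnot(identical(p$vertex_id, verts))
    hit <- hit | (!is.nan(p$z) & abs(p$z) > cutoff)
  }
  if (!any(hit)) warning("no vertex exceeds |Z| > ", cutoff,
                         "; empty ROI set")
  list(vertexIds = verts[hit], cutoff = cutoff, essential = FALSE)
}

#' Select essential ROI vertices by per-pair cutoffs
#'
#' Essential ROI vertices satisfy much higher Z cutoffs than the plain ROI
#' set. By default a vertex qualifies when any pairwise |Z| exceeds its
#' pair's cutoff (`combine = "union"`); `"intersection"` requires all
#' supplied pairs to qualify.
#'
#' @param zprofiles Named list of [pairwiseZ()] profiles of one group.
#' @param cutoffs Single cutoff or named vector per pair; every cutoff must
#'   be at least `roiCutoff`.
#' @param roiCutoff The plain ROI cutoff (default 1.5).
#' @param combine `"union"` or `"intersection"`.
#' @return List with `vertexIds`, `cutoffs`, `essential = TRUE`.
#' @export
selectEssentialROI <- function(zprofiles, cutoffs = 3,
                               roiCutoff = 1.5,
                               combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  zprofiles <- .zprofileList(zprofiles)
  if (length(cutoffs) == 1)
    cutoffs <- setNames(rep(cutoffs, length(zprofiles)), names(zprofiles))
  if (any(cutoffs < roiCutoff))
    stop("essential cutoffs must be >= the ROI cutoff (", roiCutoff, ")")
  verts <- zprofiles[[1]]$vertex_id
  hit <- rep(combine == "intersection", length(verts))
  for (nm in names(zprofiles)) {
    p <- zprofiles[[nm]]
    stopifnot(identical(p$vertex_id, verts))
    cut <- if (nm %in% names(cutoffs)) cutoffs[[nm]] else cutoffs[[1]]
    this <- !is.nan(p$z) & abs(p$z) > cut
    hit <- if (combine == "union") hit | this else hit & this
  }
  if (!any(hit)) warning("no vertex exceeds the essential cutoffs; ",
                         "empty essential ROI set")
  list(vertexIds = verts[hit], cutoffs = cutoffs, essential = TRUE,
       combine = combine)
}

#' Categorize vertices by cohort-specific thickness differences
#'
#' Classifies every vertex into one of: `monotone-descending` (thickness
#' decreases CN > MCI > AD with both adjacent |Z| above the cutoff),
#' `X-thicker` / `X-thinner` (cohort X's mean differs from both other
#' cohorts beyond the cutoff in the same direction), or `none`. When
#' several patterns hold, the priority is monotone-descending, then CN,
#' MCI, AD.
#'
#' @param zprofiles Named list with all three pairwise profiles of a group
#'   (`CN-MCI`, `CN-AD`, `MCI-AD`).
#' @param cutoff Absolute Z cutoff.
#' @return data.frame with columns `vertex_id`, `category`.
#' @export
categorizeVertices <- function(zprofiles, cutoff = 1.5) {
  zprofiles <- .zprofileList(zprofiles)
  miss <- setdiff(.PAIRS, names(zprofiles))
  if (length(miss))
    stop("need all three pairwise profiles; missing: ",
         paste(miss, collapse = ", "))
  cm <- zprofiles[["CN-MCI"]]; ca <- zprofiles[["CN-AD"]]
  ma <- zprofiles[["MCI-AD"]]
  mCN <- cm$mean1; mMCI <- cm$mean2; mAD <- ca$mean2
  sCM <- abs(cm$z) > cutoff
  sCA <- abs(ca$z) > cutoff
  sMA <- abs(ma$z) > cutoff
  cat <- rep("none", nrow(cm))
  set <- function(cond, lab) cat[cond] <<- lab
  set(sCA & sMA & mAD > mCN & mAD > mMCI, "AD-thicker")
  set(sCA & sMA & mAD < mCN & mAD < mMCI, "AD-thinner")
  set(sCM & sMA & mMCI > mCN & mMCI > mAD, "MCI-thicker")
  set(sCM & sMA & mMCI < mCN & mMCI < mAD, "MCI-thinner")
  set(sCM & sCA & mCN > mMCI & mCN > mAD, "CN-thicker")
  set(sCM & sCA & mCN < mMCI & mCN < mAD, "CN-thinner")
  set(sCM & sMA & mCN > mMCI & mMCI > mAD, "monotone-descending")
  data.frame(vertex_id = cm$vertex_id, category = cat,
             stringsAsFactors = FALSE)
}
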