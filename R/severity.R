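#' Standardize thickness profiles per vertex
#'
#' Transforms the essential-ROI thickness matrix to per-vertex zero mean
#' and unit variance over the images, using the population variance
#' convention `sigma_p^2 = <t^2> - <t>^2`. The per-vertex mean and sd are
#' kept as attributes `center` and `scale` so that new images can be
#' standardized with the training statistics.
#'
#' @param values Numeric matrix, essential-ROI vertices x images.
#' @return Standardized matrix `t'` with attributes `center`, `scale`.
#' @examples
#' normalizeProfiles(rbind(v1 = c(2.0, 2.2)))  # -1, +1
#' @export
normalizeProfiles <- function(values) {
  values <- as.matrix(values)
  mu <- rowMeans(values)
  sd <- sqrt(pmax(rowMeans(values^2) - mu^2, 0))
  if (any(sd == 0))
    stop("constant thickness at vertex ",
         rownames(values)[which(sd == 0)[1]],
         "; exclude constant vertices before normalization")
  tp <- (values - mu) / sd
  attr(tp, "center") <- setNames(mu, rownames(values))
  attr(tp, "scale") <- setNames(sd, rownames(values))
  tp
}

#' Covariance correlation matrix between images
#'
#' The Gram matrix of standardized profiles, `t''_ij = sum_p t'_pi t'_pj`,
#' normalized by its maximum element (taken over all elements including
#' the diagonal): `C = t'' / max(t'')`. The larger `C_ij`, the more alike
#' the two images' thickness profiles at the essential ROI vertices.
#'
#' @param tprime Standardized matrix from [normalizeProfiles()].
#' @return Symmetric image x image matrix with maximum element exactly 1
#'   and attribute `maxT2` (the normalizing constant).
#' @export
covarianceCorrelation <- function(tprime) {
  if (ncol(tprime) < 2) stop("need at least 2 images")
  t2 <- crossprod(tprime)
  mx <- max(t2)
  C <- t2 / mx
  attr(C, "maxT2") <- mx
  C
}

#' Continuous severity degree from a covariance correlation matrix
#'
#' For each image `i`, the contrast
#' `Cbar_i = <C_ij>_{j in AD} - <C_ij>_{j in CN}` is affinely rescaled so
#' that the CN reference images average exactly 0 and the AD reference
#' images average exactly 1:
#' \deqn{SD_i = (Cbar_i - <Cbar>_{CN}) / (<Cbar>_{AD} - <Cbar>_{CN}).}
#' MCI images contribute to `C` but never to the reference averages. By
#' default the cohort averages over `j` include the `j = i` self term when
#' image `i` belongs to that cohort; the 0/1 identities hold either way.
#'
#' @param C Matrix from [covarianceCorrelation()] with image column names.
#' @param cohort Character vector of clinical cohorts aligned with the
#'   columns of `C` (values CN, MCI, AD, UNKNOWN).
#' @param includeSelf Include the self term in the reference averages.
#' @return data.frame with `image_id`, `cohort`, `cbar`, `sd` (the severity
#'   degree) and attributes `cbarCN`, `cbarAD` (normalization constants).
#' @export
severityDegree <- function(C, cohort, includeSelf = TRUE) {
  stopifnot(ncol(C) == length(cohort))
  cohort <- as.character(cohort)
  ids <- colnames(C) %||% as.character(seq_len(ncol(C)))
  isCN <- cohort == "CN"; isAD <- cohort == "AD"
  if (!any(isCN) || !any(isAD))
    stop("need at least one CN and one AD reference image")
  avgOver <- function(members) {
    s <- rowSums(C[, members, drop = FALSE])
    n <- sum(members)
    if (includeSelf) return(s / n)
    s2 <- s - ifelse(members, diag(C), 0)
    n2 <- n - as.numeric(members)
    if (any(n2 == 0))
      stop("a reference cohort with a single image cannot exclude ",
           "the self term")
    s2 / n2
  }
  cbar <- avgOver(isAD) - avgOver(isCN)
  mCN <- mean(cbar[isCN]); mAD <- mean(cbar[isAD])
  if (mAD == mCN)
    stop("degenerate separation: CN and AD reference averages coincide")
  sd <- (cbar - mCN) / (mAD - mCN)
  out <- data.frame(image_id = ids, cohort = cohort,
                    cbar = unname(cbar), sd = unname(sd),
                    stringsAsFactors = FALSE)
  attr(out, "cbarCN") <- mCN
  attr(out, "cbarAD") <- mAD
  out
}

#' Training-set severity table of a fitted model
#'
#' Collects the per-group severity degrees computed at fit time, joined
#' with the model's self-classification, and ranks images by ascending
#' severity within each clinical cohort (per group).
#'
#' @param model A [ScoreModel-class].
#' @param x Optional training [ThicknessExperiment-class]; when given, the
#'   `predicted` cohort from [classifyImages()] is added.
#' @return data.frame with `image_id`, `group`, `cohort`, `sd`, `cbar`,
#'   `rank` (ascending severity within group x cohort) and optionally
#'   `predicted`.
#' @export
trainingSeverity <- function(model, x = NULL) {
  stopifnot(is(model, "ScoreModel"))
  tabs <- lapply(model@groups, function(g) g$severity)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (length(tabs) == 0) stop("model has no severity tables")
  out <- do.call(rbind, c(tabs, make.row.names = FALSE))
  out$rank <- stats::ave(out$sd, out$group, out$cohort,
                         FUN = function(v) rank(v, ties.method = "first"))
  if (!is.null(x)) {
    cls <- classifyImages(model, x)
    out$predicted <- cls$predicted[match(out$image_id, cls$image_id)]
  }
  out[order(out$group, match(out$cohort, .COHORT_LEVELS), out$sd), ,
      drop = FALSE]
}

#' Severity degree of a new image
#'
#' The query profile is assigned to a thickness group by its mean
#' thickness, standardized with the group's training per-vertex mean/sd,
#' correlated against the training reference profiles using the frozen
#' normalizing constant `max(t'')`, and rescaled with the frozen training
#' `<Cbar>_CN` and `<Cbar>_AD`. A query identical to a training image
#' therefore reproduces that image's training severity degree.
#'
#' @param model A [ScoreModel-class].
#' @param profile Named numeric thickness vector (mm) covering the model's
#'   vertex universe (a full image profile).
#' @return One-row data.frame with `group`, `cbar`, `sd`.
#' @export
severityForNew <- function(model, profile) {
  stopifnot(is(model, "ScoreModel"))
  if (!all(model@vertexIds %in% names(profile)))
    stop("profile must cover the model's vertex universe")
  mu <- mean(profile[model@vertexIds])
  assign <- assignGroups(setNames(mu, "query"), model@windows)
  lab <- assign$group[1]
  if (lab == "EXCLUDED")
    stop("query mean thickness ", round(mu, 4),
         " mm lies outside all group windows")
  fit <- model@groups[[lab]]
  if (is.null(fit) || is.null(fit$tprime))
    stop("group ", lab, " was not fitted; severity unavailable")
  verts <- fit$essential$vertexIds
  tq <- (profile[verts] - fit$vertexMean) / fit$vertexSD
  cq <- as.vector(crossprod(fit$tprime, tq)) / fit$maxT2
  coh <- fit$severity$cohort[match(colnames(fit$tprime),
                                   fit$severity$image_id)]
  cbar <- mean(cq[coh == "AD"]) - mean(cq[coh == "CN"])
  data.frame(group = lab, cbar = cbar,
             sd = (cbar - fit$cbarCN) / (fit$cbarAD - fit$cbarCN))
}

#' Reorder a covariance correlation matrix by cohort and severity
#'
#' Produces the permutation that sorts images into clinical cohort blocks
#' (CN, MCI, AD) and, within each block, by ascending severity degree;
#' the reordered matrix is returned together with the clinical (`E`) and
#' predicted (`S`) cohort side labels.
#'
#' @param C Image x image covariance correlation matrix.
#' @param severityTable data.frame with `image_id`, `cohort`, `sd` and
#'   optionally `predicted`, covering all images in `C`.
#' @return List with `permutation` (image ids in order), `C` (reordered),
#'   `clinical`, `predicted`.
#' @export
reorderBySeverity <- function(C, severityTable) {
  ids <- colnames(C)
  if (!all(ids %in% severityTable$image_id))
    stop("severity table must cover all images in C")
  st <- severityTable[match(ids, severityTable$image_id), ]
  ord <- order(match(st$cohort, .COHORT_LEVELS), st$sd)
  perm <- ids[ord]
  list(permutation = perm,
       C = C[perm, perm, drop = FALSE],
       clinical = st$cohort[ord],
       predicted = if ("predicted" %in% colnames(st)) st$predicted[ord]
                   else NULL)
}
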