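#' Combined score matrix over the three cohorts
#'
#' Horizontal concatenation of the CN, MCI and AD score matrices along the
#' bin axis: vertices x (3 * nBins), block order CN | MCI | AD. This is the
#' matrix whose singular modes diagnose whether the fitted score matrices
#' carry cohort-specific structure.
#'
#' @param S_cn,S_mci,S_ad Score matrices sharing vertex set and binning.
#' @return Matrix vertices x 3*nBins.
#' @export
combinedScoreMatrix <- function(S_cn, S_mci, S_ad) {
  if (!identical(rownames(S_cn), rownames(S_mci)) ||
      !identical(rownames(S_cn), rownames(S_ad)))
    stop("score matrices must share the same vertex set")
  if (ncol(S_cn) != ncol(S_mci) || ncol(S_cn) != ncol(S_ad))
    stop("score matrices must share the same binning")
  out <- cbind(S_cn, S_mci, S_ad)
  colnames(out) <- paste(rep(.COHORTS, each = ncol(S_cn)),
                         colnames(out), sep = "_")
  out
}

#' Leading singular modes of a combined score matrix
#'
#' Top-k singular values and vectors of the (uncentered) combined score
#' matrix. Each right singular vector is segmented into three length-nBins
#' cohort blocks (CN, MCI, AD over the bin index m), and the pairwise
#' cosine similarities between the blocks of each mode are reported as a
#' numeric diagnostic of how cohort-specific the mode is. Signs are fixed
#' so that the largest-magnitude component of each right vector is
#' positive.
#'
#' @param M Matrix from [combinedScoreMatrix()] (or any numeric matrix).
#' @param k Number of modes (default 6). If `k` exceeds the numerical
#'   rank, only the rank modes are returned with a warning.
#' @return List with `d` (singular values, descending), `u`, `v`,
#'   `segments` (per mode, a 3 x nBins matrix, when the column count is a
#'   multiple of 3) and `segmentCosines` (per mode, pairwise cosines).
#' @export
svdModes <- function(M, k = 6) {
  if (k > min(dim(M)))
    stop("k must not exceed the matrix dimensions")
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  rk <- sum(sv$d > tol)
  if (k > rk) {
    warning("requested ", k, " modes but rank is ", rk,
            "; returning ", rk)
    k <- rk
  }
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  segments <- segCos <- NULL
  if (ncol(M) %% 3 == 0) {
    nb <- ncol(M) / 3
    segments <- lapply(seq_len(k), function(j)
      matrix(v[, j], nrow = 3, byrow = TRUE,
             dimnames = list(.COHORTS, NULL)))
    cosine <- function(a, b) {
      na <- sqrt(sum(a^2)); nb_ <- sqrt(sum(b^2))
      if (na == 0 || nb_ == 0) return(NA_real_)
      sum(a * b) / (na * nb_)
    }
    segCos <- do.call(rbind, lapply(seq_len(k), function(j) {
      s <- segments[[j]]
      data.frame(mode = j,
                 cn_mci = cosine(s["CN", ], s["MCI", ]),
                 cn_ad = cosine(s["CN", ], s["AD", ]),
                 mci_ad = cosine(s["MCI", ], s["AD", ]))
    }))
  }
  list(d = d, u = u, v = v, segments = segments, segmentCosines = segCos)
}
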