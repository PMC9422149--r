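test_that("bin indices follow the lower-inclusive 0.2 mm convention", {
  expect_identical(binIndex(2.5), 13L)
  expect_identical(binIndex(0), 1L)
  expect_identical(binIndex(0.2), 2L)   # boundary goes to the upper bin
  expect_identical(binIndex(5.999999), 30L)
  expect_error(binIndex(6), "\\[0, 6\\)")
  expect_error(binIndex(-0.01), "\\[0, 6\\)")
  b <- binningSpec(delta = 0.3, nBins = 20)
  expect_identical(binIndex(0.3, b), 2L)
  expect_error(binningSpec(delta = 0.25, nBins = 30), "6 mm")
})

test_that("kernel coefficients match their closed forms", {
  k <- kernelWeights("integer-ratio")
  expect_equal(k$weights,
               c(1, 7, 21, 43, 56, 43, 21, 7, 1) / 200)
  expect_identical(sum(k$weights), 1)
  expect_equal(k$weights[5], 0.28)
  expect_equal(k$weights[1], 0.005)
  # kernel standard deviation in bin widths
  expect_equal(sqrt(sum(k$weights * k$offsets^2)), sqrt(412 / 200),
               tolerance = 1e-12)
  expect_equal(round(sqrt(sum(k$weights * k$offsets^2)), 3), 1.435)

  ke <- kernelWeights("erf-recursion")
  erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  expect_equal(ke$weights[5], erf_(0.25), tolerance = 1e-12)
  expect_equal(sum(ke$weights), 1, tolerance = 0.01)
  expect_equal(ke$weights, rev(ke$weights))  # symmetry a_l = a_-l
  expect_true(all(diff(ke$weights[5:9]) < 0))  # a_0 maximal, decaying

  kd <- kernelWeights("delta")
  expect_identical(kd$weights, 1)
  expect_error(kernelWeights("boxcar"))
})

test_that("probability matrices deposit kernel mass as hand-counted", {
  b <- binningSpec()
  # delta kernel, two images at one vertex
  v <- rbind(v1 = c(2.5, 2.7))
  colnames(v) <- c("i1", "i2")
  P <- probabilityMatrix(v, b, kernelWeights("delta"))
  expect_equal(unname(P[1, 13]), 0.5)
  expect_equal(unname(P[1, 14]), 0.5)
  expect_equal(sum(P), 1)

  # integer-ratio kernel, one image: bins 9..17 get the ratios/200
  v1 <- rbind(v1 = 2.5); colnames(v1) <- "i1"
  Pk <- probabilityMatrix(v1, b, kernelWeights("integer-ratio"))
  expect_equal(unname(Pk[1, 9:17]),
               c(1, 7, 21, 43, 56, 43, 21, 7, 1) / 200)
  expect_equal(sum(Pk), 1)

  # edge truncation: t = 0.1 is bin 1; only offsets 0..4 stay in range
  ve <- rbind(v1 = 0.1); colnames(ve) <- "i1"
  Pe <- probabilityMatrix(ve, b, kernelWeights("integer-ratio"))
  expect_equal(sum(Pe), (56 + 43 + 21 + 7 + 1) / 200)
  expect_equal(unname(attr(Pe, "truncated")), (1 + 7 + 21 + 43) / 200)
  expect_equal(sum(Pe) + attr(Pe, "truncated"), 1, ignore_attr = TRUE)

  expect_error(probabilityMatrix(v[, 0, drop = FALSE]), "empty cohort")
})

test_that("delta-mode rows sum to one; smoothed rows lose only truncated mass", {
  set.seed(9)
  v <- matrix(runif(4 * 12, 0.05, 5.95), 4, 12,
              dimnames = list(paste0("v", 1:4), paste0("i", 1:12)))
  Pd <- probabilityMatrix(v, kernel = kernelWeights("delta"))
  expect_equal(unname(rowSums(Pd)), rep(1, 4))
  Ps <- probabilityMatrix(v, kernel = kernelWeights("integer-ratio"))
  expect_equal(unname(rowSums(Ps) + attr(Ps, "truncated")), rep(1, 4),
               tolerance = 1e-12)
})

test_that("score matrix implements the normalized negative log probability", {
  # two vertices, rows uniform over the 30 bins: S = ln 15 everywhere
  P <- matrix(1 / 30, 2, 30, dimnames = list(c("v1", "v2"), NULL))
  S <- scoreMatrix(P)
  expect_equal(unname(S), matrix(-log((1 / 30) / (1 / 2)), 2, 30),
               ignore_attr = TRUE)
  expect_equal(S[1, 1], log(15), ignore_attr = TRUE)

  # zero-probability bins take the cap
  P2 <- rbind(v1 = c(0.5, 0.5, rep(0, 28)), v2 = rep(1 / 30, 30))
  S2 <- scoreMatrix(P2, cap = 50)
  expect_equal(unname(S2[1, 3]), 50)
  # within a vertex, larger P means strictly smaller S
  P3 <- rbind(v1 = (1:30) / sum(1:30))
  S3 <- scoreMatrix(P3)
  expect_true(all(diff(S3[1, ]) < 0))

  expect_error(scoreMatrix(rbind(v1 = rep(0, 30))), "all-zero")
})

test_that("delta-mode scores satisfy S = -ln P - ln N_p", {
  set.seed(13)
  v <- matrix(runif(6 * 20, 1, 4), 6, 20,
              dimnames = list(paste0("v", 1:6), paste0("i", 1:20)))
  P <- probabilityMatrix(v, kernel = kernelWeights("delta"))
  S <- scoreMatrix(P)
  pos <- P > 0
  expect_equal(S[pos], -log(P[pos]) - log(nrow(P)), tolerance = 1e-10)
})

test_that("total scores pick the argmin cohort with CN-first tie-break", {
  S <- list(CN = rbind(v1 = rep(10, 30)),
            MCI = rbind(v1 = rep(12, 30)),
            AD = rbind(v1 = rep(15, 30)))
  r <- totalScore(c(v1 = 2.5), S)
  expect_identical(r$predicted, "CN")
  expect_equal(r$S_CN, 10)

  Stie <- list(CN = rbind(v1 = rep(10, 30)),
               MCI = rbind(v1 = rep(10, 30)),
               AD = rbind(v1 = rep(15, 30)))
  expect_identical(totalScore(c(v1 = 2.5), Stie)$predicted, "CN")

  # single-vertex model where AD is most probable at the subject's bin
  sAD <- rep(5, 30); sAD[13] <- 1
  Sad <- list(CN = rbind(v1 = rep(3, 30)), MCI = rbind(v1 = rep(3, 30)),
              AD = rbind(v1 = sAD))
  expect_identical(totalScore(c(v1 = 2.5), Sad)$predicted, "AD")

  expect_error(totalScore(c(v9 = 2.5), S), "missing")
})

test_that("classification is invariant under shifting all score matrices", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 2))
  x <- sim$experiment
  model <- fitScoreModel(x)
  base <- classifyImages(model, x)
  shifted <- model
  for (g in names(shifted@groups))
    shifted@groups[[g]]$S <- lapply(shifted@groups[[g]]$S,
                                    function(S) S + 7.5)
  expect_identical(classifyImages(shifted, x)$predicted, base$predicted)
})

test_that("delta and smoothed kernels agree on the modal bin of P", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 3))
  x <- sim$experiment
  md <- fitScoreModel(x, kernel = "delta")
  mk <- fitScoreModel(x, kernel = "integer-ratio")
  g <- md@groups[[1]]$label
  Pd <- md@groups[[g]]$P$CN
  Pk <- mk@groups[[g]]$P$CN[rownames(Pd), , drop = FALSE]
  # compare on vertices with an unambiguous delta-mode mode
  amb <- apply(Pd, 1, function(r) sum(r == max(r)) > 1)
  expect_gt(mean(apply(Pd[!amb, ], 1, which.max) ==
                 apply(Pk[!amb, ], 1, which.max)), 0.9)
  # smoothed rows are smoother: fewer empty bins
  expect_lt(mean(Pk == 0), mean(Pd == 0))
})

test_that("a group missing a cohort fails with an informative error", {
  set.seed(31)
  v <- matrix(runif(10 * 9, 2, 3), 10, 9,
              dimnames = list(paste0("v", 1:10), paste0("i", 1:9)))
  te <- ThicknessExperiment(v, toyMetadata(colnames(v),
                                           rep(c("CN", "MCI", "AD"), 3)))
  # single window, but drop AD images so the cohort is absent
  keep <- cohorts(te) != "AD"
  expect_error(
    fitScoreModel(te[, keep], nGroups = 1, trimFraction = 0),
    "cohort AD")
})

test_that("model serialization round-trips bit-identically", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 4))
  x <- sim$experiment
  model <- fitScoreModel(x)
  dir <- tempfile()
  saveScoreModel(model, dir)
  back <- readScoreModel(dir)
  expect_identical(back@windows@lower, model@windows@lower)
  expect_identical(back@kernel$weights, model@kernel$weights)
  for (g in names(model@groups)) {
    expect_identical(back@groups[[g]]$essential$vertexIds,
                     model@groups[[g]]$essential$vertexIds)
    stripA <- function(m) { m <- unclass(m); attributes(m) <-
      attributes(m)[c("dim", "dimnames")]; m }
    expect_identical(stripA(back@groups[[g]]$S$AD),
                     stripA(model@groups[[g]]$S$AD))
    expect_identical(stripA(back@groups[[g]]$P$CN),
                     stripA(model@groups[[g]]$P$CN))
    expect_identical(back@groups[[g]]$maxT2, model@groups[[g]]$maxT2)
    expect_identical(back@groups[[g]]$severity$sd,
                     model@groups[[g]]$severity$sd)
  }
  expect_identical(classifyImages(back, x)$predicted,
                   classifyImages(model, x)$predicted)
})
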