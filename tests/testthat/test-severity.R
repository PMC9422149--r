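test_that("profile normalization uses the population convention", {
  tp <- normalizeProfiles(rbind(v1 = c(2.0, 2.2)))
  expect_equal(unname(tp[1, ]), c(-1, 1))   # mean 2.1, population sd 0.1
  expect_equal(unname(attr(tp, "center")), 2.1)
  expect_equal(unname(attr(tp, "scale")), 0.1)

  # idempotence on an already standardized row
  tp2 <- normalizeProfiles(tp)
  expect_equal(tp2, tp, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(normalizeProfiles(rbind(v1 = c(2.2, 2.2))), "constant")
})

test_that("covariance correlation matches the hand-computed Gram example", {
  tpr <- cbind(CN1 = c(1, 0), CN2 = c(0, 1), AD1 = c(-1, 0),
               AD2 = c(0, -1))
  rownames(tpr) <- c("v1", "v2")
  C <- covarianceCorrelation(tpr)
  expect_equal(max(C), 1)
  expect_equal(attr(C, "maxT2"), 1)
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_equal(C["CN1", "AD1"], -1)
  expect_equal(C["CN1", "CN2"], 0)
  expect_identical(C, t(C))
  # duplicated profiles are perfectly correlated
  twin <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, 0, 1))
  Ct <- covarianceCorrelation(twin)
  expect_equal(Ct["a", "b"], Ct["a", "a"])
  expect_error(covarianceCorrelation(tpr[, 1, drop = FALSE]), "2 images")
})

test_that("severity degree reproduces the four-subject closed form", {
  tpr <- cbind(CN1 = c(1, 0), CN2 = c(0, 1), AD1 = c(-1, 0),
               AD2 = c(0, -1))
  rownames(tpr) <- c("v1", "v2")
  C <- covarianceCorrelation(tpr)
  sev <- severityDegree(C, c("CN", "CN", "AD", "AD"))
  expect_equal(sev$cbar, c(-1, -1, 1, 1))
  expect_equal(sev$sd, c(0, 0, 1, 1))
})

test_that("CN and AD severity means are exactly 0 and 1 on any data", {
  set.seed(41)
  for (rep_ in 1:4) {
    n <- sample(8:20, 1)
    coh <- sample(c("CN", "MCI", "AD"), n, replace = TRUE)
    coh[1:2] <- c("CN", "AD")
    tpr <- matrix(rnorm(12 * n), 12, n,
                  dimnames = list(NULL, paste0("i", 1:n)))
    C <- covarianceCorrelation(tpr)
    for (incl in c(TRUE, FALSE)) {
      if (!incl && (sum(coh == "CN") < 2 || sum(coh == "AD") < 2)) next
      sev <- severityDegree(C, coh, includeSelf = incl)
      expect_equal(mean(sev$sd[coh == "CN"]), 0, tolerance = 1e-10)
      expect_equal(mean(sev$sd[coh == "AD"]), 1, tolerance = 1e-10)
    }
  }
})

test_that("severity is invariant under rescaling the standardized profiles", {
  set.seed(43)
  tpr <- matrix(rnorm(10 * 9), 10, 9,
                dimnames = list(NULL, paste0("i", 1:9)))
  coh <- rep(c("CN", "MCI", "AD"), 3)
  sd1 <- severityDegree(covarianceCorrelation(tpr), coh)$sd
  sd2 <- severityDegree(covarianceCorrelation(tpr * 3.7), coh)$sd
  expect_equal(sd1, sd2, tolerance = 1e-12)
})

test_that("new-image severity is consistent with training severity", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 6))
  x <- sim$experiment
  model <- fitScoreModel(x)
  sev <- trainingSeverity(model)
  tm <- thickness(x)

  # a query identical to a training AD image reproduces its training SD
  ad <- sev$image_id[sev$cohort == "AD"][1]
  got <- severityForNew(model, tm[, ad])
  expect_equal(got$sd, sev$sd[sev$image_id == ad], tolerance = 1e-10)

  # the CN centroid of a group maps to SD = 0 (linearity of Cbar)
  g <- sev$group[sev$image_id == ad]
  cnImgs <- sev$image_id[sev$group == g & sev$cohort == "CN"]
  adImgs <- sev$image_id[sev$group == g & sev$cohort == "AD"]
  cnCentroid <- rowMeans(tm[, cnImgs, drop = FALSE])
  adCentroid <- rowMeans(tm[, adImgs, drop = FALSE])
  expect_equal(severityForNew(model, cnCentroid)$sd, 0, tolerance = 1e-10)
  expect_equal(severityForNew(model, adCentroid)$sd, 1, tolerance = 1e-10)

  # interpolating CN -> AD centroid gives monotone non-decreasing SD
  lam <- seq(0, 1, by = 0.2)
  sds <- vapply(lam, function(l)
    severityForNew(model, (1 - l) * cnCentroid + l * adCentroid)$sd,
    numeric(1))
  expect_true(all(diff(sds) >= -1e-12))

  # a query far outside the windows is refused
  expect_error(severityForNew(model, cnCentroid + 2), "outside")
})

test_that("reordering by severity sorts cohort blocks and is idempotent", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 7))
  model <- fitScoreModel(sim$experiment)
  g <- model@groups[[1]]
  C <- covarianceCorrelation(g$tprime)
  ord <- reorderBySeverity(C, g$severity)
  expect_setequal(ord$permutation, colnames(C))
  blocks <- rle(ord$clinical)$values   # cohort blocks must be contiguous
  expect_identical(blocks, intersect(c("CN", "MCI", "AD"), blocks))
  within <- split(seq_along(ord$permutation), ord$clinical)
  sd <- g$severity$sd[match(ord$permutation, g$severity$image_id)]
  for (ix in within) expect_true(all(diff(sd[ix]) >= 0))

  again <- reorderBySeverity(ord$C, g$severity)
  expect_identical(again$permutation, ord$permutation)
  expect_identical(again$C, ord$C)

  # planted structure: AD block coheres more than AD-vs-CN cross block
  adIx <- which(ord$clinical == "AD"); cnIx <- which(ord$clinical == "CN")
  expect_gt(mean(ord$C[adIx, adIx]), mean(ord$C[adIx, cnIx]))
})

test_that("latent severity ordering is recovered on the gradient preset", {
  sim <- simulateCohortStudy(simulationPreset("severity-gradient",
                                              seed = 1))
  model <- fitScoreModel(sim$experiment)
  sev <- trainingSeverity(model)
  subj <- unname(subjectIds(sim$experiment)[sev$image_id])
  s <- sim$truth$severity[subj]
  expect_gte(cor(sev$sd, s, method = "spearman"), 0.9)
})
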