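test_that("pairwise Z matches the Welch statistic with sample variance", {
  v <- rbind(v1 = c(2.5, 2.6, 2.7, 2.0, 2.1, 2.2))
  colnames(v) <- paste0("i", 1:6)
  te <- ThicknessExperiment(
    v, toyMetadata(colnames(v), rep(c("CN", "AD"), each = 3)))
  z <- pairwiseZ(te, "CN-AD")
  # oracle: direct evaluation
  cn <- c(2.5, 2.6, 2.7); ad <- c(2.0, 2.1, 2.2)
  expected <- (mean(cn) - mean(ad)) /
    sqrt(var(cn) / 3 + var(ad) / 3)
  expect_equal(z$z, expected, tolerance = 1e-12)
  expect_equal(z$z, 6.1237, tolerance = 1e-4)
  expect_equal(z$mean1, mean(cn))
  expect_equal(z$n2, 3L, ignore_attr = TRUE)

  # antisymmetry under swapping the pair (relabel cohorts)
  te2 <- ThicknessExperiment(
    v, toyMetadata(paste0("i", 1:6), rep(c("AD", "CN"), each = 3)))
  expect_equal(pairwiseZ(te2, "CN-AD")$z, -z$z)
})

test_that("identical cohorts give Z = 0 and tiny cohorts error", {
  v <- rbind(v1 = c(2.5, 2.6, 2.5, 2.6))
  colnames(v) <- paste0("i", 1:4)
  te <- ThicknessExperiment(v, toyMetadata(colnames(v),
                                           c("CN", "CN", "AD", "AD")))
  expect_equal(pairwiseZ(te, "CN-AD")$z, 0)
  te1 <- ThicknessExperiment(v, toyMetadata(colnames(v),
                                            c("CN", "AD", "AD", "AD")))
  expect_error(pairwiseZ(te1, "CN-AD"), "fewer than 2")
})

test_that("zero pooled variance yields an infinite sentinel with warning", {
  v <- rbind(v1 = c(2.5, 2.5, 2.1, 2.1), v2 = c(2.2, 2.2, 2.2, 2.2))
  colnames(v) <- paste0("i", 1:4)
  te <- ThicknessExperiment(v, toyMetadata(colnames(v),
                                           c("CN", "CN", "AD", "AD")))
  expect_warning(z <- pairwiseZ(te, "CN-AD"), "zero pooled variance")
  expect_identical(z$z, c(Inf, 0))
})

test_that("Z is invariant under a common shift and obeys the x/y-axis identity", {
  set.seed(21)
  for (rep_ in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- matrix(runif(4 * (n1 + n2), 2, 3), nrow = 4)
    dimnames(v) <- list(paste0("v", 1:4), paste0("i", seq_len(n1 + n2)))
    coh <- rep(c("CN", "AD"), c(n1, n2))
    te <- ThicknessExperiment(v, toyMetadata(colnames(v), coh))
    z <- pairwiseZ(te, "CN-AD")
    shifted <- ThicknessExperiment(v + 0.5, toyMetadata(colnames(v), coh))
    expect_equal(pairwiseZ(shifted, "CN-AD")$z, z$z, tolerance = 1e-10)
    # separation axes: x, y normalized by each cohort's dispersion alone;
    # Z^2 = [x^-2 + y^-2]^-1
    x <- (z$mean1 - z$mean2) / sqrt(z$sd1^2 / z$n1)
    y <- (z$mean1 - z$mean2) / sqrt(z$sd2^2 / z$n2)
    expect_equal(z$z^2, 1 / (1 / x^2 + 1 / y^2), tolerance = 1e-10)
  }
})

test_that("ROI selection applies the |Z| cutoff with union and nesting", {
  zp <- data.frame(vertex_id = c("v1", "v2", "v3"),
                   z = c(1.6, -1.7, 1.4))
  attr(zp, "pair") <- "CN-AD"
  roi <- selectROI(zp, cutoff = 1.5)
  expect_identical(roi$vertexIds, c("v1", "v2"))
  expect_identical(selectROI(zp, cutoff = 0)$vertexIds,
                   c("v1", "v2", "v3"))
  # nested cutoffs: higher-cutoff set is a subset
  set.seed(5)
  zr <- data.frame(vertex_id = paste0("v", 1:200), z = rnorm(200, 0, 2))
  attr(zr, "pair") <- "CN-AD"
  hi <- selectROI(zr, cutoff = 3.0)$vertexIds
  lo <- selectROI(zr, cutoff = 1.5)$vertexIds
  expect_true(all(hi %in% lo))
  # empty set warns
  zlow <- data.frame(vertex_id = "v1", z = 0.2)
  attr(zlow, "pair") <- "CN-AD"
  expect_warning(empty <- selectROI(zlow), "empty")
  expect_length(empty$vertexIds, 0)
})

test_that("essential selection uses per-pair cutoffs with union semantics", {
  mk <- function(z, pair) {
    d <- data.frame(vertex_id = paste0("v", seq_along(z)), z = z)
    attr(d, "pair") <- pair
    d
  }
  zp <- list(mk(c(3.5, 0.5), "CN-MCI"), mk(c(0, 0.5), "CN-AD"),
             mk(c(0, 0.5), "MCI-AD"))
  ess <- selectEssentialROI(zp, cutoffs = 3)
  expect_identical(ess$vertexIds, "v1")
  expect_true(ess$essential)
  expect_error(selectEssentialROI(zp, cutoffs = 1.0, roiCutoff = 1.5),
               ">=")
  expect_warning(
    none <- selectEssentialROI(list(mk(c(0.1, 0.2), "CN-MCI")),
                               cutoffs = 3),
    "empty")
  expect_length(none$vertexIds, 0)
  # intersection mode is stricter than union
  zp2 <- list(mk(c(4, 4), "CN-MCI"), mk(c(4, 0), "CN-AD"))
  expect_identical(
    selectEssentialROI(zp2, 3, combine = "intersection")$vertexIds, "v1")
})

test_that("vertex categories follow the monotone/thicker/thinner rules", {
  mk <- function(m1, m2, z, pair) {
    d <- data.frame(vertex_id = paste0("v", seq_along(z)),
                    z = z, mean1 = m1, mean2 = m2,
                    sd1 = 0.1, sd2 = 0.1, n1 = 10, n2 = 10)
    attr(d, "pair") <- pair
    d
  }
  # v1: monotone CN>MCI>AD; v2: CN-thinner; v3: nothing significant
  zp <- list(
    "CN-MCI" = mk(c(2.6, 2.2, 2.4), c(2.4, 2.5, 2.4), c(4, -4, 0.2),
                  "CN-MCI"),
    "CN-AD" = mk(c(2.6, 2.2, 2.4), c(2.2, 2.5, 2.4), c(8, -4, 0.3),
                 "CN-AD"),
    "MCI-AD" = mk(c(2.4, 2.5, 2.4), c(2.2, 2.5, 2.4), c(4, 0.1, 0.1),
                  "MCI-AD"))
  cats <- categorizeVertices(zp, cutoff = 1.5)
  expect_identical(cats$category,
                   c("monotone-descending", "CN-thinner", "none"))
})

test_that("essential selection recovers planted vertices on separated data", {
  sim <- simulateCohortStudy(simulationPreset("separated", seed = 1))
  ess <- selectEssentialROI(allPairwiseZ(sim$experiment), cutoffs = 3.5,
                            roiCutoff = 1.5)
  planted <- unlist(sim$truth$planted, use.names = FALSE)
  sens <- mean(planted %in% ess$vertexIds)
  fpr <- length(setdiff(ess$vertexIds, planted)) /
    (length(vertexIds(sim$experiment)) - length(planted))
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.01)
})
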