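# Shared fixture builders. Everything is generated in code; no data files.

.cohorts <- c("CN", "MCI", "AD")
.pairs <- c("CN-MCI", "CN-AD", "MCI-AD")

# minimal metadata for a set of image ids, one subject per image by default
toyMetadata <- function(imageIds, cohort,
                        subjectIds = paste0("S", seq_along(imageIds))) {
  data.frame(image_id = imageIds, subject_id = subjectIds,
             cohort = cohort, stringsAsFactors = FALSE)
}

# small deterministic ThicknessExperiment: nv vertices, 3 images per cohort
toyExperiment <- function(nv = 5, perCohort = 3, seed = 7, sd = 0.15) {
  set.seed(seed)
  n <- 3 * perCohort
  ids <- sprintf("img%02d", seq_len(n))
  coh <- rep(.cohorts, each = perCohort)
  base <- runif(nv, 2.1, 2.9)
  shift <- c(CN = 0.25, MCI = 0, AD = -0.25)
  v <- sapply(seq_len(n), function(j)
    base + shift[coh[j]] * (seq_len(nv) %% 2) + rnorm(nv, 0, sd))
  dimnames(v) <- list(sprintf("v%03d", seq_len(nv)), ids)
  ThicknessExperiment(v, toyMetadata(ids, coh))
}

# all three pairwise Z profiles for an experiment / image subset
allPairwiseZ <- function(x, images = NULL) {
  zp <- lapply(.pairs, function(p) pairwiseZ(x, p, images = images))
  setNames(zp, .pairs)
}

# write a ThicknessExperiment to tempfiles, return the two paths
writeToTemp <- function(x, digits = 6) {
  tf <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".tsv")
  writeThicknessMatrix(x, tf, mf, digits = digits)
  c(thickness = tf, metadata = mf)
}

# reassign cohort labels balanced at random within each thickness group
# (stratified permutation null)
stratifiedShuffle <- function(x, windows, seed) {
  cd <- SummarizedExperiment::colData(x)
  asg <- assignGroups(meanThickness(x), windows)
  md <- data.frame(subject_id = cd$subject_id,
                   group = asg$group[match(cd$image_id, asg$image_id)])
  subj <- md[!duplicated(md$subject_id), ]
  newcoh <- setNames(rep(NA_character_, nrow(subj)), subj$subject_id)
  withr::with_seed(seed, {
    for (g in split(subj, subj$group))
      newcoh[g$subject_id] <-
        sample(rep(.cohorts, length.out = nrow(g)))
  })
  cd$cohort <- unname(newcoh[cd$subject_id])
  SummarizedExperiment::colData(x) <- cd
  x
}
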