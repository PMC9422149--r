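---
title: "Score-matrix classification and continuous severity staging from cortical thickness"
author: "CorticalScore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-matrix classification and continuous severity staging from cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorticalScore)
```

## The problem

Cortical thinning is one of the anatomical imprints of Alzheimer's disease
(AD), but person-to-person variation in overall cortical thickness is large
enough that a cognitively normal (CN) person can have a thinner cortex than
a person with AD, and most of the cortex carries no disease signal at all.
CorticalScore implements an algebraic classifier and a continuous severity
predictor that work directly on a vertex-by-image matrix of cortical
thickness values $t_{p,h}$ (vertex $p$, MR image $h$, in mm, as produced by
surface-based MRI pipelines at hundreds of thousands of vertices):

1. images are partitioned into groups by mean cortical thickness, which
   removes the dominant "globally thick vs globally thin" nuisance axis;
2. within each group, discriminative vertices are selected by pairwise
   Welch $Z$ statistics between the CN, MCI (mild cognitive impairment)
   and AD cohorts;
3. a per-cohort *score matrix* over binned thickness turns a new image's
   profile into three summed negative-log-probability scores, and the
   smallest score names the predicted cohort;
4. a *covariance correlation matrix* between standardized profiles yields
   a continuous severity degree per image, affinely scaled so CN
   references average exactly 0 and AD references average exactly 1.

The package also ships a synthetic cohort generator with full ground
truth, so every stage is testable without access to clinical data.

## Thickness groups

The per-image mean thickness $\langle t \rangle$ is computed over all
(complete) vertices, and images are assigned to contiguous, half-open
windows `A` (thickest) through `D`. The window boundaries of the original
study are not published; the default therefore derives equal-count windows
from the quantiles of the training means, after trimming a configurable
fraction (default 0.4% in total, mirroring an out-of-bounds exclusion of
roughly 6 images in 1500) at the two extremes. Explicit boundaries can be
supplied instead (`makeGroupWindows(mode = "explicit")`). Windows are
lower-inclusive and upper-exclusive; a mean on a boundary belongs to the
thicker window. Group windows are a *trained* quantity: during
cross-validation they are re-derived from each training fold.

## ROI and essential-ROI vertices

For each cohort pair within a group,
$$Z_p = \frac{\langle t_{p,h\in k_1}\rangle - \langle t_{p,h\in k_2}\rangle}
 {\sqrt{\sigma^2_{p,k_1}/n_{k_1} + \sigma^2_{p,k_2}/n_{k_2}}},$$
with $n$ counting images and $\sigma^2$ the unbiased sample variance (the
standard convention for Welch-type statistics; the population convention
is used later for profile standardization, where the defining equation is
written that way). Vertices with $|Z| > 1.5$ in any pair form the ROI set;
*essential* ROI vertices must clear a higher per-pair cutoff (default 3.0
for every pair, configurable per pair) and are the only vertices the
classifier and the severity predictor use. The per-group, per-pair
cutoffs of the original study are not published; 3.0 is "much higher"
than 1.5 while keeping a few dozen vertices on realistic effect sizes.
Essential membership combines the three pairwise criteria by union
(maximizing discriminative coverage; intersection is available).

Vertices can additionally be categorized by the pattern of cohort means
(`categorizeVertices()`): monotone-descending (CN > MCI > AD with both
adjacent $|Z|$ above cutoff), or X-thicker / X-thinner when one cohort
differs from both others in the same direction; the priority when several
patterns hold is monotone first, then CN, MCI, AD.

## Probability and score matrices

Thickness is binned into $m = 1,\dots,30$ bins of width
$\Delta = 0.2$ mm, covering 0-6 mm. Bin membership is lower-inclusive and
upper-exclusive ($m = \lfloor t/\Delta\rfloor + 1$): the defining
indicator functions are ambiguous exactly on a boundary, and a partition
is required, so the boundary value goes to the upper bin (documented and
tested).

Each image of a cohort deposits kernel mass $a_l$ into bins $m+l$,
$l = -4,\dots,4$, around its own bin — a discrete kernel density
estimate that compensates for small cohorts. Two kernels are provided:

* **integer-ratio** (default): weights proportional to
  $56\!:\!43\!:\!21\!:\!7\!:\!1$, normalized to total mass exactly 1;
  its standard deviation is $\sqrt{412/200} = 1.4353$ bin widths,
  matching the printed $\sigma_f \approx 1.435$;
* **erf-recursion**: $a_0 = \mathrm{erf}(0.25)$ and
  $a_l = 0.5\,\mathrm{erf}(0.25+0.5l) + a_0/2 - \sum_{l'<l} a_{l'}$,
  giving ratios $\approx 55.3\!:\!43.5\!:\!21.2\!:\!6.4\!:\!1.2$
  (total mass $\approx 0.9987$, $\sigma \approx 1.431$). The rounding
  that leads from these to the printed integer ratios is not specified;
  since the printed $\sigma_f$ matches the integer ratios exactly, the
  integer-ratio kernel is the default and the recursion is kept for
  fidelity.

A **delta** (unsmoothed) mode is available for exact-identity checks.
Kernel mass falling outside bins 1-30 is truncated, not renormalized
(the defining sum runs over bins 1-30 only and gives no edge rule); the
truncated mass is recorded per vertex. At realistic thickness values
(1-4 mm) the edge is more than 4 bins away and no mass is lost.

The score matrix is
$$S_{p,m} = -\ln\!\left[\frac{Q_{p,m}}{Q_p}\right],\qquad
  Q_{p,m} = \frac{P_{p,m}}{\sum_m P_{p,m}},\qquad
  Q_p = \frac{\sum_m P_{p,m}}{\sum_p\sum_m P_{p,m}}.$$
Bins with zero probability would give an infinite score; they receive a
configurable cap (default 50 — the score a bin of probability
$e^{-50}$ would earn, far below anything attainable, so a cap event
dominates any sum it enters without overflowing). In delta mode
$\sum_m P_{p,m} = 1$ and the identity
$S_{p,m} = -\ln P_{p,m} - \ln N_p$ holds exactly (tested to $10^{-10}$).

A subject's total score per cohort sums $S_{p,m'(p)}$ over the essential
vertices of its group, where $m'(p)$ is the bin of the subject's
thickness at $p$; the predicted cohort attains the minimum, with ties
broken deterministically CN < MCI < AD.

## SVD diagnostics

Concatenating the three cohort score matrices along the bin axis
(vertices $\times$ 90, block order CN | MCI | AD) and taking the leading
singular modes shows how much cohort-specific structure the model
carries: each right singular vector holds one curve per cohort over the
bin index. The matrix is not centered before decomposition (uncentered
is the plain reading of the source analysis). Singular-vector signs are
arbitrary, so each vector is scaled to make its largest-magnitude
component positive, which makes results reproducible across runs. The
pairwise cosine similarities between the three cohort segments of each
mode are reported as numbers; typically the first modes are shared
"default" shapes (cosines near 1) while later modes differentiate the
cohorts.

## Covariance correlation and the severity degree

Within a group, thickness at the essential vertices is standardized per
vertex, $t'_{p,h} = (t_{p,h} - \langle t_{p,h}\rangle_h)/\sigma_p$ with
$\sigma_p^2 = \langle t^2\rangle - \langle t\rangle^2$ (population
convention, exactly as the defining equation is written), pooling all
cohorts of the group. The Gram matrix $t''_{ij} = \sum_p t'_{p,i}
t'_{p,j}$, normalized by its maximum element (taken over all elements,
including the diagonal), is the covariance correlation matrix $C$ with
$\max C = 1$. The severity degree of image $i$ is
$$SD_i = \frac{\bar C_i - \langle \bar C\rangle_{CN}}
              {\langle \bar C\rangle_{AD} - \langle \bar C\rangle_{CN}},
  \qquad \bar C_i = \langle C_{ij}\rangle_{j\in AD}
                  - \langle C_{ij}\rangle_{j\in CN}.$$
Two identities follow algebraically and hold on every dataset to float
precision: the mean of $SD$ over CN references is exactly 0 and over AD
references exactly 1. MCI images enter $t'$ and $C$ but never the
reference averages. The reference averages include the $j = i$ self term
when applicable (the choice is switchable; the 0/1 identities hold
either way, and including it makes a query identical to a training
image reproduce that image's training severity exactly). For a new
image, the training per-vertex mean/sd, the normalizing constant
$\max t''$ and the two reference constants are frozen, so severity is a
pure plug-in evaluation; because $\bar C$ is linear in the query
profile, severity along the segment from the CN centroid to the AD
centroid is exactly linear from 0 to 1.

## Validation

`selfRecognition()` classifies the training images with their own model.
`crossValidate()` runs stratified k-fold (default threefold)
cross-validation in which *everything* — group windows, ROI and
essential-ROI selection, probability and score matrices — is re-fitted
on each training fold; anything less would leak test labels through the
vertex selection. Stratification is by thickness group × cohort, and the
default unit is the subject, so the two acquisitions (e.g. MPRAGE and
MPRAGE_SENSE2) of one subject can never straddle the train/test split;
per-image stratification is available for comparison with study designs
that split by image. `k` equal to the number of units degenerates to
leave-one-out.

## The synthetic cohort generator

`simulateCohortStudy()` draws
$$t_{p,h} = \text{baseline}_p + \text{offset}_{s(h)} +
  \text{effect}_{p,s(h)} + \varepsilon_{p,h},$$
with a per-vertex baseline uniform on 2-3 mm, a Gaussian per-subject
global offset (default sd 0.1 mm, which spreads image means across the
four group windows the way a 0.05 mm-wide window structure requires),
planted effect vertices in three disjoint sets mirroring the vertex
categories (AD-thinner, AD-thicker, monotone-descending with the MCI
step at half the AD step), i.i.d. Gaussian measurement noise (default
sd 0.1 mm — chosen as the simplest structure matching the Z statistic's
assumptions), and two twin images per subject that share all subject
terms and differ only by noise. In latent-severity mode each subject
carries $s \in [0,1]$ (CN uniform on [0, 0.1], AD on [0.9, 1], MCI on
[0, 1], so MCI spans both basins) and all planted effects scale
linearly with $s$.

Presets fix the study conditions used throughout the tests:
`separated` (300 vertices, 100 images/cohort, 0.3 mm effects against
0.1 mm noise, i.e. standardized $d = 3$ at AD-contrast vertices and
$d = 1.5$ at the MCI step), `overlapping` (0.1 mm effects), `null`
(no effects), and `severity-gradient` (60 monotone vertices, 0.2 mm
full effect so $d_\max = 2$, latent-severity mode, offset spread
reduced to 0.05 mm — the global offset is a coherent nuisance mode of
the covariance correlation matrix, and this fixture exists to probe
ordering by latent severity, not offset trimming; the `separated`
preset keeps the full spread).

What the generator deliberately does **not** emulate: spatial
correlation between neighboring vertices, anatomically structured
effect regions, scanner/site batch effects, and non-Gaussian thickness
distributions. Passing recovery tests on these fixtures therefore
demonstrates correctness of the algorithms under their own
assumptions, not clinical performance.

## Numerical choices and degenerate inputs

* Values outside $[0,6)$ mm are rejected at load (`thicknessRangeError`)
  because the binning cannot represent them; missing entries are allowed
  only until `dropIncompleteVertices()`.
* Zero pooled variance at a vertex yields a $\pm\infty$ Z sentinel with a
  warning (0 when the means also agree); constant vertices must be
  excluded before standardization and produce a named error.
* An empty essential set is a warning, not an error: the group's images
  are reported as unscored rather than silently misclassified.
* Equal CN and AD reference averages make the severity scale degenerate
  and raise an error.
* Serialization writes every float with 17 significant digits, so a
  reloaded model reproduces scores and severities bit-identically.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on the presets
above (300 vertices, 300 images) and on toys of 5-10 vertices; a full
fit takes well under a second and the complete suite a few seconds.
Statistical checks on stochastic fixtures use fixed seeds and
tolerances stated next to each test; in particular the permutation-null
check pools three balanced within-group label permutations and compares
per-cohort accuracy with the binomial band around 1/3. Because all test
images in a fold share one fitted model, null predictions are weakly
correlated at the model level, which the binomial band cannot capture;
the pooled design keeps that correlation small, but this check is the
one most sensitive to the simulation seed.

## Known limitations

* MCI is intrinsically the hardest cohort: the severity degree of MCI
  subjects legitimately spans both basins, which is the method's point
  but caps MCI classification accuracy.
* The severity degree is a relative, cohort-anchored scale: it is only
  comparable across models sharing reference cohorts and essential
  vertices.
* Group windows, cutoffs and the score cap are data-scale dependent;
  defaults target thickness in mm with 0.2 mm bins.
* Within the CN and AD ends of the latent-severity scale the true
  ordering is nearly degenerate, so rank agreement there is limited by
  noise even for a perfect model.
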