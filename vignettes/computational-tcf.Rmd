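---
title: "Computational tumor cellular fraction: methods and workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational tumor cellular fraction: methods and workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantTCF)
```

## The problem

Molecular testing of tumor samples reports copy numbers and variant allele
fractions that are diluted by non-neoplastic cells. Laboratories therefore
estimate the *tumor cellular fraction* (TCF) — the proportion of viable
cells that are neoplastic — before sequencing, and use it both as an
adequacy gate and to correct copy-number calls for purity. Visual TCF
estimation is known to be biased upward and poorly reproducible between
observers: large tumor nuclei occupy a disproportionate share of the field,
so area-based perception overestimates the cell-count fraction.

`quantTCF` implements a computational alternative: count nuclei inside the
marked region of interest (ROI), classify each as `Tumor`, `NonNeoplastic`
or `Ignore` (non-nuclear objects), and report

$$\mathrm{cTCF} = \frac{n_\mathrm{Tumor}}{n_\mathrm{Tumor} + n_\mathrm{NonNeoplastic}}.$$

Because the cohort-scale behavior of such a pipeline can only be verified
against slides, the package also ships a fully synthetic test bed: an H&E
scene generator with per-nucleus ground truth, simulated observer panels,
and synthetic copy-number tables. Every stage is deterministic given its
seed.

## Synthetic scenes

`generateScene()` renders a Beer–Lambert two-stain H&E tile from sampled
elliptical nuclei. Tumor nuclei are drawn larger than non-neoplastic nuclei
(mean areas 80 vs 25 µm² by default), and artifacts are rendered
eosin-dominant with a hematoxylin density below any nucleus, so the three
classes are learnable from stain and morphometry features alone.

```{r scene}
spec <- sceneSpec(widthPx = 512, heightPx = 512,
                  nTumor = 15, nNonneo = 35, nArtifact = 5, seed = 11)
scene <- generateScene(spec)
scene
trueTCF(scene)
```

## Detection

`detectNuclei()` deconvolves the tile into hematoxylin and eosin optical
densities (Ruifrok–Johnston stain vectors), thresholds the hematoxylin
channel, and separates touching nuclei with a distance-map watershed.
Detections are filtered by area (8–400 µm² at 0.4416 µm/px) and by the
centroid-in-ROI rule: a nucleus belongs to the ROI if its centroid does,
and its polygon is clipped to the ROI boundary.

```{r detect}
det <- detectNuclei(sceneImage(scene), sceneROI(scene))
det
```

## Few-shot classification

`extractFeatures()` computes eight morphometric and stain features per
detection (area, perimeter, circularity, eccentricity, solidity, and the
mean/SD hematoxylin and mean eosin optical densities). A random forest is
trained from a deliberately small, class-balanced annotation set —
`annotationSet()` enforces equal `Tumor` and `NonNeoplastic` counts and a
per-class cap of ten — mirroring the few-annotation regime the workflow is
designed for. `learningCurve()` quantifies how accuracy depends on that
budget.

```{r classify}
m <- matchDetections(det, scene)          # ground-truth pairing, for training
set.seed(1)
idx <- unlist(lapply(c("Tumor", "NonNeoplastic", "Ignore"),
                     function(cl) sample(which(m$trueLabel %in% cl), 5)))
feats <- extractFeatures(sceneImage(scene), det)
clf <- trainClassifier(feats, annotationSet(m$id[idx], m$trueLabel[idx]),
                       seed = 1)
pred <- classifyDetections(clf, feats)
det <- setDetectionLabels(det, pred)
```

## TCF and the adequacy gate

`computeCTCF()` counts the labeled detections (`Ignore` is excluded from
both numerator and denominator) and applies the molecular adequacy gate:
at least 100 viable tumor cells *and* TCF ≥ 20 %, both inclusive.

```{r tcf}
res <- computeCTCF(det)
res
```

`tumorAreaFraction()` computes the area-based comparator: the share of ROI
area covered by tumor polygons. On scenes with few large tumor nuclei among
many small cells, it exceeds the count-based cTCF — the geometric origin of
visual overestimation.

## Purity-corrected copy-number calling

With observed copies $C$ in a sample of cellularity $f$, the
tumor-intrinsic copy number is

$$x = \frac{C - 2(1 - f)}{f},$$

the inversion of the two-population mixture $C = f x + (1-f)\,2$. A call is
reported as *confident* only when at least 5 of 6 criteria hold:
cellularity ≥ 50 %, ≥ 10,000 reads, MAPD ≤ 0.5, 5 % copy-number confidence
bound ≥ 4, corrected copies ≥ 5, and p ≤ 1e-5. `recallWithTCF()` re-applies
the correction with a revised (computational) cellularity, and
`compareCallSets()` tabulates how the software-call and confident-call sets
change:

```{r cnv}
correctCopyNumber(C = 3, f = 0.5)
co <- syntheticCNVCohort()
cmp <- compareCallSets(co$before, co$after)
c(software = cmp$softwarePctChange,
  confident = cmp$confidentPctChange,
  discrepancy = cmp$discrepancyPct)
```

On the bundled synthetic cohort, replacing the visual cellularity with the
computational one removes a small number of purity-inflated software calls
(−6.9 %), nearly doubles the confident-call yield (+85.7 %), and reveals a
24 % discrepancy between the two call sets.

## Observer agreement

TCF scores are ordinal once binned (`binTCF()`); `weightedKappa()` computes
the quadratic weighted kappa

$$\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},
\qquad w_{ij} = \frac{(i-j)^2}{(k-1)^2},$$

with a one-sided permutation test as the primary null procedure (the
marginals, hence the expected disagreement, are permutation-invariant) and
the large-sample normal approximation reported alongside.
`simulateObservers()` provides biased, noisy rating panels and
`agreementMatrix()` the pairwise table.

```{r kappa}
set.seed(7)
truth <- runif(60, 5, 95)
ratings <- data.frame(case_id = sprintf("c%02d", 1:60),
                      obsA = pmin(100, pmax(0, truth + rnorm(60, 18, 10))),
                      obsB = pmin(100, pmax(0, truth + rnorm(60, 22, 10))))
agreementMatrix(ratings, truth = truth, binWidth = 10, nPerm = 500)
```

## The full report

`runReport()` chains every stage on a simulated cohort — scenes, detection,
few-shot classification, cTCF with adequacy flags, biased observer panels,
the cTCF-vs-observer direction counts, the agreement matrix, and a CNV
re-call — and optionally writes a reproducible bundle (CSV tables, JSON
report, and a manifest with seeds and a config hash). Identical
configuration and seed reproduce every output bit-identically.

```{r report, eval = FALSE}
cfg <- pipelineConfig(nCases = 8)
report <- runReport(cfg, seed = 1, outDir = "report")
report$scoreComparison$counts
```

With positively biased observers, the report reproduces the qualitative
finding the pipeline exists to demonstrate: the mean visual score exceeds
the mean computational score, and the per-case direction counts show a
"lower" majority for cTCF.
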