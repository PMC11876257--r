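test_that("scene generation conserves spec counts and labels", {
  spec <- sceneSpec(widthPx = 512, heightPx = 512,
                    nTumor = 30, nNonneo = 70, nArtifact = 10, seed = 1)
  scene <- generateScene(spec)
  cells <- sceneCells(scene)
  expect_equal(nrow(cells), 110L)
  tab <- table(cells$trueClass)
  expect_equal(unname(tab[["Tumor"]]), 30L)
  expect_equal(unname(tab[["NonNeoplastic"]]), 70L)
  expect_equal(unname(tab[["Artifact"]]), 10L)
  # the true scene TCF is recomputable from the emitted labels
  expect_equal(trueTCF(scene), 30 / 100)
  # every centroid lies inside the ROI
  roi <- sceneROI(scene)
  expect_true(all(quantTCF:::.pointsInPolygon(cells$x, cells$y, roi)))
})

test_that("the empty spec yields a blank stroma tile", {
  scene <- generateScene(sceneSpec(widthPx = 128, heightPx = 128,
                                   nTumor = 0, nNonneo = 0, nArtifact = 0))
  expect_equal(nrow(sceneCells(scene)), 0L)
  expect_true(is.na(trueTCF(scene)))
  img <- sceneImage(scene)
  expect_equal(dim(img), c(128L, 128L, 3L))
  # blank background: hematoxylin OD stays near the stromal level everywhere
  od <- deconvolveStains(img)
  expect_lt(max(od$odH), 0.2)
})

test_that("identical spec and seed reproduce the scene bit-identically", {
  spec <- sceneSpec(widthPx = 384, heightPx = 384,
                    nTumor = 10, nNonneo = 20, nArtifact = 3, seed = 4)
  s1 <- generateScene(spec)
  s2 <- generateScene(spec)
  expect_identical(sceneImage(s1), sceneImage(s2))
  expect_identical(sceneCells(s1), sceneCells(s2))
  expect_identical(scenePolygons(s1), scenePolygons(s2))
})

test_that("zero-overlap scenes have strictly disjoint polygons", {
  scene <- generateScene(sceneSpec(widthPx = 384, heightPx = 384,
                                   nTumor = 12, nNonneo = 25, nArtifact = 4,
                                   maxOverlapFrac = 0, seed = 9))
  polys <- scenePolygons(scene)
  cells <- sceneCells(scene)
  rmax <- vapply(seq_along(polys), function(i) {
    max(sqrt((polys[[i]][, 1] - cells$x[i])^2 + (polys[[i]][, 2] - cells$y[i])^2))
  }, numeric(1))
  for (i in seq_along(polys)) for (j in seq_len(i - 1L)) {
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    expect_gt(d, rmax[i] + rmax[j])
  }
})

test_that("infeasible object counts raise an overcrowded-scene error", {
  expect_error(
    generateScene(sceneSpec(widthPx = 96, heightPx = 96, roiMarginPx = 8,
                            nTumor = 150, nNonneo = 150, nArtifact = 0),
                  maxTriesPerObject = 50L),
    "overcrowded")
})

test_that("rendered optical densities are ordered: nuclei > artifacts > background", {
  nucleus <- ellipseRing(30, 30, 10, 8)
  artifact <- ellipseRing(70, 70, 10, 8)
  img <- renderHE(list(nucleus, artifact), c("Tumor", "Artifact"),
                  100, 100, noiseSD = 0)
  od <- deconvolveStains(img)
  nucOd <- mean(od$odH[quantTCF:::.rasterizePolygon(ellipseRing(30, 30, 6, 5))])
  artOd <- mean(od$odH[quantTCF:::.rasterizePolygon(ellipseRing(70, 70, 6, 5))])
  bgOd <- mean(od$odH[1:10, 1:10])
  nucMin <- min(vapply(quantTCF:::.renderLevels()[c("Tumor", "NonNeoplastic")],
                       `[[`, numeric(1), "h"))
  expect_gt(nucOd, bgOd)
  expect_lt(artOd, nucMin)     # artifact hematoxylin below any nucleus
  expect_gt(artOd, bgOd)       # but detectable above stroma
  # artifacts are eosin-dominant (the red signature)
  artOdE <- mean(od$odE[quantTCF:::.rasterizePolygon(ellipseRing(70, 70, 6, 5))])
  expect_gt(artOdE, nucOd)
})

test_that("zero-noise zero-bias observers return rounded truth; ratings clip", {
  out <- simulateObservers(c(40), list(observerModel(bias = 0, noiseSD = 0)))
  expect_equal(out$obs1, 40)
  out <- simulateObservers(c(95), list(observerModel(bias = 20, noiseSD = 0)))
  expect_equal(out$obs1, 100)
  out <- simulateObservers(c(0), list(observerModel(bias = -30, noiseSD = 0)))
  expect_equal(out$obs1, 0)
})

test_that("observer bias is recovered by Monte Carlo within 3 SE", {
  set.seed(77)
  truth <- runif(121, 5, 60)
  mod <- observerModel(bias = 18, noiseSD = 10, seed = 123)
  out <- simulateObservers(truth, list(mod))
  delta <- out$obs1 - truth
  se <- sd(delta) / sqrt(length(delta))
  expect_lt(abs(mean(delta) - 18), 3 * se)
})

test_that("CNV table generator: empty case and paired tables differing only in f", {
  expect_equal(nrow(generateCNVTable(0, "pathologist")), 0L)
  pair <- pairedCNVTables(25, seed = 3)
  cols <- setdiff(names(pair$pathologist), "f")
  expect_identical(pair$pathologist[cols], pair$computational[cols])
  expect_false(identical(pair$pathologist$f, pair$computational$f))
  # pathologist cellularity runs higher on average, mirroring visual
  # over-estimation
  expect_gt(mean(pair$pathologist$f), mean(pair$computational$f))
})

test_that("tuned generator yields 7 gated records of 29 at pathologist cellularity", {
  tab <- generateCNVTable(29, "pathologist", seed = 7)
  expect_equal(sum(evaluateConfidence(tab)$confident), 7L)
})
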