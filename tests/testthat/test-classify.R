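test_that("geometric features match analytic values on ideal shapes", {
  img <- renderHE(list(), character(0), 200, 200, noiseSD = 0)
  circle <- ellipseRing(100, 100, 30, 30)
  f <- extractFeatures(img, circle, mpp = 1)
  expect_lt(abs(f$circularity - 1), 0.02)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$solidity, 0.98)
  expect_lt(abs(f$area_um2 - pi * 30^2) / (pi * 30^2), 0.02)
  ell <- ellipseRing(100, 100, 40, 20)
  f2 <- extractFeatures(img, ell, mpp = 1)
  expect_lt(abs(f2$eccentricity - sqrt(1 - 1 / 4)), 0.02 * sqrt(1 - 1 / 4))
})

test_that("degenerate polygons raise an explicit error", {
  img <- renderHE(list(), character(0), 50, 50, noiseSD = 0)
  tiny <- rbind(c(10, 10), c(10.5, 10), c(10.5, 10.3))
  expect_error(extractFeatures(img, tiny, mpp = 1), "degenerate")
})

test_that("tumor and non-neoplastic feature distributions separate as generated", {
  feats <- fixture("feat110")
  m <- fixture("match110")
  areaT <- feats$area_um2[m$trueLabel %in% "Tumor"]
  areaN <- feats$area_um2[m$trueLabel %in% "NonNeoplastic"]
  expect_gt(mean(areaT), mean(areaN))   # generator direction: tumor larger
  # separation of at least 2 pooled SDs (the regime the classifier assumes)
  pooled <- sqrt((var(areaT) + var(areaN)) / 2)
  expect_gt((mean(areaT) - mean(areaN)) / pooled, 2)
})

test_that("the annotation protocol enforces Tumor/NonNeoplastic balance and the cap", {
  expect_error(annotationSet(letters[1:11],
                             rep(c("Tumor", "NonNeoplastic"), c(6, 5))),
               "unbalanced")
  expect_error(annotationSet(sprintf("c%02d", 1:22),
                             rep(c("Tumor", "NonNeoplastic"), each = 11)),
               "budget")
  # Ignore is exempt from the balance rule
  ann <- annotationSet(letters[1:12],
                       rep(c("Tumor", "NonNeoplastic", "Ignore"), c(5, 5, 2)))
  expect_equal(nrow(ann), 12L)
  expect_error(annotationSet("a", "Stroma"), "unknown")
})

test_that("a balanced 5+5 training set on separable data reaches accuracy 1 and is deterministic", {
  feats <- fixture("feat110")
  m <- fixture("match110")
  set.seed(31)
  idx <- unlist(lapply(c("Tumor", "NonNeoplastic", "Ignore"),
                       function(cl) sample(which(m$trueLabel %in% cl), 5)))
  ann <- annotationSet(m$id[idx], m$trueLabel[idx])
  clf <- trainClassifier(feats, ann, seed = 5)
  pred <- classifyDetections(clf, feats)
  # training exemplars get their training labels back
  trainPred <- pred$label[match(ann$id, pred$id)]
  expect_equal(trainPred, ann$label)
  clf2 <- trainClassifier(feats, ann, seed = 5)
  pred2 <- classifyDetections(clf2, feats)
  expect_identical(pred, pred2)
})

test_that("probabilities are normalized and prediction is order-invariant", {
  feats <- fixture("feat110")
  m <- fixture("match110")
  set.seed(13)
  idx <- unlist(lapply(c("Tumor", "NonNeoplastic", "Ignore"),
                       function(cl) sample(which(m$trueLabel %in% cl), 5)))
  clf <- trainClassifier(feats, annotationSet(m$id[idx], m$trueLabel[idx]),
                         seed = 2)
  pred <- classifyDetections(clf, feats)
  probs <- as.matrix(pred[, grep("^prob\\.", names(pred))])
  expect_true(all(probs >= 0))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  perm <- sample(nrow(feats))
  predPerm <- classifyDetections(clf, feats[perm, , drop = FALSE])
  expect_equal(predPerm[order(perm), ], pred, ignore_attr = TRUE)
  # empty input is a valid empty result
  expect_equal(nrow(classifyDetections(clf, feats[0, , drop = FALSE])), 0L)
  # feature mismatch errors
  expect_error(classifyDetections(clf, feats[, 1:3]), "feature columns")
})

test_that("few-shot classification reaches 90 percent accuracy on a 110-object scene", {
  feats <- fixture("feat110")
  m <- fixture("match110")
  set.seed(42)
  idx <- unlist(lapply(c("Tumor", "NonNeoplastic", "Ignore"),
                       function(cl) sample(which(m$trueLabel %in% cl), 5)))
  clf <- trainClassifier(feats, annotationSet(m$id[idx], m$trueLabel[idx]),
                         seed = 7)
  pred <- classifyDetections(clf, feats)
  keep <- !is.na(m$trueLabel)
  acc <- mean(pred$label[keep] == m$trueLabel[keep])
  expect_gte(acc, 0.9)
})

test_that("the learning curve does not degrade from 5 to 10 annotations and is reproducible", {
  feats <- fixture("feat110")
  m <- fixture("match110")
  keep <- !is.na(m$trueLabel)
  lc <- learningCurve(feats[keep, ], m$trueLabel[keep], counts = c(5, 10),
                      reps = 2, seed = 3)
  expect_equal(lc$nPerClass, c(5L, 10L))
  expect_gte(lc$meanAccuracy[2], lc$meanAccuracy[1] - 0.02)
  lc2 <- learningCurve(feats[keep, ], m$trueLabel[keep], counts = c(5, 10),
                       reps = 2, seed = 3)
  expect_identical(lc, lc2)
  expect_error(
    learningCurve(feats[keep, ], m$trueLabel[keep], counts = 1000, reps = 1),
    "exceeds available")
})
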