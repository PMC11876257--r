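# Morphometric/intensity feature extraction and few-shot nucleus
# classification with a randomized decision-tree ensemble, following the
# balanced-annotation protocol: equal numbers of Tumor and Non-neoplastic
# exemplars, capped at a small per-class budget.

.FEATURE_NAMES <- c("area_um2", "perimeter_um", "circularity", "eccentricity",
                    "solidity", "mean_od_h", "sd_od_h", "mean_od_e")

#' Extract per-nucleus morphometric and intensity features
#'
#' Geometric features come from the polygon outline (area, perimeter,
#' circularity `4*pi*A/P^2`, eccentricity of the equivalent-covariance
#' ellipse, solidity against the convex hull); intensity features are the
#' mean and SD of the hematoxylin OD and the mean eosin OD over the polygon
#' interior pixels.
#'
#' @param img RGB array the detections were made on.
#' @param det a [DetectionSet-class], or a single polygon matrix.
#' @param mpp microns per pixel (taken from `det` when it is a
#'   DetectionSet).
#' @return data.frame with one row per detection: `id` plus the eight
#'   feature columns.
#' @export
extractFeatures <- function(img, det, mpp = 0.4416) {
  if (is.matrix(det)) {
    polys <- list(det)
    ids <- "polygon-1"
  } else {
    stopifnot(is(det, "DetectionSet"))
    polys <- det@polygons
    ids <- det@data$id
    mpp <- det@mpp
  }
  od <- deconvolveStains(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rows <- lapply(seq_along(polys), function(i) {
    .featureRow(polys[[i]], od, w, h, mpp)
  })
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

.featureRow <- function(poly, od, width, height, mpp) {
  areaPx <- .polygonArea(poly)
  if (areaPx < 1) stop("degenerate polygon: area below one pixel")
  perim <- .polygonPerimeter(poly)
  pix <- .rasterizePolygon(poly, width = width, height = height)
  if (nrow(pix) == 0L) stop("degenerate polygon: no interior pixels")
  vh <- od$odH[pix]; ve <- od$odE[pix]
  data.frame(
    area_um2 = areaPx * mpp^2,
    perimeter_um = perim * mpp,
    circularity = min(4 * pi * areaPx / perim^2, 1.2),
    eccentricity = .polygonEccentricity(poly),
    solidity = .polygonSolidity(poly),
    mean_od_h = mean(vh),
    sd_od_h = if (length(vh) > 1L) stats::sd(vh) else 0,
    mean_od_e = mean(ve))
}

#' Build a balanced annotation set
#'
#' Enforces the few-shot training protocol: Tumor and Non-neoplastic
#' annotation counts must be equal and no class may exceed the per-class
#' cap (default 10; performance plateaus there). The Ignore class is exempt
#' from the balance requirement and may have 0 to `maxPerClass` exemplars.
#'
#' @param ids detection ids of the annotated nuclei.
#' @param labels their labels, in `c("Tumor", "NonNeoplastic", "Ignore")`.
#' @param maxPerClass annotation cap per class.
#' @return data.frame with columns `id`, `label`.
#' @export
annotationSet <- function(ids, labels, maxPerClass = 10L) {
  if (length(ids) != length(labels)) stop("ids and labels must be parallel")
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad)) stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = .CLASS_LEVELS))
  if (tab[["Tumor"]] != tab[["NonNeoplastic"]])
    stop("unbalanced annotations: ", tab[["Tumor"]], " Tumor vs ",
         tab[["NonNeoplastic"]], " NonNeoplastic (the protocol mandates a ",
         "balanced ratio)")
  if (any(tab > maxPerClass))
    stop("annotation budget exceeded: at most ", maxPerClass, " per class")
  data.frame(id = as.character(ids), label = as.character(labels),
             stringsAsFactors = FALSE)
}

#' Train the few-shot nucleus classifier
#'
#' Fits a randomized decision-tree ensemble (random forest) on the eight
#' features of the annotated detections. Deterministic given the seed.
#'
#' @param features feature data.frame from [extractFeatures()] covering at
#'   least the annotated ids.
#' @param annotations a balanced annotation data.frame from
#'   [annotationSet()] (passing `ids`/`labels` through it enforces the
#'   balance protocol).
#' @param seed integer training seed.
#' @param ntree number of trees (default 200).
#' @return a [NucleusClassifier-class].
#' @export
trainClassifier <- function(features, annotations, seed = 1L, ntree = 200L) {
  annotations <- annotationSet(annotations$id, annotations$label)
  idx <- match(annotations$id, features$id)
  if (anyNA(idx)) stop("annotated ids missing from the feature table: ",
                       paste(annotations$id[is.na(idx)], collapse = ", "))
  classes <- intersect(.CLASS_LEVELS, unique(annotations$label))
  if (length(classes) < 2L) stop("need annotations from at least two classes")
  x <- features[idx, .FEATURE_NAMES, drop = FALSE]
  if (any(!is.finite(as.matrix(x)))) stop("non-finite feature values")
  y <- factor(annotations$label, levels = classes)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, y = y, ntree = as.integer(ntree))
  new("NucleusClassifier", model = fit, classes = classes,
      featureNames = .FEATURE_NAMES,
      trainingCounts = stats::setNames(as.integer(table(y)), classes),
      seed = as.integer(seed))
}

#' Classify detections
#'
#' Assigns each detection a class label and a class-probability vector
#' (normalized to sum to one). Ties in probability are broken by the fixed
#' class order Tumor, NonNeoplastic, Ignore. Prediction is a per-row
#' operation, hence invariant to detection ordering.
#'
#' @param clf a [NucleusClassifier-class].
#' @param features feature data.frame from [extractFeatures()].
#' @return data.frame with `id`, `label` and one `prob.<class>` column per
#'   trained class; empty input yields an empty frame.
#' @export
classifyDetections <- function(clf, features) {
  stopifnot(is(clf, "NucleusClassifier"))
  if (!all(clf@featureNames %in% names(features)))
    stop("feature columns do not match training: need ",
         paste(clf@featureNames, collapse = ", "))
  probCols <- paste0("prob.", clf@classes)
  if (nrow(features) == 0L) {
    out <- data.frame(id = character(0), label = character(0),
                      stringsAsFactors = FALSE)
    for (pc in probCols) out[[pc]] <- numeric(0)
    return(out)
  }
  x <- features[, clf@featureNames, drop = FALSE]
  prob <- stats::predict(clf@model, newdata = x, type = "prob")
  prob <- prob[, clf@classes, drop = FALSE]
  prob <- prob / rowSums(prob)
  # argmax with ties broken by the fixed class order
  lab <- clf@classes[apply(prob, 1L, which.max)]
  out <- data.frame(id = features$id, label = lab, stringsAsFactors = FALSE)
  for (j in seq_along(probCols)) out[[probCols[j]]] <- unname(prob[, j])
  rownames(out) <- NULL
  out
}

#' Assign classifier labels into a DetectionSet
#'
#' @param det a [DetectionSet-class].
#' @param labeled output of [classifyDetections()] (matched by id).
#' @return the DetectionSet with a `label` column filled.
#' @export
setDetectionLabels <- function(det, labeled) {
  idx <- match(det@data$id, labeled$id)
  if (anyNA(idx)) stop("labels missing for detection(s): ",
                       paste(det@data$id[is.na(idx)], collapse = ", "))
  det@data$label <- labeled$label[idx]
  det
}

#' Few-shot learning curve
#'
#' Measures classification accuracy against ground truth as a function of
#' the per-class annotation budget, averaged over repeated draws of the
#' annotation set (distinct sub-seeds per repetition).
#'
#' @param features feature data.frame of all cells in the scene.
#' @param truth character vector of true labels parallel to `features`
#'   (`Tumor`, `NonNeoplastic`, `Ignore`).
#' @param counts ascending integer vector of annotations per class.
#' @param reps repetitions per budget.
#' @param seed master seed.
#' @return data.frame with `nPerClass` and `meanAccuracy` (accuracy on the
#'   cells not used for training).
#' @export
learningCurve <- function(features, truth, counts, reps = 3L, seed = 1L) {
  if (is.unsorted(counts)) stop("counts must be ascending")
  truth <- as.character(truth)
  avail <- table(factor(truth, levels = .CLASS_LEVELS))
  present <- names(avail)[avail > 0L]
  if (any(max(counts) > avail[present]))
    stop("requested count ", max(counts), " exceeds available cells of class ",
         paste(present[avail[present] < max(counts)], collapse = ", "))
  out <- data.frame(nPerClass = integer(0), meanAccuracy = numeric(0))
  for (n in counts) {
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
      subSeed <- as.integer(seed) + 1000L * match(n, counts) + r
      set.seed(subSeed)
      trainIdx <- unlist(lapply(present, function(cl) {
        sample(which(truth == cl), n)
      }))
      ann <- annotationSet(features$id[trainIdx], truth[trainIdx],
                           maxPerClass = max(n, 10L))
      clf <- trainClassifier(features, ann, seed = subSeed)
      test <- setdiff(seq_along(truth), trainIdx)
      pred <- classifyDetections(clf, features[test, , drop = FALSE])
      acc[r] <- mean(pred$label == truth[test])
    }
    out <- rbind(out, data.frame(nPerClass = n, meanAccuracy = mean(acc)))
  }
  out
}
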