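# Shared fixtures, built lazily and cached for the session: scene generation
# and feature extraction are the expensive steps, and several test files
# reuse the same scenes.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixtureCache[[name]])) return(.fixtureCache[[name]])
  val <- switch(name,
    # 50 well-separated nuclei, no artifacts: detection benchmark
    scene50 = generateScene(sceneSpec(widthPx = 512, heightPx = 512,
                                      nTumor = 15, nNonneo = 35, nArtifact = 0,
                                      seed = 11)),
    # 100 nuclei + 10 artifacts at true tumor fraction 0.30: the
    # classification / end-to-end benchmark
    scene110 = generateScene(sceneSpec(nTumor = 30, nNonneo = 70,
                                       nArtifact = 10, seed = 2)),
    det110 = detectNuclei(sceneImage(fixture("scene110")),
                          sceneROI(fixture("scene110"))),
    feat110 = extractFeatures(sceneImage(fixture("scene110")),
                              fixture("det110")),
    match110 = matchDetections(fixture("det110"), fixture("scene110")),
    stop("unknown fixture: ", name))
  .fixtureCache[[name]] <- val
  val
}

# regular n-gon approximation of an ellipse, for analytic feature checks
ellipseRing <- function(cx, cy, a, b, n = 64L, theta = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

# independent brute-force quadratic weighted kappa: direct summation over
# observed pairs and over the n^2 marginal pairs (no matrix formulation)
bruteForceKappa <- function(a, b, k) {
  w <- function(i, j) (i - j)^2 / (k - 1)^2
  qO <- mean(mapply(w, a, b))
  qE <- mean(outer(a, b, w))
  1 - qO / qE
}
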