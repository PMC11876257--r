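test_that("binning handles edges, the documented example and out-of-range input", {
  expect_equal(binTCF(c(0, 100), binWidth = 10), c(0L, 9L))   # top edge merged
  expect_equal(binTCF(c(4, 5, 6), binWidth = 5), c(0L, 1L, 1L))
  expect_equal(binTCF(c(0, 9.99, 10), binWidth = 10), c(0L, 0L, 1L))
  expect_equal(binTCF(37), 37L)                               # default width 1
  expect_error(binTCF(c(5, 101)), "\\[0, 100\\]")
  expect_error(binTCF(c(5, NA)), "non-finite")
  # binning is monotone
  v <- sort(runif(50, 0, 100))
  expect_true(all(diff(binTCF(v, binWidth = 7)) >= 0))
})

.kappaOracleDefined <- function(a, b, k) {
  kap <- bruteForceKappa(a, b, k)
  list(defined = is.finite(kap), kappa = kap)
}

test_that("kappa equals 1 on identical ratings and matches the brute-force oracle", {
  a <- c(0L, 1L, 2L, 3L, 2L, 1L, 0L, 3L)
  expect_equal(kappaValue(weightedKappa(a, a, nPerm = 50)), 1)
  set.seed(101)
  for (r in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(10:40, 1)
    a <- sample(0:(k - 1L), n, replace = TRUE)
    b <- sample(0:(k - 1L), n, replace = TRUE)
    m <- .kappaOracleDefined(a, b, k)
    res <- weightedKappa(a, b, k = k, nPerm = 10)
    if (m$defined) {
      expect_equal(kappaValue(res), m$kappa, tolerance = 1e-12)
    } else {
      expect_true(is.na(kappaValue(res)))
    }
  }
})

test_that("kappa is symmetric in its arguments", {
  set.seed(4)
  a <- sample(0:4, 30, replace = TRUE)
  b <- sample(0:4, 30, replace = TRUE)
  expect_equal(kappaValue(weightedKappa(a, b, k = 5, nPerm = 10)),
               kappaValue(weightedKappa(b, a, k = 5, nPerm = 10)))
})

test_that("with k = 2 the quadratic weighted kappa reduces to Cohen's kappa", {
  set.seed(9)
  a <- rbinom(60, 1, 0.4)
  b <- ifelse(runif(60) < 0.7, a, 1L - a)
  O <- table(factor(a, 0:1), factor(b, 0:1)) / 60
  po <- sum(diag(O))
  pe <- sum(rowSums(O) * colSums(O))
  cohen <- (po - pe) / (1 - pe)
  expect_equal(kappaValue(weightedKappa(a, b, k = 2, nPerm = 10)), cohen)
})

test_that("kappa at chance level is near zero for independent raters", {
  set.seed(12)
  n <- 10000
  a <- sample(0:9, n, replace = TRUE)
  b <- sample(0:9, n, replace = TRUE)
  res <- weightedKappa(a, b, k = 10, nPerm = 200)
  expect_lt(abs(kappaValue(res)), 0.05)
  expect_gt(kappaPValue(res), 0.05)   # no spurious significance
})

test_that("permutation p-value is reproducible and both nulls agree on strong signal", {
  set.seed(21)
  truth <- sample(0:9, 200, replace = TRUE)
  noisy <- pmin(9L, pmax(0L, truth + sample(-1:1, 200, replace = TRUE)))
  r1 <- weightedKappa(truth, noisy, k = 10, nPerm = 500, seed = 42)
  r2 <- weightedKappa(truth, noisy, k = 10, nPerm = 500, seed = 42)
  expect_identical(kappaPValue(r1), kappaPValue(r2))
  expect_gt(kappaValue(r1), 0.5)
  expect_lt(r1@pPermutation, 0.01)
  expect_lt(r1@pAsymptotic, 0.01)
  # permutation p has the +1 floor: never exactly zero
  expect_gte(r1@pPermutation, 1 / 501)
})

test_that("permutation and asymptotic p-values agree near the boundary", {
  set.seed(33)
  n <- 400
  a <- sample(0:4, n, replace = TRUE)
  # weak dependence: mostly independent with a small coupled fraction
  b <- ifelse(runif(n) < 0.12, a, sample(0:4, n, replace = TRUE))
  r <- weightedKappa(a, b, k = 5, nPerm = 4000, seed = 5)
  expect_lt(abs(r@pPermutation - r@pAsymptotic), 0.03)
})

test_that("a constant rater makes kappa undefined, returned as NA with a reason", {
  r <- weightedKappa(rep(2L, 20), rep(2L, 20), k = 5)
  expect_true(is.na(kappaValue(r)))
  expect_true(is.na(kappaPValue(r)))
  expect_match(r@method$undefined, "constant")
  # mismatched lengths and bad indices error
  expect_error(weightedKappa(0:3, 0:4), "equal length")
  expect_error(weightedKappa(c(0, 1), c(0, 5), k = 3), "outside")
  expect_error(weightedKappa(c(-1, 1), c(0, 1)), "0-based")
})

test_that("two-group tests: identical samples, a hand-computed chi-square, shifted ranks", {
  x <- c(10, 20, 30, 40, 50)
  tt <- compareGroups(x, x, test = "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  # Pearson chi-square without continuity correction, computed by hand
  tab <- rbind(c(17, 104), c(8, 113))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  cg <- compareGroups(c(17, 104), c(8, 113), test = "chi2")
  expect_equal(cg$statistic, stat)
  expect_equal(cg$p_value, stats::pchisq(stat, 1, lower.tail = FALSE))
  # matrix input gives the same answer
  expect_equal(compareGroups(tab, test = "chi2"), cg)
  # disjoint ranges are detected by the rank test
  set.seed(2)
  lo <- runif(20, 0, 10); hi <- runif(20, 20, 30)
  mw <- compareGroups(lo, hi, test = "mann_whitney")
  expect_lt(mw$p_value, 0.01)
  expect_error(compareGroups(numeric(0), x, test = "t"), "empty")
  expect_error(compareGroups(rbind(c(-1, 2), c(3, 4)), test = "chi2"),
               "negative")
})

test_that("the agreement matrix covers all pairs and truth columns", {
  set.seed(6)
  truth <- runif(60, 5, 95)
  ratings <- data.frame(
    case_id = sprintf("c%02d", 1:60),
    obsA = pmin(100, pmax(0, truth + rnorm(60, 0, 8))),
    obsB = pmin(100, pmax(0, truth + rnorm(60, 5, 8))))
  am <- agreementMatrix(ratings, truth = truth, binWidth = 10,
                        nPerm = 300, seed = 3)
  expect_setequal(paste(am$rater_a, am$rater_b),
                  c("obsA obsB", "obsA truth", "obsB truth"))
  # raters tracking the same truth agree beyond chance
  expect_true(all(am$kappa > 0.3))
  expect_true(all(am$p_value < 0.05))
  am2 <- agreementMatrix(ratings, truth = truth, binWidth = 10,
                         nPerm = 300, seed = 3)
  expect_identical(am, am2)
})
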