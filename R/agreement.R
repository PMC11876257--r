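# Ordinal agreement on TCF scores: binning to an ordinal scale, the
# quadratic weighted kappa with permutation and large-sample p-values, and
# the standard two-group comparison tests.

#' Bin TCF percentages to an ordinal scale
#'
#' `index = floor(value / binWidth)` with the top edge (value = 100) merged
#' into the last bin. `binWidth = 1` (the default) keeps the raw
#' integer-percent ordinal scale.
#'
#' @param values numeric TCF values in `[0, 100]`.
#' @param binWidth bin width in percent points.
#' @return integer 0-based ordinal indices.
#' @examples
#' binTCF(c(4, 5, 6), binWidth = 5)   # 0 1 1
#' @export
binTCF <- function(values, binWidth = 1) {
  if (any(!is.finite(values))) stop("non-finite TCF values")
  if (any(values < 0 | values > 100)) stop("TCF values must be in [0, 100]")
  k <- ceiling(100 / binWidth)
  as.integer(pmin(floor(values / binWidth), k - 1L))
}

# observed joint proportion matrix, expected (independence) matrix and
# disagreement weights for two 0-based rating vectors
.kappaMatrices <- function(a, b, k, weights) {
  fa <- factor(a, levels = 0:(k - 1L))
  fb <- factor(b, levels = 0:(k - 1L))
  O <- table(fa, fb) / length(a)
  E <- outer(rowSums(O), colSums(O))
  i <- matrix(0:(k - 1L), k, k)
  j <- t(i)
  w <- switch(weights,
              quadratic = (i - j)^2 / (k - 1L)^2,
              linear = abs(i - j) / (k - 1L),
              stop("unknown weight scheme: ", weights))
  list(O = unclass(O), E = E, w = w)
}

#' Quadratic weighted kappa for two raters
#'
#' Chance-corrected ordinal agreement: with disagreement weights
#' `w_ij = (i - j)^2 / (k - 1)^2`, `kappa = 1 - sum(w * O) / sum(w * E)`
#' where `O` is the observed joint proportion matrix and `E` the outer
#' product of the marginals. The p-value tests the null of no agreement
#' beyond chance, by permutation of one rating vector (default) with the
#' large-sample normal approximation reported alongside. When a rater is
#' constant the expected disagreement is zero and kappa is undefined
#' (returned as `NA` with an explanation in the method metadata).
#'
#' @param a,b integer 0-based ordinal ratings of the same cases (e.g. from
#'   [binTCF()]).
#' @param k number of ordinal categories (default: largest index + 1).
#' @param weights `"quadratic"` (default) or `"linear"` disagreement
#'   weights.
#' @param null `"permutation"` (default) or `"asymptotic"`: which p-value
#'   fills the `pValue` slot; both are always computed.
#' @param nPerm number of permutations.
#' @param seed permutation seed.
#' @return an [AgreementResult-class].
#' @examples
#' r <- weightedKappa(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 2, 2, 0))
#' kappaValue(r)
#' @export
weightedKappa <- function(a, b, k = NULL, weights = "quadratic",
                          null = c("permutation", "asymptotic"),
                          nPerm = 10000L, seed = 1L) {
  null <- match.arg(null)
  if (length(a) != length(b)) stop("rating vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least two rated cases")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite ratings")
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 0L) || any(b < 0L)) stop("ratings must be 0-based indices")
  if (is.null(k)) k <- max(a, b) + 1L
  k <- as.integer(k)
  if (k < 2L) stop("need at least two categories")
  if (max(a, b) >= k) stop("rating index outside [0, k)")
  m <- .kappaMatrices(a, b, k, weights)
  qE <- sum(m$w * m$E)
  meta <- list(weights = weights, null = null, nPerm = as.integer(nPerm),
               seed = as.integer(seed), binning = "0-based ordinal indices")
  if (qE <= .Machine$double.eps) {
    meta$undefined <- "expected disagreement is zero (a rater is constant)"
    return(new("AgreementResult", kappa = NA_real_, pValue = NA_real_,
               pPermutation = NA_real_, pAsymptotic = NA_real_,
               n = n, k = k, method = meta))
  }
  qO <- sum(m$w * m$O)
  kap <- 1 - qO / qE
  # permutation null: shuffle b, one-sided (agreement beyond chance)
  # marginals (hence E and qE) are invariant under permutation of b, so only
  # the observed weighted disagreement needs recomputing per shuffle
  set.seed(as.integer(seed))
  exceed <- 0L
  for (p in seq_len(nPerm)) {
    bp <- sample.int(n)
    qOp <- sum(m$w[cbind(a + 1L, b[bp] + 1L)]) / n
    if (1 - qOp / qE >= kap - 1e-12) exceed <- exceed + 1L
  }
  pPerm <- (exceed + 1L) / (nPerm + 1L)
  # large-sample normal approximation under H0 (agreement-weight form)
  wAgree <- 1 - m$w
  pr <- rowSums(m$O); pc <- colSums(m$O)
  pe <- sum(wAgree * m$E)
  wbarRow <- as.vector(wAgree %*% pc)       # E_j[w_ij]
  wbarCol <- as.vector(pr %*% wAgree)       # E_i[w_ij]
  wsum <- outer(wbarRow, rep(1, k)) + outer(rep(1, k), wbarCol)
  var0 <- (sum(m$E * (wAgree - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  pAsym <- if (var0 > 0) stats::pnorm(kap / sqrt(var0), lower.tail = FALSE) else
    as.numeric(kap <= 0)
  new("AgreementResult", kappa = kap,
      pValue = if (null == "permutation") pPerm else pAsym,
      pPermutation = pPerm, pAsymptotic = pAsym,
      n = n, k = k, method = meta)
}

#' AgreementResult accessors
#' @param x an [AgreementResult-class].
#' @return `kappaValue`: the weighted kappa; `kappaPValue`: the p-value of
#'   the selected null procedure.
#' @name agreement-accessors
NULL

#' @rdname agreement-accessors
#' @export
kappaValue <- function(x) x@kappa

#' @rdname agreement-accessors
#' @export
kappaPValue <- function(x) x@pValue

#' Two-group comparison tests
#'
#' Standard two-sided tests used to compare TCF score sets: Welch t-test or
#' Mann-Whitney U for continuous samples, and the Pearson chi-square
#' (without continuity correction) for a 2 x 2 adequacy contingency, given
#' either as two count vectors (rows of the table) or as a matrix in `a`.
#'
#' @param a,b numeric sample vectors; for `test = "chi2"`, count vectors
#'   `c(n_below, n_atOrAbove)` per group (or `a` a 2 x 2 matrix, `b`
#'   omitted).
#' @param test `"t"`, `"mann_whitney"` or `"chi2"`.
#' @return list with `statistic` and `p_value`.
#' @examples
#' compareGroups(c(17, 104), c(8, 113), test = "chi2")
#' @export
compareGroups <- function(a, b = NULL, test = c("t", "mann_whitney", "chi2")) {
  test <- match.arg(test)
  if (test == "chi2") {
    tab <- if (is.matrix(a)) a else {
      if (is.null(b)) stop("chi2 needs two count vectors or a matrix")
      rbind(a, b)
    }
    if (any(tab < 0)) stop("negative counts")
    if (any(dim(tab) < 2L)) stop("contingency table must be at least 2 x 2")
    ht <- stats::chisq.test(tab, correct = FALSE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (!length(a) || !length(b)) stop("empty sample(s)")
  ht <- switch(test,
               t = stats::t.test(a, b),
               mann_whitney = stats::wilcox.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pairwise agreement matrix for a rating table
#'
#' Computes the weighted kappa for every observer pair (and each observer
#' against the ground truth when given), after binning -- the shape of a
#' published inter-observer agreement table.
#'
#' @param ratings data.frame with `case_id` and one rating column per
#'   observer (percent scale).
#' @param truth optional named/parallel numeric vector of true TCF percent
#'   values.
#' @param binWidth bin width passed to [binTCF()].
#' @param nPerm,seed permutation settings per pair.
#' @return data.frame with `rater_a`, `rater_b`, `kappa`, `p_value`.
#' @export
agreementMatrix <- function(ratings, truth = NULL, binWidth = 1,
                            nPerm = 2000L, seed = 1L) {
  obsCols <- setdiff(names(ratings), "case_id")
  k <- ceiling(100 / binWidth)
  binned <- lapply(ratings[obsCols], binTCF, binWidth = binWidth)
  if (!is.null(truth)) binned$truth <- binTCF(truth, binWidth = binWidth)
  nm <- names(binned)
  out <- data.frame(rater_a = character(0), rater_b = character(0),
                    kappa = numeric(0), p_value = numeric(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    if (nm[i] == "truth") next
    r <- weightedKappa(binned[[i]], binned[[j]], k = k,
                       nPerm = nPerm, seed = seed)
    out <- rbind(out, data.frame(rater_a = nm[i], rater_b = nm[j],
                                 kappa = r@kappa, p_value = r@pValue,
                                 stringsAsFactors = FALSE))
  }
  out
}
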