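test_that("purity correction matches hand-computed values and domain errors", {
  # diploid fixed point and pure-tumor identity
  for (f in c(0.1, 0.3, 0.5, 0.9, 1)) expect_equal(correctCopyNumber(2, f), 2)
  expect_equal(correctCopyNumber(5.3, 1), 5.3)
  # hand substitution into x = (C - 2(1-f))/f
  expect_equal(correctCopyNumber(3, 0.5), 4)
  expect_equal(correctCopyNumber(6, 0.8), 7)
  expect_error(correctCopyNumber(3, 0), "cellularity")
  expect_error(correctCopyNumber(3, 1.2), "cellularity")
  expect_error(correctCopyNumber(-1, 0.5), "copy number")
})

test_that("the mixture model round-trips to 1e-12 and is monotone in f", {
  set.seed(2)
  C <- runif(1e4, 0, 10)
  f <- runif(1e4, 0.01, 1)
  x <- correctCopyNumber(C, f)
  expect_lt(max(abs(f * x + (1 - f) * 2 - C)), 1e-12)
  # monotonicity on a grid: decreasing in f for C > 2, increasing for C < 2
  fg <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(correctCopyNumber(rep(4, length(fg)), fg)) < 0))
  expect_true(all(diff(correctCopyNumber(rep(1, length(fg)), fg)) > 0))
  expect_true(all(abs(diff(correctCopyNumber(rep(2, length(fg)), fg))) < 1e-12))
})

# a record whose six criteria can be switched on/off independently
.critRecord <- function(pattern) {
  data.frame(case_id = "c1", gene = "EGFR",
             C = NA_real_,                           # set from x below
             f = if (pattern[1]) 0.6 else 0.4,
             read_count = if (pattern[2]) 20000L else 5000L,
             mapd = if (pattern[3]) 0.3 else 0.8,
             cn_conf_5 = if (pattern[4]) 4.5 else 2.0,
             p_value = if (pattern[6]) 1e-6 else 0.5,
             stringsAsFactors = FALSE) -> rec
  x <- if (pattern[5]) 6 else 3
  rec$C <- rec$f * x + 2 * (1 - rec$f)
  rec
}

test_that("confidence gating: exhaustive enumeration of all 64 criterion patterns", {
  for (code in 0:63) {
    pattern <- as.logical(bitwAnd(code, 2^(0:5)))
    rec <- evaluateConfidence(.critRecord(pattern))
    expect_equal(unname(unlist(rec[quantTCF:::.CNV_CRITERIA])), pattern)
    expect_equal(rec$n_met, sum(pattern))
    expect_equal(rec$confident, sum(pattern) >= 5)
  }
})

test_that("gating is monotone: meeting one more criterion never revokes confidence", {
  for (code in 0:63) {
    pattern <- as.logical(bitwAnd(code, 2^(0:5)))
    base <- evaluateConfidence(.critRecord(pattern))$confident
    for (i in which(!pattern)) {
      up <- pattern; up[i] <- TRUE
      expect_gte(evaluateConfidence(.critRecord(up))$confident, base)
    }
  }
})

test_that("gate thresholds are inclusive at their boundaries", {
  rec <- .critRecord(rep(TRUE, 6))
  rec$f <- 0.5; rec$read_count <- 10000L; rec$mapd <- 0.5
  rec$cn_conf_5 <- 4; rec$p_value <- 1e-5
  rec$C <- rec$f * 5 + 2 * (1 - rec$f)     # x exactly 5
  ev <- evaluateConfidence(rec)
  expect_equal(ev$n_met, 6)
  expect_true(ev$confident)
})

test_that("missing QC fields count as unmet, not as errors", {
  rec <- .critRecord(rep(TRUE, 6))
  rec$mapd <- NA_real_
  ev <- evaluateConfidence(rec)
  expect_false(ev$crit_mapd)
  expect_equal(ev$n_met, 5)
  expect_true(ev$confident)
})

test_that("re-calling with revised cellularity is pure and flips the level criterion", {
  rec <- data.frame(case_id = "k", gene = "MET", C = 3.5, f = 0.9,
                    read_count = 20000L, mapd = 0.3, cn_conf_5 = 4.5,
                    p_value = 1e-6, stringsAsFactors = FALSE)
  before <- evaluateConfidence(rec)
  expect_equal(before$x, (3.5 - 0.2) / 0.9)
  expect_false(before$crit_level)
  after <- recallWithTCF(rec, c(k = 0.3))
  expect_equal(after$x, 7)
  expect_true(after$crit_level)
  expect_equal(rec$f, 0.9)                     # input untouched
  # idempotence when f is unchanged
  same <- recallWithTCF(rec, c(k = 0.9))
  expect_equal(same, before)
  # diploid stays diploid whatever the revision
  dip <- data.frame(case_id = "d", gene = "EGFR", C = 2, f = 0.4,
                    read_count = 1L, mapd = 1, cn_conf_5 = 0, p_value = 1)
  expect_equal(recallWithTCF(dip, c(d = 0.9))$x, 2)
  expect_error(recallWithTCF(rec, c(other = 0.5)), "no revised cellularity")
})

test_that("negative corrected copy numbers are flagged implausible, not clamped", {
  rec <- data.frame(case_id = "n", gene = "CDK4", C = 0.5, f = 0.2,
                    read_count = 20000L, mapd = 0.3, cn_conf_5 = 1,
                    p_value = 0.5, stringsAsFactors = FALSE)
  ev <- evaluateConfidence(rec)
  expect_lt(ev$x, 0)
  expect_true(ev$implausible)
})

test_that("call-set comparison reproduces the printed percentages from the printed counts", {
  co <- syntheticCNVCohort()
  cmp <- compareCallSets(co$before, co$after)
  expect_equal(cmp$softwareBefore, 29L)
  expect_equal(cmp$softwareAfter, 27L)
  expect_equal(cmp$softwarePctChange, -6.9)
  expect_equal(cmp$confidentBefore, 7L)
  expect_equal(cmp$confidentAfter, 13L)
  expect_equal(cmp$confidentPctChange, 85.7)
  expect_equal(cmp$discrepantN, 7L)
  expect_equal(cmp$discrepancyPct, 24)
})

test_that("comparison counts are conserved and empty call sets stay defined", {
  co <- syntheticCNVCohort()
  cmp <- compareCallSets(co$before, co$after)
  unchanged <- sum(cmp$before$confident & cmp$after$confident)
  expect_equal(nrow(cmp$gained) + unchanged, cmp$confidentAfter)
  expect_equal(nrow(cmp$lost) + unchanged, cmp$confidentBefore)
  # before-count zero: percent changes undefined, no division error
  empty <- co$before[co$before$C < 2.1 & co$before$gene == "BRAF", ]
  cmp0 <- compareCallSets(empty, empty)
  expect_true(is.na(cmp0$softwarePctChange))
  expect_true(is.na(cmp0$discrepancyPct))
  expect_error(compareCallSets(co$before[1:3, ], co$after[4:6, ]),
               "one-to-one")
})

test_that("CNV tables round-trip through CSV", {
  tab <- generateCNVTable(10, "computational", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCNVTable(tab, path)
  back <- readCNVTable(path)
  expect_equal(back, tab, tolerance = 1e-12)
})
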