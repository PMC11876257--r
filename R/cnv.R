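# Tumor-purity correction of observed copy numbers and the six-criterion
# confidence gate. The observed copy number C of a mixed sample is modeled
# as f*x + (1-f)*2 = C: a fraction f of tumor cells with x copies diluted by
# normal diploid cells, hence x = (C - 2*(1-f)) / f.

.CNV_CRITERIA <- c("crit_cellularity", "crit_reads", "crit_mapd",
                   "crit_conf5", "crit_level", "crit_pvalue")

#' Default thresholds of the six CNV confidence criteria
#'
#' All thresholds are inclusive: cellularity `f >= 0.50`, read count
#' `>= 10000`, MAPD `<= 0.5`, lower 5 percent confidence bound `>= 4`
#' copies, corrected copy number `>= 5` copies, and call p-value
#' `<= 1e-5`.
#'
#' @return named list of thresholds.
#' @export
cnvCriteria <- function() {
  list(minCellularity = 0.50, minReads = 10000, maxMapd = 0.5,
       minConf5 = 4, minLevel = 5, maxPValue = 1e-5)
}

#' Purity-correct an observed copy number
#'
#' Inverts the two-population mixture `f*x + (1-f)*2 = C`:
#' `x = (C - 2*(1-f)) / f`. The diploid value is a fixed point (`C = 2`
#' gives `x = 2` for any cellularity) and at `f = 1` the observed value is
#' returned unchanged. Negative corrected values (possible when
#' `C < 2*(1-f)`) are returned as-is so callers can flag them as
#' implausible rather than silently clamping.
#'
#' @param C observed copy number in the mixed sample (`>= 0`); vectorized.
#' @param f tumor cellularity as a fraction in `(0, 1]`; vectorized.
#' @return corrected (tumor-intrinsic) copy number `x`.
#' @examples
#' correctCopyNumber(C = 3, f = 0.5)   # 4
#' correctCopyNumber(C = 6, f = 0.8)   # 7
#' @export
correctCopyNumber <- function(C, f) {
  if (any(!is.finite(f)) || any(f <= 0 | f > 1))
    stop("cellularity f must be in (0, 1]")
  if (any(!is.finite(C)) || any(C < 0))
    stop("observed copy number C must be finite and >= 0")
  (C - 2 * (1 - f)) / f
}

#' Evaluate the CNV confidence criteria
#'
#' Computes the corrected copy number `x` for each record and evaluates the
#' six criteria of [cnvCriteria()] (a missing QC field counts as unmet). A
#' record is `confident` when at least `minCriteria` of the six are met.
#' Negative corrected copy numbers are flagged `implausible`.
#'
#' @param records data.frame with columns `case_id`, `gene`, `C`, `f`,
#'   `read_count`, `mapd`, `cn_conf_5`, `p_value`.
#' @param minCriteria minimum number of criteria for a confident call
#'   (default 5 of 6).
#' @param thresholds criterion thresholds, see [cnvCriteria()].
#' @return the records with columns `x`, the six `crit_*` logicals,
#'   `n_met`, `confident` and `implausible` appended.
#' @examples
#' tab <- generateCNVTable(5, "pathologist", seed = 1)
#' evaluateConfidence(tab)[, c("gene", "x", "n_met", "confident")]
#' @export
evaluateConfidence <- function(records, minCriteria = 5L,
                               thresholds = cnvCriteria()) {
  need <- c("C", "f", "read_count", "mapd", "cn_conf_5", "p_value")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  rec <- records
  rec$x <- correctCopyNumber(rec$C, rec$f)
  met <- function(v) !is.na(v) & v   # NA (missing field) counts as unmet
  rec$crit_cellularity <- met(rec$f >= thresholds$minCellularity)
  rec$crit_reads <- met(rec$read_count >= thresholds$minReads)
  rec$crit_mapd <- met(rec$mapd <= thresholds$maxMapd)
  rec$crit_conf5 <- met(rec$cn_conf_5 >= thresholds$minConf5)
  rec$crit_level <- met(rec$x >= thresholds$minLevel)
  rec$crit_pvalue <- met(rec$p_value <= thresholds$maxPValue)
  rec$n_met <- rowSums(as.matrix(rec[, .CNV_CRITERIA, drop = FALSE]))
  rec$confident <- rec$n_met >= minCriteria
  rec$implausible <- rec$x < 0
  rec
}

#' Re-call CNVs with revised tumor cellularity
#'
#' Pure transformation: replaces the cellularity of each case with its
#' revised value, recomputes the corrected copy numbers and re-evaluates the
#' confidence criteria (the cellularity criterion uses the revised f). The
#' input records are left untouched.
#'
#' @param records CNV records (as for [evaluateConfidence()]).
#' @param newF revised cellularity: a named numeric vector keyed by
#'   `case_id`, or a data.frame with columns `case_id`, `f`.
#' @param minCriteria,thresholds passed to [evaluateConfidence()].
#' @return re-evaluated records.
#' @export
recallWithTCF <- function(records, newF, minCriteria = 5L,
                          thresholds = cnvCriteria()) {
  if (is.data.frame(newF)) {
    stopifnot(all(c("case_id", "f") %in% names(newF)))
    newF <- stats::setNames(newF$f, newF$case_id)
  }
  miss <- setdiff(records$case_id, names(newF))
  if (length(miss))
    stop("no revised cellularity for case(s): ", paste(unique(miss), collapse = ", "))
  out <- records[, setdiff(names(records),
                           c("x", .CNV_CRITERIA, "n_met", "confident", "implausible")),
                 drop = FALSE]
  out$f <- unname(newF[out$case_id])
  evaluateConfidence(out, minCriteria = minCriteria, thresholds = thresholds)
}

#' Compare CNV call sets before and after cellularity revision
#'
#' Matches records by `case_id` + `gene`, evaluates both sets, and reports:
#' the number of software calls (records whose corrected copy number passes
#' the primary-call threshold, default `x >= 4`) before and after with the
#' relative percent change; the confidence-gated call counts with their
#' percent change; the discrepancy fraction (the share of *before* software
#' calls whose final confident status differs after revision); and the
#' per-gene gained/lost confident calls. Percent changes are rounded to one
#' decimal, the discrepancy percent to the nearest integer. With zero
#' before-calls the percent changes are `NA`, not an error.
#'
#' @param before,after matched CNV record data.frames (e.g. from
#'   [syntheticCNVCohort()] or [recallWithTCF()]).
#' @param callThreshold corrected-copy-number cutoff of the primary software
#'   call predicate (default 4).
#' @param minCriteria,thresholds confidence-gate settings.
#' @return list with `softwareBefore`, `softwareAfter`,
#'   `softwarePctChange`, `confidentBefore`, `confidentAfter`,
#'   `confidentPctChange`, `discrepantN`, `discrepancyPct`, `gained`,
#'   `lost` (data.frames of case/gene), and the evaluated record sets.
#' @export
compareCallSets <- function(before, after, callThreshold = 4,
                            minCriteria = 5L, thresholds = cnvCriteria()) {
  keyB <- paste(before$case_id, before$gene)
  keyA <- paste(after$case_id, after$gene)
  if (!setequal(keyB, keyA) || anyDuplicated(keyB) || anyDuplicated(keyA))
    stop("before/after record sets must match one-to-one on case_id + gene")
  after <- after[match(keyB, keyA), , drop = FALSE]
  evB <- evaluateConfidence(before, minCriteria, thresholds)
  evA <- evaluateConfidence(after, minCriteria, thresholds)
  calledB <- evB$x >= callThreshold
  calledA <- evA$x >= callThreshold
  pct <- function(a, b) if (b == 0L) NA_real_ else round(100 * (a - b) / b, 1)
  nCalledB <- sum(calledB); nCalledA <- sum(calledA)
  nConfB <- sum(evB$confident); nConfA <- sum(evA$confident)
  flipped <- evB$confident != evA$confident
  discrepantN <- sum(flipped & calledB)
  gained <- evA[!evB$confident & evA$confident, c("case_id", "gene"), drop = FALSE]
  lost <- evB[evB$confident & !evA$confident, c("case_id", "gene"), drop = FALSE]
  rownames(gained) <- rownames(lost) <- NULL
  list(softwareBefore = nCalledB, softwareAfter = nCalledA,
       softwarePctChange = pct(nCalledA, nCalledB),
       confidentBefore = nConfB, confidentAfter = nConfA,
       confidentPctChange = pct(nConfA, nConfB),
       discrepantN = discrepantN,
       discrepancyPct = if (nCalledB == 0L) NA_real_
                        else round(100 * discrepantN / nCalledB),
       gained = gained, lost = lost,
       before = evB, after = evA)
}

#' Read / write CNV tables as CSV
#'
#' CSV with header `case_id, gene, C, f, read_count, mapd, cn_conf_5,
#' p_value` (additional columns are preserved).
#'
#' @param path CSV file path.
#' @param records a CNV record data.frame.
#' @return `readCNVTable`: the data.frame; `writeCNVTable`: `path`,
#'   invisibly.
#' @export
readCNVTable <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "gene", "C", "f", "read_count", "mapd", "cn_conf_5", "p_value")
  if (!all(need %in% names(rec)))
    stop("CNV table must have columns: ", paste(need, collapse = ", "))
  rec
}

#' @rdname readCNVTable
#' @export
writeCNVTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
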