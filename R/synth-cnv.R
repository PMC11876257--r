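# Synthetic copy-number tables. generateCNVTable() draws records from
# configurable distributions; pairedCNVTables() emits the pathologist- vs
# computational-cellularity pair sharing every column except f;
# syntheticCNVCohort() is a fixed, hand-constructed synthetic cohort whose
# call-count structure mirrors the published before/after comparison.

.cnvGenePool <- c("EGFR", "KRAS", "MET", "ERBB2", "PIK3CA", "ALK", "BRAF",
                  "FGFR1", "FGFR2", "FGFR3", "CDK4", "CDK6", "CCND1", "MDM2")

#' Default distribution parameters for synthetic CNV tables
#'
#' @return list of tunable generator parameters: `gainProb` (probability a
#'   record carries a copy gain), `gainShape`/`gainScale` (gamma excess over
#'   the diploid 2 copies), `neutralSD`, `readMeanLog`/`readSDLog` (lognormal
#'   read counts), `mapdMean`/`mapdSD`, `conf5Offset` (range subtracted from
#'   C for the 5 percent confidence bound), `pExpMax` (p-values are
#'   `10^-U(0, pExpMax)`), and the cellularity distributions
#'   `fPathMean`/`fPathSD` and `fCompMean`/`fCompSD` (fractions).
#' @export
cnvTableParams <- function() {
  list(gainProb = 0.5, gainShape = 2, gainScale = 0.9, neutralSD = 0.15,
       readMeanLog = log(30000), readSDLog = 0.6,
       mapdMean = 0.35, mapdSD = 0.12,
       conf5Offset = c(0.3, 1.5), pExpMax = 10,
       fPathMean = 0.55, fPathSD = 0.18,
       fCompMean = 0.30, fCompSD = 0.10)
}

#' Generate a synthetic gene-level CNV call table
#'
#' Emits one record per case with observed copy number `C`, cellularity `f`,
#' read count, MAPD, lower 5 percent confidence bound on copies, and call
#' p-value. All columns except `f` are a function of `seed` alone, so two
#' tables generated with the same seed but different `cellularitySource`
#' are identical except for the cellularity column (paired design).
#'
#' @param n number of records.
#' @param cellularitySource `"pathologist"` (visual TCF, higher mean) or
#'   `"computational"` (pipeline cTCF, lower mean).
#' @param seed integer seed.
#' @param params distribution parameters, see [cnvTableParams()].
#' @return data.frame with columns `case_id`, `gene`, `C`, `f`,
#'   `read_count`, `mapd`, `cn_conf_5`, `p_value`.
#' @examples
#' generateCNVTable(3, "pathologist", seed = 1)
#' @export
generateCNVTable <- function(n, cellularitySource = c("pathologist", "computational"),
                             seed = 1L, params = cnvTableParams()) {
  cellularitySource <- match.arg(cellularitySource)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  cols <- c("case_id", "gene", "C", "f", "read_count", "mapd", "cn_conf_5", "p_value")
  if (n == 0L) {
    out <- data.frame(case_id = character(0), gene = character(0),
                      C = numeric(0), f = numeric(0), read_count = integer(0),
                      mapd = numeric(0), cn_conf_5 = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
    return(out[cols])
  }
  set.seed(as.integer(seed))
  gain <- stats::runif(n) < params$gainProb
  C <- ifelse(gain,
              2 + stats::rgamma(n, shape = params$gainShape, scale = params$gainScale),
              pmax(0.5, stats::rnorm(n, 2, params$neutralSD)))
  read_count <- as.integer(round(stats::rlnorm(n, params$readMeanLog, params$readSDLog)))
  mapd <- pmax(0.05, stats::rnorm(n, params$mapdMean, params$mapdSD))
  cn_conf_5 <- pmax(0.2, C - stats::runif(n, params$conf5Offset[1L], params$conf5Offset[2L]))
  p_value <- 10^(-stats::runif(n, 0, params$pExpMax))
  gene <- sample(.cnvGenePool, n, replace = TRUE)
  # cellularity drawn from a source-specific sub-seed so paired tables share
  # everything else
  offset <- if (cellularitySource == "pathologist") 1009L else 2003L
  set.seed(as.integer(seed) + offset)
  fm <- if (cellularitySource == "pathologist") params$fPathMean else params$fCompMean
  fs <- if (cellularitySource == "pathologist") params$fPathSD else params$fCompSD
  f <- round(pmin(0.95, pmax(0.05, stats::rnorm(n, fm, fs))) / 0.05) * 0.05
  data.frame(case_id = sprintf("cnv-%03d", seq_len(n)), gene = gene,
             C = C, f = f, read_count = read_count, mapd = mapd,
             cn_conf_5 = cn_conf_5, p_value = p_value,
             stringsAsFactors = FALSE)[cols]
}

#' Paired CNV tables differing only in cellularity
#'
#' @inheritParams generateCNVTable
#' @return list with elements `pathologist` and `computational`, two
#'   data.frames identical except for the `f` column.
#' @export
pairedCNVTables <- function(n, seed = 1L, params = cnvTableParams()) {
  list(pathologist = generateCNVTable(n, "pathologist", seed, params),
       computational = generateCNVTable(n, "computational", seed, params))
}

#' A fixed synthetic CNV cohort mirroring the published call-count structure
#'
#' A deterministic, hand-constructed stand-in for the study's supplementary
#' per-case CNV table (which is not deposited): 40 gene-level records whose
#' before/after cellularity revision reproduces the published count
#' structure -- 29 software calls before vs 27 after, 7 vs 13
#' confidence-gated calls, and 7 of the 29 original calls changing final
#' status. Useful for exercising [compareCallSets()] end to end.
#'
#' @return list with data.frames `before` (pathologist cellularity) and
#'   `after` (computational cellularity), sharing `case_id`, `gene`, `C` and
#'   QC columns and differing only in `f`.
#' @export
syntheticCNVCohort <- function() {
  rec <- function(n, gene, xB, fB, fA, reads, mapd, conf5, p) {
    C <- fB * xB + 2 * (1 - fB)
    data.frame(gene = gene, C = C, fB = fB, fA = fA, read_count = reads,
               mapd = mapd, cn_conf_5 = conf5, p_value = p,
               stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  }
  blocks <- rbind(
    # stable confident calls: all six criteria before, five after
    rec(6L, "EGFR", xB = 6.0, fB = 0.60, fA = 0.35,
        reads = 50000L, mapd = 0.30, conf5 = 4.2, p = 1e-7),
    # gained confidence after revision: corrected copies cross 5
    rec(6L, "KRAS", xB = 4.5, fB = 0.45, fA = 0.30,
        reads = 30000L, mapd = 0.25, conf5 = 4.0, p = 1e-6),
    # lost confidence after revision: cellularity criterion drops out
    rec(1L, "MET", xB = 4.2, fB = 0.60, fA = 0.45,
        reads = 45000L, mapd = 0.28, conf5 = 4.1, p = 1e-6),
    # software calls dropped after revision (cellularity revised upward)
    rec(2L, "CDK4", xB = 4.2, fB = 0.40, fA = 0.80,
        reads = 20000L, mapd = 0.70, conf5 = 2.0, p = 1e-2),
    # called but never confidence-gated (noisy QC)
    rec(14L, "CCND1", xB = 4.3, fB = 0.55, fA = 0.30,
        reads = 15000L, mapd = 0.80, conf5 = 2.0, p = 5e-2),
    # copy-neutral background, never called
    rec(10L, "BRAF", xB = 2.0, fB = 0.60, fA = 0.30,
        reads = 25000L, mapd = 0.30, conf5 = 1.5, p = 0.5),
    # newly confident after revision via the cellularity criterion alone
    rec(1L, "PIK3CA", xB = 3.111111111111111, fB = 0.45, fA = 0.55,
        reads = 40000L, mapd = 0.30, conf5 = 4.0, p = 1e-6))
  # distinguish gene labels of the confident blocks for readable reports
  blocks$gene[1:6] <- c("EGFR", "EGFR", "EGFR", "KRAS", "MET", "ERBB2")
  blocks$gene[7:12] <- c("EGFR", "EGFR", "KRAS", "KRAS", "MET", "PIK3CA")
  base <- data.frame(case_id = sprintf("case-%02d", seq_len(nrow(blocks))),
                     gene = blocks$gene, C = blocks$C,
                     read_count = blocks$read_count, mapd = blocks$mapd,
                     cn_conf_5 = blocks$cn_conf_5, p_value = blocks$p_value,
                     stringsAsFactors = FALSE)
  before <- cbind(base, f = blocks$fB)
  after <- cbind(base, f = blocks$fA)
  cols <- c("case_id", "gene", "C", "f", "read_count", "mapd", "cn_conf_5", "p_value")
  list(before = before[cols], after = after[cols])
}
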