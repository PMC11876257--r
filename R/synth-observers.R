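#' Simulate observer (pathologist) TCF ratings
#'
#' Given true tumor-cellular-fraction values on the percent scale and one
#' rating model per observer, emits `rating = clip(round(truth + bias +
#' noise))`, with rounding to each observer's reporting granularity and
#' clipping to `[0, 100]`. A positive bias emulates the visual
#' over-estimation of tumor cellularity relative to a cell-by-cell count.
#'
#' @param trueTCF numeric vector of true TCF values in `[0, 100]` (percent).
#' @param models list of [ObserverModel-class] objects (one per observer).
#' @param caseIds optional case identifiers (default `case-001`, ...).
#' @return data.frame with `case_id` and one integer rating column per
#'   observer (`obs1`, `obs2`, ...).
#' @examples
#' simulateObservers(c(30, 50), list(observerModel(bias = 20, noiseSD = 0)))
#' @export
simulateObservers <- function(trueTCF, models, caseIds = NULL) {
  if (any(!is.finite(trueTCF)) || any(trueTCF < 0 | trueTCF > 100))
    stop("trueTCF values must be finite and in [0, 100]")
  if (!length(models)) stop("need at least one observer model")
  if (is.null(caseIds)) caseIds <- sprintf("case-%03d", seq_along(trueTCF))
  out <- data.frame(case_id = caseIds, stringsAsFactors = FALSE)
  for (j in seq_along(models)) {
    mod <- models[[j]]
    stopifnot(is(mod, "ObserverModel"))
    set.seed(mod@seed)
    noise <- if (mod@noiseSD > 0)
      stats::rnorm(length(trueTCF), 0, mod@noiseSD) else rep(0, length(trueTCF))
    raw <- trueTCF + mod@bias + noise
    rated <- round(raw / mod@rounding) * mod@rounding
    out[[paste0("obs", j)]] <- pmin(100, pmax(0, rated))
  }
  out
}
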