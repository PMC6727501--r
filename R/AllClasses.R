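#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowData colData
NULL

#' ClaimSet: DRG claims as a SummarizedExperiment
#'
#' Container for diagnosis-related-group (DRG) claims data. Fee items are rows,
#' discharge cases are columns. The \code{"fee"} assay holds the claimed amount
#' per (item, case) in currency units, with \code{NA} marking missing cells: a
#' zero or absent fee means the item was not claimed and is treated as missing
#' throughout (it never enters normalisation bounds, calibration or residuals).
#' An optional logical \code{"deducted"} assay carries the insurer's audit
#' labels (TRUE where the item was deducted from reimbursement).
#'
#' Row metadata gives the fee-item schema (\code{label}, \code{category});
#' column metadata gives \code{case_id}, \code{drg} and \code{year}. The
#' \code{role} slot records whether the set is a \code{"norm"} group (clean
#' reference claims used to calibrate item difficulties) or an
#' \code{"experimental"} group (cases to be scored, optionally audited).
#'
#' @slot role character, \code{"norm"} or \code{"experimental"}.
#' @seealso [claimSet()], [readClaims()], [simulateClaimSet()]
#' @export
setClass("ClaimSet", contains = "SummarizedExperiment",
         representation(role = "character"))

setValidity("ClaimSet", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !object@role %in% c("norm", "experimental"))
    msg <- c(msg, "role must be 'norm' or 'experimental'")
  if (!"fee" %in% assayNames(object))
    msg <- c(msg, "a 'fee' assay is required")
  else {
    fee <- assay(object, "fee")
    if (any(fee <= 0, na.rm = TRUE))
      msg <- c(msg, "fees must be positive or NA (zero fees are missing)")
  }
  cd <- colData(object)
  for (col in c("case_id", "drg", "year"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  rd <- rowData(object)
  for (col in c("label", "category"))
    if (!col %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", col))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "item ids (rownames) must be unique")
  if ("deducted" %in% assayNames(object) &&
      !is.logical(assay(object, "deducted")))
    msg <- c(msg, "'deducted' assay must be logical")
  if (length(msg)) msg else TRUE
})

#' NormModel: per-DRG calibrated item parameters
#'
#' Result of calibrating the continuous-response Rasch model on a norm group
#' for one DRG: per-item difficulty delta (logits, centred to mean zero for
#' identifiability), its standard error, the number of norm cases informing
#' it, and the min--max normalisation bounds derived from the norm group.
#' Items excluded from modelling (never observed, or degenerate with all fees
#' equal) are listed in \code{excluded} with a reason.
#'
#' @slot drg character DRG code.
#' @slot items data.frame with columns item_id, delta, se, n_obs, min, max.
#' @slot excluded data.frame with columns item_id, reason.
#' @slot calibration list: eps, tol, max_iter, iterations, max_change,
#'   converged, centered.
#' @slot schema data.frame fee-item schema (item_id, label, category).
#' @seealso [calibrateNormModel()], [writeNormModel()]
#' @export
setClass("NormModel",
         representation(drg = "character", items = "data.frame",
                        excluded = "data.frame", calibration = "list",
                        schema = "data.frame"))

setValidity("NormModel", function(object) {
  msg <- character()
  it <- object@items
  need <- c("item_id", "delta", "se", "n_obs", "min", "max")
  if (!all(need %in% colnames(it)))
    return(sprintf("items must have columns %s", paste(need, collapse = ", ")))
  if (nrow(it) < 2L) msg <- c(msg, "a model needs at least 2 items")
  if (any(!is.finite(it$delta))) msg <- c(msg, "difficulties must be finite")
  if (abs(mean(it$delta)) > 1e-8)
    msg <- c(msg, "difficulties must be centred to mean 0 (within 1e-8)")
  if (any(it$se <= 0)) msg <- c(msg, "standard errors must be positive")
  if (any(it$n_obs < 2L)) msg <- c(msg, "each item needs >= 2 observations")
  if (any(it$min > it$max)) msg <- c(msg, "bounds must satisfy min <= max")
  if (length(msg)) msg else TRUE
})

#' CaseScores: per-case Rasch residual scoring results
#'
#' Output of [scoreClaimSet()]: one row per scored case in \code{cases}
#' (ability theta and its SE, items used, convergence, outfit mean-square,
#' flag counts, status) and one row per observed (case, item) cell in
#' \code{cells} (raw fee, normalised observed score O, model-expected score E,
#' variance E(1-E), standardized residual Z, flag). Cases whose DRG had no
#' model, or with no observed modelled items, appear in \code{skipped} /
#' with status \code{"unscorable"} rather than raising errors.
#'
#' @slot cases data.frame of per-case summaries.
#' @slot cells data.frame of per-cell residuals.
#' @slot skipped data.frame of cases not scored, with a reason.
#' @slot threshold numeric flag threshold on Z (default 2).
#' @slot side character, \code{"upper"} (flag Z > threshold, the up-coding
#'   direction) or \code{"two"} (flag |Z| > threshold).
#' @export
setClass("CaseScores",
         representation(cases = "data.frame", cells = "data.frame",
                        skipped = "data.frame", threshold = "numeric",
                        side = "character"))

setValidity("CaseScores", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive number")
  if (!object@side %in% c("upper", "two"))
    msg <- c(msg, "side must be 'upper' or 'two'")
  if (nrow(object@cells)) {
    z <- object@cells$z
    chk <- (object@cells$O - object@cells$E) / sqrt(object@cells$var)
    if (max(abs(z - chk)) > 1e-12)
      msg <- c(msg, "z must equal (O - E)/sqrt(var)")
  }
  if (length(msg)) msg else TRUE
})

#' EvalTable: stratified accuracy with a chi-square homogeneity test
#'
#' Per-stratum correct/incorrect counts and rates, a pooled row, and an
#' uncorrected Pearson chi-square test of homogeneity of the correct rate
#' across strata (omitted, NA, when there is a single stratum).
#'
#' @slot strata data.frame: stratum, correct, incorrect, total, rate.
#' @slot pooled named numeric: correct, incorrect, total, rate.
#' @slot chi2,p numeric statistic and two-sided p (NA if single stratum).
#' @slot mode character counting rule used ("matched", "any", "category" or
#'   "counts" when built directly from printed counts).
#' @slot n_excluded integer cases excluded as not evaluable.
#' @export
setClass("EvalTable",
         representation(strata = "data.frame", pooled = "numeric",
                        chi2 = "numeric", p = "numeric", mode = "character",
                        n_excluded = "integer"))

setValidity("EvalTable", function(object) {
  s <- object@strata
  if (!all(c("stratum", "correct", "incorrect", "total", "rate") %in% colnames(s)))
    return("strata must have columns stratum, correct, incorrect, total, rate")
  if (any(s$correct + s$incorrect != s$total))
    return("correct + incorrect must equal total")
  if (any(s$rate < 0 | s$rate > 1)) return("rates must lie in [0, 1]")
  if (!is.na(object@chi2) && object@chi2 < 0) return("chi2 must be >= 0")
  TRUE
})

#' RocResult: Mann-Whitney AUC with a test against 0.5
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability (ties counted half), with the Hanley-McNeil standard error and
#' a two-sided normal test of AUC = 0.5.
#'
#' @slot auc numeric in [0, 1].
#' @slot n_pos,n_neg integer class sizes.
#' @slot se numeric Hanley-McNeil standard error.
#' @slot p_vs_half numeric two-sided p for AUC != 0.5.
#' @export
setClass("RocResult",
         representation(auc = "numeric", n_pos = "integer", n_neg = "integer",
                        se = "numeric", p_vs_half = "numeric"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (object@n_pos < 1L || object@n_neg < 1L)
    return("both classes must be non-empty")
  TRUE
})
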