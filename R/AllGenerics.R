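#' Accessors for raschDRG classes
#'
#' Small accessor layer over the S4 slots: fee and deduction assays, case
#' metadata and role for [ClaimSet-class]; difficulties, bounds and
#' calibration report for [NormModel-class]; per-case and per-cell tables for
#' [CaseScores-class].
#'
#' @param x a ClaimSet, NormModel or CaseScores object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `fees()`: numeric matrix (items x cases) of claimed amounts, NA
#'   where missing.
#' @export
setGeneric("fees", function(x) standardGeneric("fees"))

#' @rdname accessors
#' @export
setMethod("fees", "ClaimSet", function(x) assay(x, "fee"))

#' @rdname accessors
#' @return `deductions()`: logical matrix (items x cases) of audit labels, or
#'   NULL when the set carries none.
#' @export
setGeneric("deductions", function(x) standardGeneric("deductions"))

#' @rdname accessors
#' @export
setMethod("deductions", "ClaimSet", function(x) {
  if ("deducted" %in% assayNames(x)) assay(x, "deducted") else NULL
})

#' @rdname accessors
#' @return `claimRole()`: "norm" or "experimental".
#' @export
setGeneric("claimRole", function(x) standardGeneric("claimRole"))

#' @rdname accessors
#' @export
setMethod("claimRole", "ClaimSet", function(x) x@role)

#' @rdname accessors
#' @return `caseInfo()`: data.frame of per-case metadata (case_id, drg, year).
#' @export
setGeneric("caseInfo", function(x) standardGeneric("caseInfo"))

#' @rdname accessors
#' @export
setMethod("caseInfo", "ClaimSet", function(x)
  as.data.frame(colData(x)))

#' @rdname accessors
#' @return `feeSchema()`: data.frame fee-item schema (item_id, label,
#'   category).
#' @export
setGeneric("feeSchema", function(x) standardGeneric("feeSchema"))

#' @rdname accessors
#' @export
setMethod("feeSchema", "ClaimSet", function(x) {
  rd <- as.data.frame(rowData(x))
  data.frame(item_id = rownames(x), label = rd$label,
             category = rd$category, row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("feeSchema", "NormModel", function(x) x@schema)

#' @rdname accessors
#' @return `drgCode()`: the model's DRG code.
#' @export
setGeneric("drgCode", function(x) standardGeneric("drgCode"))

#' @rdname accessors
#' @export
setMethod("drgCode", "NormModel", function(x) x@drg)

#' @rdname accessors
#' @return `difficulties()`: named numeric vector of item difficulties
#'   (logits, mean-centred).
#' @export
setGeneric("difficulties", function(x) standardGeneric("difficulties"))

#' @rdname accessors
#' @export
setMethod("difficulties", "NormModel", function(x)
  stats::setNames(x@items$delta, x@items$item_id))

#' @rdname accessors
#' @return `itemTable()`: data.frame of per-item calibration results
#'   (item_id, delta, se, n_obs, min, max).
#' @export
setGeneric("itemTable", function(x) standardGeneric("itemTable"))

#' @rdname accessors
#' @export
setMethod("itemTable", "NormModel", function(x) x@items)

#' @rdname accessors
#' @return `normBounds()`: data.frame of per-item normalisation bounds
#'   (item_id, min, max).
#' @export
setGeneric("normBounds", function(x) standardGeneric("normBounds"))

#' @rdname accessors
#' @export
setMethod("normBounds", "NormModel", function(x)
  x@items[, c("item_id", "min", "max")])

#' @rdname accessors
#' @return `calibrationInfo()`: list with eps, tol, max_iter, iterations,
#'   max_change, converged.
#' @export
setGeneric("calibrationInfo", function(x) standardGeneric("calibrationInfo"))

#' @rdname accessors
#' @export
setMethod("calibrationInfo", "NormModel", function(x) x@calibration)

#' @rdname accessors
#' @return `excludedItems()`: data.frame of items dropped before calibration
#'   (item_id, reason).
#' @export
setGeneric("excludedItems", function(x) standardGeneric("excludedItems"))

#' @rdname accessors
#' @export
setMethod("excludedItems", "NormModel", function(x) x@excluded)

#' @rdname accessors
#' @return `caseSummary()`: data.frame, one row per scored case (theta, se,
#'   n_items, converged, outfit_mnsq, n_flagged, case_flagged, status).
#' @export
setGeneric("caseSummary", function(x) standardGeneric("caseSummary"))

#' @rdname accessors
#' @export
setMethod("caseSummary", "CaseScores", function(x) x@cases)

#' @rdname accessors
#' @return `residualCells()`: data.frame, one row per observed (case, item)
#'   cell (raw_fee, O, E, var, z, flagged).
#' @export
setGeneric("residualCells", function(x) standardGeneric("residualCells"))

#' @rdname accessors
#' @export
setMethod("residualCells", "CaseScores", function(x) x@cells)

#' @rdname accessors
#' @return `skippedCases()`: data.frame of cases not scored, with reasons.
#' @export
setGeneric("skippedCases", function(x) standardGeneric("skippedCases"))

#' @rdname accessors
#' @export
setMethod("skippedCases", "CaseScores", function(x) x@skipped)

#' @rdname accessors
#' @return `flagThreshold()`: the Z threshold used for flagging.
#' @export
setGeneric("flagThreshold", function(x) standardGeneric("flagThreshold"))

#' @rdname accessors
#' @export
setMethod("flagThreshold", "CaseScores", function(x) x@threshold)

#' @rdname accessors
#' @return `evalStrata()`: per-stratum counts and rates of an EvalTable.
#' @export
setGeneric("evalStrata", function(x) standardGeneric("evalStrata"))

#' @rdname accessors
#' @export
setMethod("evalStrata", "EvalTable", function(x) x@strata)

#' @rdname accessors
#' @return `pooledRate()`: the pooled correct rate of an EvalTable.
#' @export
setGeneric("pooledRate", function(x) standardGeneric("pooledRate"))

#' @rdname accessors
#' @export
setMethod("pooledRate", "EvalTable", function(x) unname(x@pooled["rate"]))

#' @rdname accessors
#' @return `chisqStat()`: c(chi2, p) of an EvalTable's homogeneity test.
#' @export
setGeneric("chisqStat", function(x) standardGeneric("chisqStat"))

#' @rdname accessors
#' @export
setMethod("chisqStat", "EvalTable", function(x) c(chi2 = x@chi2, p = x@p))

#' @rdname accessors
#' @return `auc()`: the area under the ROC curve of a RocResult.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

setMethod("show", "ClaimSet", function(object) {
  cat(sprintf("ClaimSet (%s role): %d fee items x %d cases\n",
              object@role, nrow(object), ncol(object)))
  drg <- unique(colData(object)$drg)
  cat(sprintf("  DRGs: %s\n", paste(utils::head(drg, 6), collapse = ", ")))
  fee <- assay(object, "fee")
  cat(sprintf("  observed cells: %d of %d (%.1f%% missing)\n",
              sum(!is.na(fee)), length(fee), 100 * mean(is.na(fee))))
  if ("deducted" %in% assayNames(object))
    cat(sprintf("  audit labels: %d deducted cells\n",
                sum(assay(object, "deducted"), na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "NormModel", function(object) {
  cal <- object@calibration
  cat(sprintf("NormModel for DRG %s: %d items calibrated\n",
              object@drg, nrow(object@items)))
  cat(sprintf("  delta range [%.2f, %.2f] logits; %s in %d sweeps (max change %.2g)\n",
              min(object@items$delta), max(object@items$delta),
              if (isTRUE(cal$converged)) "converged" else "NOT converged",
              cal$iterations, cal$max_change))
  if (nrow(object@excluded))
    cat(sprintf("  excluded items: %s\n",
                paste(object@excluded$item_id, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "CaseScores", function(object) {
  cat(sprintf("CaseScores: %d cases scored, %d residual cells (threshold Z > %g, %s-sided)\n",
              nrow(object@cases), nrow(object@cells), object@threshold,
              object@side))
  if (nrow(object@cases))
    cat(sprintf("  flagged cases: %d (%.1f%%)\n",
                sum(object@cases$case_flagged),
                100 * mean(object@cases$case_flagged)))
  if (nrow(object@skipped))
    cat(sprintf("  skipped: %d cases\n", nrow(object@skipped)))
  invisible(NULL)
})

setMethod("show", "EvalTable", function(object) {
  cat(sprintf("EvalTable (%s mode)\n", object@mode))
  print(object@strata, row.names = FALSE)
  cat(sprintf("  pooled rate %.3f (%d/%d)", object@pooled["rate"],
              object@pooled["correct"], object@pooled["total"]))
  if (!is.na(object@chi2))
    cat(sprintf("; chi2 = %.3f, p = %.3f", object@chi2, object@p))
  cat("\n")
  if (object@n_excluded > 0L)
    cat(sprintf("  %d cases excluded as not evaluable\n", object@n_excluded))
  invisible(NULL)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("ROC AUC = %.3f (n+ = %d, n- = %d, SE = %.4f, p vs 0.5 = %.4g)\n",
              object@auc, object@n_pos, object@n_neg, object@se,
              object@p_vs_half))
  invisible(NULL)
})
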