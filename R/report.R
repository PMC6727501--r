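#' Bubble-chart dashboard payload for one scored case
#'
#' Builds the data behind the per-case diagnostic bubble chart: one bubble
#' per scored fee item with item difficulty on the y-axis (hardest item on
#' top -- bubbles are ordered by difficulty, descending), the standardized
#' residual Z on the x-axis, bubble size proportional to the difficulty's
#' standard error, the raw claimed fee attached, and flagged items (Z beyond
#' the threshold) marked for distinct styling. A separate case bubble carries
#' the estimated ability, and the payload records the vertical threshold line
#' (x = 2 by default) plus case metadata (DRG, outfit mean-square).
#'
#' @param scores a [CaseScores-class].
#' @param case_id the case to display.
#' @param model the [NormModel-class] the case was scored against (supplies
#'   item SEs and labels).
#' @return payload list: \code{case} (case_id, drg, theta, theta_se,
#'   outfit_mnsq), \code{threshold}, \code{side}, \code{items} (list of
#'   bubbles: item_id, label, y = delta, x = z, size = se, raw_fee,
#'   flagged).
#' @export
kidnapPayload <- function(scores, case_id, model) {
  stopifnot(is(scores, "CaseScores"), is(model, "NormModel"))
  cases <- caseSummary(scores)
  row <- cases[cases$case_id == case_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("case '", case_id, "' not found in scores")
  if (row$status != "scored")
    stop("case '", case_id, "' is ", row$status, "; no payload can be built")
  cells <- residualCells(scores)
  cells <- cells[cells$case_id == case_id, , drop = FALSE]
  it <- itemTable(model)
  idx <- match(cells$item_id, it$item_id)
  schema <- feeSchema(model)
  bubbles <- data.frame(item_id = cells$item_id,
                        label = schema$label[match(cells$item_id,
                                                   schema$item_id)],
                        y = it$delta[idx], x = cells$z, size = it$se[idx],
                        raw_fee = cells$raw_fee, flagged = cells$flagged,
                        stringsAsFactors = FALSE)
  bubbles <- bubbles[order(-bubbles$y, bubbles$item_id), , drop = FALSE]
  list(case = list(case_id = case_id, drg = row$drg, theta = row$theta,
                   theta_se = row$se, outfit_mnsq = row$outfit_mnsq),
       threshold = flagThreshold(scores),
       side = scores@side,
       items = lapply(seq_len(nrow(bubbles)),
                      function(i) as.list(bubbles[i, ])))
}

#' Write / read a dashboard payload
#'
#' Lossless JSON round-trip of a [kidnapPayload()] list (numbers at full
#' precision, no timestamps, so repeated writes are byte-identical).
#'
#' @param payload a payload list.
#' @param path file path.
#' @return `writeKidnapPayload()`: the path, invisibly;
#'   `readKidnapPayload()`: the payload list.
#' @export
writeKidnapPayload <- function(payload, path) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeKidnapPayload
#' @export
readKidnapPayload <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  p$items <- lapply(p$items, function(b) {
    b$flagged <- isTRUE(b$flagged)
    b
  })
  p
}

#' Render a static detection report
#'
#' Writes one dashboard payload JSON per scored case, an \code{index.json}
#' summarising every case (ability, outfit, flags, status), and -- when
#' labelled claims are supplied -- the accuracy and category evaluation
#' tables as CSV. Output is deterministic: rerunning on the same inputs
#' yields byte-identical files.
#'
#' @param scores a [CaseScores-class] with at least one scored case.
#' @param models a [NormModel-class] or list of them named by DRG.
#' @param out_dir output directory (created if absent).
#' @param claims optional labelled [ClaimSet-class] to add evaluation tables.
#' @param mode counting rule for the accuracy table, see [caseCorrect()].
#' @return character vector of files written, invisibly.
#' @export
renderReport <- function(scores, models, out_dir, claims = NULL,
                         mode = c("matched", "any")) {
  mode <- match.arg(mode)
  stopifnot(is(scores, "CaseScores"))
  cases <- caseSummary(scores)
  scored <- cases[cases$status == "scored", , drop = FALSE]
  if (nrow(scored) == 0L) stop("no scored cases; nothing to report")
  if (is(models, "NormModel")) models <- list(models)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, drgCode, character(1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0L)
    stop("output directory '", out_dir, "' is not writable")
  written <- character()
  for (i in seq_len(nrow(scored))) {
    cid <- scored$case_id[i]
    payload <- kidnapPayload(scores, cid, models[[scored$drg[i]]])
    f <- file.path(out_dir, paste0("case_", cid, ".json"))
    writeKidnapPayload(payload, f)
    written <- c(written, f)
  }
  idx <- file.path(out_dir, "index.json")
  jsonlite::write_json(list(threshold = flagThreshold(scores),
                            side = scores@side,
                            cases = cases,
                            skipped = skippedCases(scores)),
                       idx, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  written <- c(written, idx)
  if (!is.null(claims) && !is.null(deductions(claims))) {
    f1 <- file.path(out_dir, "accuracy_by_year.csv")
    writeEvalTable(accuracyTable(scores, claims, mode = mode), f1)
    f2 <- file.path(out_dir, "accuracy_by_category.csv")
    writeEvalTable(categoryTable(scores, claims), f2)
    written <- c(written, f1, f2)
  }
  invisible(written)
}
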