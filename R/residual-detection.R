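#' Standardized residual Z-score of a cell
#'
#' \deqn{Z = \frac{O - E}{\sqrt{E(1-E)}}}
#' for an observed normalised fee O and its model expectation E. Positive Z
#' means the fee is above the model standard for this case and item (the
#' up-coding direction); negative Z means below.
#'
#' @param O observed normalised score(s).
#' @param E expected score(s), strictly inside (0, 1).
#' @return standardized residual(s); sign equals sign of O - E.
#' @examples
#' residualZ(0.9, 0.1)   # 0.8/0.3 = 2.667
#' @export
residualZ <- function(O, E) {
  (O - E) / sqrt(cellVariance(E))
}

#' Outfit mean-square of a case
#'
#' Unweighted person-fit statistic: the mean of squared standardized
#' residuals over a case's observed cells. Zero iff every residual is zero;
#' values below 2 are conventionally read as fit that is not severely
#' aberrant overall (individual cells can still be flagged).
#'
#' @param z numeric vector of standardized residuals, length >= 1.
#' @return non-negative mean of \code{z^2}.
#' @examples
#' outfitMNSQ(c(1, -1, 2))   # 2
#' @export
outfitMNSQ <- function(z) {
  if (length(z) == 0L) stop("outfit needs at least one residual cell")
  mean(z^2)
}

#' Flag suspicious fee items by residual Z
#'
#' Items whose standardized residual exceeds the threshold. The default,
#' upper one-sided with threshold 2.0 (approximately the 1.96 two-sided
#' normal criterion at p < 0.05, rounded up for small samples), flags the
#' up-coding direction \code{z > threshold}; \code{side = "two"} flags
#' \code{|z| > threshold}. The inequality is strict: a residual exactly at
#' the threshold is not flagged.
#'
#' @param cells data.frame with columns \code{item_id} and \code{z} (as in
#'   [residualCells()]).
#' @param threshold positive flag threshold, default 2.
#' @param side \code{"upper"} (default) or \code{"two"}.
#' @return character vector of flagged item ids (possibly empty).
#' @export
flagItems <- function(cells, threshold = 2, side = c("upper", "two")) {
  side <- match.arg(side)
  stopifnot(threshold > 0)
  hit <- if (side == "upper") cells$z > threshold else abs(cells$z) > threshold
  cells$item_id[hit]
}

#' Score one case against a calibrated norm model
#'
#' The per-case detection pipeline: normalise the case's non-missing fees
#' with the model's norm-group bounds (values outside the bounds are
#' clamped), estimate the case ability from the observed modelled items only,
#' then fill one residual cell per observed item -- observed O, expected
#' E(theta, delta), variance E(1-E), standardized Z -- and derive the outfit
#' mean-square and the flag set. Ability is estimated from all observed
#' items, including any up-coded one.
#'
#' A case with no observed modelled items returns status
#' \code{"unscorable"} (with empty cells), not an error.
#'
#' @param fee named numeric vector of raw fees for one case (NA or 0 =
#'   missing); names are item ids.
#' @param model a [NormModel-class] for the case's DRG.
#' @param threshold,side flag rule, see [flagItems()].
#' @param tol,max_iter passed to [estimateAbility()].
#' @return list with \code{status} ("scored" or "unscorable"), \code{ability}
#'   (as returned by [estimateAbility()]), \code{cells} (data.frame item_id,
#'   raw_fee, O, E, var, z, flagged), \code{outfit_mnsq},
#'   \code{flagged_items}, \code{case_flagged}.
#' @export
scoreCase <- function(fee, model, threshold = 2, side = c("upper", "two"),
                      tol = 1e-4, max_iter = 100L) {
  side <- match.arg(side)
  stopifnot(is(model, "NormModel"))
  it <- model@items
  eps <- model@calibration$eps
  if (is.null(eps)) eps <- 0.005
  fee <- fee[!is.na(fee) & fee > 0]
  fee <- fee[names(fee) %in% it$item_id]
  if (length(fee) == 0L)
    return(list(status = "unscorable", ability = NULL,
                cells = data.frame(), outfit_mnsq = NA_real_,
                flagged_items = character(), case_flagged = FALSE))
  idx <- match(names(fee), it$item_id)
  O <- normalizeFee(unname(fee), it$min[idx], it$max[idx], eps = eps)
  names(O) <- names(fee)
  d <- stats::setNames(it$delta[idx], names(fee))
  ab <- estimateAbility(O, d, tol = tol, max_iter = max_iter)
  E <- expectedScore(ab$theta, d)
  V <- cellVariance(E)
  z <- residualZ(O, E)
  cells <- data.frame(item_id = names(fee), raw_fee = unname(fee),
                      O = unname(O), E = unname(E), var = unname(V),
                      z = unname(z), row.names = NULL,
                      stringsAsFactors = FALSE)
  flagged <- flagItems(cells, threshold = threshold, side = side)
  cells$flagged <- cells$item_id %in% flagged
  list(status = "scored", ability = ab, cells = cells,
       outfit_mnsq = outfitMNSQ(z), flagged_items = flagged,
       case_flagged = length(flagged) > 0L)
}

#' Score every case in a claim set
#'
#' Applies [scoreCase()] to each case, looking up the norm model for the
#' case's DRG. Cases whose DRG has no model are reported in the skipped
#' table, not errored; cases with no observed modelled items get status
#' \code{"unscorable"}. The total number of residual cells equals the number
#' of observed (case, modelled-item) fees.
#'
#' @param claims a [ClaimSet-class] (typically experimental role).
#' @param models a single [NormModel-class], or a list of them named by DRG
#'   code (unnamed lists are named from the models' own DRG codes).
#' @param threshold,side flag rule, see [flagItems()].
#' @return a [CaseScores-class].
#' @export
scoreClaimSet <- function(claims, models, threshold = 2,
                          side = c("upper", "two")) {
  side <- match.arg(side)
  stopifnot(is(claims, "ClaimSet"))
  if (is(models, "NormModel")) models <- list(models)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, drgCode, character(1))
  info <- caseInfo(claims)
  fee <- fees(claims)
  case_rows <- list(); cell_rows <- list(); skip_rows <- list()
  for (j in seq_len(ncol(fee))) {
    cid <- info$case_id[j]; drg <- info$drg[j]
    if (!drg %in% names(models)) {
      skip_rows[[length(skip_rows) + 1L]] <-
        data.frame(case_id = cid, drg = drg,
                   reason = "no model for DRG", stringsAsFactors = FALSE)
      next
    }
    sc <- scoreCase(fee[, j], models[[drg]], threshold = threshold,
                    side = side)
    if (sc$status == "unscorable") {
      case_rows[[length(case_rows) + 1L]] <-
        data.frame(case_id = cid, drg = drg, year = info$year[j],
                   theta = NA_real_, se = NA_real_, n_items = 0L,
                   converged = NA, outfit_mnsq = NA_real_, n_flagged = 0L,
                   case_flagged = FALSE, status = "unscorable",
                   stringsAsFactors = FALSE)
      next
    }
    case_rows[[length(case_rows) + 1L]] <-
      data.frame(case_id = cid, drg = drg, year = info$year[j],
                 theta = sc$ability$theta, se = sc$ability$se,
                 n_items = sc$ability$n_items_used,
                 converged = sc$ability$converged,
                 outfit_mnsq = sc$outfit_mnsq,
                 n_flagged = length(sc$flagged_items),
                 case_flagged = sc$case_flagged, status = "scored",
                 stringsAsFactors = FALSE)
    cells <- sc$cells
    cells <- cbind(data.frame(case_id = cid, drg = drg,
                              year = info$year[j],
                              stringsAsFactors = FALSE), cells)
    cell_rows[[length(cell_rows) + 1L]] <- cells
  }
  empty_case <- data.frame(case_id = character(), drg = character(),
                           year = integer(), theta = numeric(),
                           se = numeric(), n_items = integer(),
                           converged = logical(), outfit_mnsq = numeric(),
                           n_flagged = integer(), case_flagged = logical(),
                           status = character(), stringsAsFactors = FALSE)
  empty_cell <- data.frame(case_id = character(), drg = character(),
                           year = integer(), item_id = character(),
                           raw_fee = numeric(), O = numeric(), E = numeric(),
                           var = numeric(), z = numeric(),
                           flagged = logical(), stringsAsFactors = FALSE)
  new("CaseScores",
      cases = if (length(case_rows)) do.call(rbind, case_rows) else empty_case,
      cells = if (length(cell_rows)) do.call(rbind, cell_rows) else empty_cell,
      skipped = if (length(skip_rows)) do.call(rbind, skip_rows)
                else data.frame(case_id = character(), drg = character(),
                                reason = character(), stringsAsFactors = FALSE),
      threshold = threshold, side = side)
}

#' Export case scores to CSV
#'
#' Flat per-cell export (case_id, drg, year, item_id, raw_fee, O, E, var, z,
#' flagged) for spreadsheets and downstream tools.
#'
#' @param scores a [CaseScores-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCaseScores <- function(scores, file) {
  stopifnot(is(scores, "CaseScores"))
  utils::write.csv(residualCells(scores), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}
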