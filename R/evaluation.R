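#' Was a case's deduction correctly predicted?
#'
#' Compares one case's residual flags against its audit labels. In
#' \code{"matched"} mode the prediction counts as correct iff at least one
#' actually-deducted item was flagged (z above threshold); a case with no
#' deducted items is not evaluable in this mode and returns NA. In
#' \code{"any"} mode the case counts as correct iff any item was flagged,
#' regardless of which.
#'
#' @param z named numeric vector of residual Z-scores for the case's observed
#'   items.
#' @param deducted named logical vector of audit labels (missing names are
#'   treated as not deducted).
#' @param threshold flag threshold, default 2.
#' @param side \code{"upper"} or \code{"two"}, see [flagItems()].
#' @param mode \code{"matched"} (default) or \code{"any"}.
#' @return TRUE, FALSE, or NA (not evaluable).
#' @export
caseCorrect <- function(z, deducted, threshold = 2,
                        side = c("upper", "two"),
                        mode = c("matched", "any")) {
  side <- match.arg(side); mode <- match.arg(mode)
  hit <- if (side == "upper") z > threshold else abs(z) > threshold
  if (mode == "any") return(any(hit))
  ded <- names(z) %in% names(deducted)[deducted %in% TRUE]
  if (!any(ded)) return(NA)
  any(hit & ded)
}

## Assemble an EvalTable from per-stratum counts; shared by the counts path
## and the score paths.
.eval_table <- function(strata, correct, incorrect, mode,
                        n_excluded = 0L) {
  total <- correct + incorrect
  tab <- data.frame(stratum = as.character(strata), correct = correct,
                    incorrect = incorrect, total = total,
                    rate = correct / total, stringsAsFactors = FALSE)
  pooled <- c(correct = sum(correct), incorrect = sum(incorrect),
              total = sum(total), rate = sum(correct) / sum(total))
  if (nrow(tab) >= 2L && all(total > 0)) {
    if (sum(correct) == 0L || sum(incorrect) == 0L) {
      ## identical row proportions (all correct or all incorrect everywhere)
      chi2 <- 0; p <- 1
    } else {
      ct <- suppressWarnings(
        stats::chisq.test(cbind(correct, incorrect), correct = FALSE))
      chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
    }
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  new("EvalTable", strata = tab, pooled = pooled, chi2 = chi2, p = p,
      mode = mode, n_excluded = as.integer(n_excluded))
}

#' Accuracy table from fixed counts
#'
#' Builds an [EvalTable-class] directly from per-stratum correct/incorrect
#' counts (e.g. published audit summaries): rates, the pooled row, and the
#' uncorrected Pearson chi-square homogeneity test across strata.
#'
#' @param counts data.frame with columns \code{stratum}, \code{correct},
#'   \code{incorrect}.
#' @return an [EvalTable-class].
#' @examples
#' evalFromCounts(data.frame(stratum = c(2015, 2016),
#'                           correct = c(154, 164),
#'                           incorrect = c(40, 30)))
#' @export
evalFromCounts <- function(counts) {
  stopifnot(all(c("stratum", "correct", "incorrect") %in% names(counts)))
  .eval_table(counts$stratum, counts$correct, counts$incorrect,
              mode = "counts")
}

#' Accuracy table of deduction prediction by stratum
#'
#' Scores each case with [caseCorrect()] against the audit labels in
#' \code{claims}, stratifies (by year by default), and returns per-stratum
#' correct/incorrect counts, rates, the pooled rate, and an uncorrected
#' Pearson chi-square test of rate homogeneity across strata. Not-evaluable
#' cases (matched mode, no deducted item) are excluded and counted.
#'
#' @param scores a [CaseScores-class].
#' @param claims the labelled experimental [ClaimSet-class] the scores came
#'   from.
#' @param by stratifying column of [caseSummary()], default \code{"year"}.
#' @param mode \code{"matched"} (default) or \code{"any"}, see
#'   [caseCorrect()].
#' @return an [EvalTable-class].
#' @export
accuracyTable <- function(scores, claims, by = "year",
                          mode = c("matched", "any")) {
  mode <- match.arg(mode)
  stopifnot(is(scores, "CaseScores"), is(claims, "ClaimSet"))
  ded <- deductions(claims)
  if (is.null(ded))
    stop("claims carry no 'deducted' audit labels; evaluation needs them")
  cases <- caseSummary(scores)
  cases <- cases[cases$status == "scored", , drop = FALSE]
  if (nrow(cases) == 0L) stop("no scored cases to evaluate")
  cells <- residualCells(scores)
  ok <- vapply(seq_len(nrow(cases)), function(i) {
    cc <- cells[cells$case_id == cases$case_id[i], , drop = FALSE]
    lab <- ded[cc$item_id, cases$case_id[i]]
    caseCorrect(stats::setNames(cc$z, cc$item_id),
                stats::setNames(lab %in% TRUE, cc$item_id),
                threshold = flagThreshold(scores), side = scores@side,
                mode = mode)
  }, logical(1))
  evaluable <- !is.na(ok)
  n_excl <- sum(!evaluable)
  if (n_excl > 0L)
    warning(n_excl, " case(s) not evaluable (no deducted items), excluded")
  cases <- cases[evaluable, , drop = FALSE]
  ok <- ok[evaluable]
  strat <- cases[[by]]
  agg_c <- tapply(ok, strat, sum)
  agg_t <- tapply(ok, strat, length)
  .eval_table(names(agg_c), as.integer(agg_c),
              as.integer(agg_t - agg_c), mode = mode, n_excluded = n_excl)
}

#' Per-category accuracy tables
#'
#' For each fee category (drug, material, examination by default) and each
#' case, the prediction is correct iff flagging anywhere in the category
#' agrees with deduction anywhere in the category: (any item in the category
#' flagged) == (any item in the category deducted). Every scored case counts
#' in every category's denominator. Returns one [EvalTable-class] per
#' category, stratified by year.
#'
#' @param scores a [CaseScores-class].
#' @param claims the labelled experimental [ClaimSet-class].
#' @param categories categories to tabulate, default
#'   \code{c("drug", "material", "examination")}.
#' @return named list of [EvalTable-class], one per category.
#' @export
categoryTable <- function(scores, claims,
                          categories = c("drug", "material", "examination")) {
  stopifnot(is(scores, "CaseScores"), is(claims, "ClaimSet"))
  ded <- deductions(claims)
  if (is.null(ded))
    stop("claims carry no 'deducted' audit labels; evaluation needs them")
  schema <- feeSchema(claims)
  bad <- setdiff(categories, schema$category)
  if (length(bad))
    stop("no schema items in category: ", paste(bad, collapse = ", "))
  cases <- caseSummary(scores)
  cases <- cases[cases$status == "scored", , drop = FALSE]
  cells <- residualCells(scores)
  unknown <- setdiff(cells$item_id, schema$item_id)
  if (length(unknown))
    stop("scored item(s) missing from schema: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (cat in categories) {
    cat_items <- schema$item_id[schema$category == cat]
    ok <- vapply(seq_len(nrow(cases)), function(i) {
      cc <- cells[cells$case_id == cases$case_id[i] &
                  cells$item_id %in% cat_items, , drop = FALSE]
      flagged <- any(cc$flagged)
      deducted <- any(ded[cat_items, cases$case_id[i]] %in% TRUE)
      flagged == deducted
    }, logical(1))
    agg_c <- tapply(ok, cases$year, sum)
    agg_t <- tapply(ok, cases$year, length)
    out[[cat]] <- .eval_table(names(agg_c), as.integer(agg_c),
                              as.integer(agg_t - agg_c),
                              mode = "category")
  }
  out
}

#' Uncorrected Pearson chi-square on a 2x2 table
#'
#' Pearson statistic with df = 1 and two-sided tail probability, without the
#' Yates continuity correction. The table rows are the two strata (e.g.
#' years), columns correct/incorrect counts.
#'
#' @param a,b first-row counts (correct, incorrect).
#' @param c,d second-row counts (correct, incorrect).
#' @return named numeric c(chi2, p).
#' @examples
#' pearsonChi2(154, 40, 164, 30)   # chi2 = 1.743, p = 0.187
#' @export
pearsonChi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all row and column marginals must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  c(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Mann-Whitney ROC AUC with a test against 0.5
#'
#' AUC as the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted half, computed from mid-ranks. Significance versus the chance
#' value 0.5 uses the Hanley-McNeil standard error
#' \deqn{SE^2 = \frac{A(1-A) + (n_+-1)(Q_1 - A^2) + (n_--1)(Q_2 - A^2)}
#'   {n_+ n_-},}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}, and a two-sided normal
#' test.
#'
#' @param score numeric predictor (here: residual Z).
#' @param label logical (TRUE = positive, here: deducted).
#' @return a [RocResult-class].
#' @examples
#' auc(aucMannWhitney(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE)))  # 1
#' @export
aucMannWhitney <- function(score, label) {
  stopifnot(length(score) == length(label), is.logical(label),
            !anyNA(score), !anyNA(label))
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos < 1L || n_neg < 1L)
    stop("both classes must be present (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ")")
  r <- rank(score)   # mid-ranks handle ties as half-concordant
  A <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) +
                (n_neg - 1) * (Q2 - A^2)) / (n_pos * n_neg))
  p <- if (se > 0) 2 * stats::pnorm(-abs(A - 0.5) / se)
       else if (A == 0.5) 1 else 0
  new("RocResult", auc = A, n_pos = as.integer(n_pos),
      n_neg = as.integer(n_neg), se = se, p_vs_half = p)
}

#' Case-level ROC per category and year
#'
#' For each (year, category) stratum: predictor = the case's maximum residual
#' Z over the category's observed items, label = any deduction in the
#' category for that case; AUC and its test against 0.5 from
#' [aucMannWhitney()]. Cases with no observed item in the category are
#' skipped for that category.
#'
#' @param scores a [CaseScores-class].
#' @param claims the labelled experimental [ClaimSet-class].
#' @param categories default \code{c("drug", "material", "examination")}.
#' @param by_year stratify by year (default) or pool years.
#' @return data.frame: year, category, auc, se, n_pos, n_neg, p_vs_half.
#' @export
categoryROC <- function(scores, claims,
                        categories = c("drug", "material", "examination"),
                        by_year = TRUE) {
  stopifnot(is(scores, "CaseScores"), is(claims, "ClaimSet"))
  ded <- deductions(claims)
  if (is.null(ded))
    stop("claims carry no 'deducted' audit labels; evaluation needs them")
  schema <- feeSchema(claims)
  cases <- caseSummary(scores)
  cases <- cases[cases$status == "scored", , drop = FALSE]
  cells <- residualCells(scores)
  out <- list()
  years <- if (by_year) sort(unique(cases$year)) else NA_integer_
  for (yr in years) {
    cs <- if (by_year) cases[cases$year == yr, , drop = FALSE] else cases
    for (cat in categories) {
      cat_items <- schema$item_id[schema$category == cat]
      sc <- rep(NA_real_, nrow(cs)); lab <- rep(NA, nrow(cs))
      for (i in seq_len(nrow(cs))) {
        cc <- cells[cells$case_id == cs$case_id[i] &
                    cells$item_id %in% cat_items, , drop = FALSE]
        if (nrow(cc) == 0L) next
        sc[i] <- max(cc$z)
        lab[i] <- any(ded[cat_items, cs$case_id[i]] %in% TRUE)
      }
      keep <- !is.na(sc)
      if (sum(lab[keep]) < 1L || sum(!lab[keep]) < 1L) next
      rr <- aucMannWhitney(sc[keep], lab[keep])
      out[[length(out) + 1L]] <- data.frame(
        year = yr, category = cat, auc = rr@auc, se = rr@se,
        n_pos = rr@n_pos, n_neg = rr@n_neg, p_vs_half = rr@p_vs_half,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(year = integer(), category = character(),
                      auc = numeric(), se = numeric(), n_pos = integer(),
                      n_neg = integer(), p_vs_half = numeric()))
  do.call(rbind, out)
}

#' Item-level ROC over all residual cells
#'
#' Pools every observed (case, item) cell: predictor = the cell's residual Z,
#' label = the cell's deduction status. The finest-grained view of detection
#' power.
#'
#' @param scores a [CaseScores-class].
#' @param claims the labelled experimental [ClaimSet-class].
#' @return a [RocResult-class].
#' @export
itemROC <- function(scores, claims) {
  stopifnot(is(scores, "CaseScores"), is(claims, "ClaimSet"))
  ded <- deductions(claims)
  if (is.null(ded))
    stop("claims carry no 'deducted' audit labels; evaluation needs them")
  cells <- residualCells(scores)
  if (nrow(cells) == 0L) stop("no residual cells to evaluate")
  lab <- ded[cbind(cells$item_id, cells$case_id)] %in% TRUE
  aucMannWhitney(cells$z, lab)
}

#' Export an EvalTable (or list of them) to CSV
#'
#' One row per stratum plus a pooled row; a leading \code{table} column names
#' the category when a named list is given.
#'
#' @param x an [EvalTable-class] or a named list of them.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeEvalTable <- function(x, file) {
  as_rows <- function(tab, name) {
    s <- evalStrata(tab)
    s <- rbind(s, data.frame(stratum = "pooled",
                             correct = tab@pooled["correct"],
                             incorrect = tab@pooled["incorrect"],
                             total = tab@pooled["total"],
                             rate = tab@pooled["rate"]))
    s$chi2 <- c(rep(NA, nrow(s) - 1L), tab@chi2)
    s$p <- c(rep(NA, nrow(s) - 1L), tab@p)
    cbind(data.frame(table = name, stringsAsFactors = FALSE), s)
  }
  rows <- if (is(x, "EvalTable")) as_rows(x, "overall")
          else do.call(rbind, Map(as_rows, x, names(x)))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
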