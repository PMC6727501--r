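test_that("caseCorrect distinguishes matched and any counting rules", {
  z <- c(a = 3.62, b = 0.5)
  expect_true(caseCorrect(z, c(a = TRUE)))                     # deducted & flagged
  z2 <- c(a = 1.5, b = 2.5)
  expect_false(caseCorrect(z2, c(a = TRUE), mode = "matched"))
  expect_true(caseCorrect(z2, c(a = TRUE), mode = "any"))
  ## no deducted items: not evaluable in matched mode
  expect_true(is.na(caseCorrect(z, c(a = FALSE), mode = "matched")))
  ## two-sided option catches the negative tail
  z3 <- c(a = -3)
  expect_false(caseCorrect(z3, c(a = TRUE), side = "upper"))
  expect_true(caseCorrect(z3, c(a = TRUE), side = "two"))
})

test_that("count-based tables reproduce rates and the homogeneity chi-square", {
  tab <- evalFromCounts(data.frame(stratum = c(2015, 2016),
                                   correct = c(154, 164),
                                   incorrect = c(40, 30)))
  expect_equal(round(pooledRate(tab), 2), 0.82)
  s <- evalStrata(tab)
  expect_equal(round(s$rate, 2), c(0.79, 0.85))
  expect_equal(round(chisqStat(tab)[["p"]], 2), 0.19)
  expect_equal(chisqStat(tab)[["chi2"]], 1.743, tolerance = 1e-3)
  ## all-correct strata: rate 1, chi2 0
  perfect <- evalFromCounts(data.frame(stratum = 1:2, correct = c(10, 20),
                                       incorrect = c(0, 0)))
  expect_equal(pooledRate(perfect), 1)
  expect_equal(chisqStat(perfect)[["chi2"]], 0)
  ## single stratum: table emitted, chi-square omitted
  single <- evalFromCounts(data.frame(stratum = 1, correct = 5, incorrect = 5))
  expect_true(is.na(chisqStat(single)[["chi2"]]))
})

test_that("pearsonChi2 is uncorrected, symmetric, and guards its marginals", {
  r <- pearsonChi2(154, 40, 164, 30)
  expect_equal(r[["chi2"]], 1.743, tolerance = 1e-3)
  expect_equal(round(r[["p"]], 2), 0.19)
  expect_equal(pearsonChi2(50, 50, 50, 50)[["chi2"]], 0)
  expect_equal(pearsonChi2(50, 50, 50, 50)[["p"]], 1)
  ## invariance under row and column exchange
  expect_equal(pearsonChi2(164, 30, 154, 40)[["chi2"]], r[["chi2"]])
  expect_equal(pearsonChi2(40, 154, 30, 164)[["chi2"]], r[["chi2"]])
  expect_error(pearsonChi2(0, 0, 10, 10), "marginal")
})

test_that("Mann-Whitney AUC handles separation, ties, and label swaps", {
  expect_equal(auc(aucMannWhitney(c(2, 3, 0, 1),
                                  c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_equal(auc(aucMannWhitney(rep(1, 10),
                                  rep(c(TRUE, FALSE), 5))), 0.5)
  set.seed(31)
  for (rep in 1:20) {
    score <- sample(1:8, 30, replace = TRUE)   # heavy ties
    label <- runif(30) < 0.4
    if (!any(label) || all(label)) next
    a <- auc(aucMannWhitney(score, label))
    expect_equal(a, auc_pair_count(score, label))     # O(n^2) oracle, exact
    expect_equal(auc(aucMannWhitney(score, !label)), 1 - a)  # label-swap duality
  }
  expect_error(aucMannWhitney(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  score <- rnorm(80)
  label <- runif(80) < plogis(score)
  a <- auc(aucMannWhitney(score, label))
  ref <- as.numeric(pROC::auc(pROC::roc(response = label, predictor = score,
                                        direction = "<", quiet = TRUE)))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("the Hanley-McNeil test calls a clearly informative AUC significant", {
  set.seed(33)
  score <- c(rnorm(100, 1), rnorm(100, 0))
  label <- rep(c(TRUE, FALSE), each = 100)
  r <- aucMannWhitney(score, label)
  expect_gt(auc(r), 0.5)
  expect_lt(r@p_vs_half, 0.05)
  ## and a null AUC non-significant
  r0 <- aucMannWhitney(rnorm(200), rep(c(TRUE, FALSE), 100))
  expect_gt(r0@p_vs_half, 0.05)
})

test_that("accuracy tables equal a brute-force recount over case scores", {
  cfg <- small_config(seed = 41, n_exp = 60)
  sim <- simulateClaimSet(cfg)
  model <- calibrateNormModel(sim$norm)
  scores <- scoreClaimSet(sim$experimental, model)
  tab <- accuracyTable(scores, sim$experimental, mode = "matched")
  ## independent recount straight from cells and labels
  cells <- residualCells(scores)
  ded <- deductions(sim$experimental)
  recount <- sapply(split(cells, cells$case_id), function(cc) {
    any(cc$z > 2 & ded[cbind(cc$item_id, cc$case_id)])
  })
  info <- caseInfo(sim$experimental)
  yr <- info$year[match(names(recount), info$case_id)]
  expect_equal(sum(evalStrata(tab)$correct), sum(recount))
  for (y in unique(yr))
    expect_equal(evalStrata(tab)$correct[evalStrata(tab)$stratum == y],
                 sum(recount[yr == y]))
  ## rates recomputed two ways agree exactly
  s <- evalStrata(tab)
  expect_equal(s$rate, s$correct / (s$correct + s$incorrect))
  expect_equal(pooledRate(tab), sum(s$correct) / sum(s$total))
})

test_that("category tables count agreement of flags and deductions per category", {
  cfg <- small_config(seed = 42, n_exp = 40)
  sim <- simulateClaimSet(cfg)
  model <- calibrateNormModel(sim$norm)
  scores <- scoreClaimSet(sim$experimental, model)
  tabs <- categoryTable(scores, sim$experimental)
  expect_named(tabs, c("drug", "material", "examination"))
  ## every scored case counts in every category's denominator
  n_scored <- sum(caseSummary(scores)$status == "scored")
  for (tab in tabs)
    expect_equal(sum(evalStrata(tab)$total), n_scored)
  ## a category with no deductions and no flags anywhere is all-correct
  ded <- deductions(sim$experimental)
  schema <- feeSchema(sim$experimental)
  cells <- residualCells(scores)
  for (cat in names(tabs)) {
    items <- schema$item_id[schema$category == cat]
    if (!any(ded[items, ]) && !any(cells$flagged[cells$item_id %in% items]))
      expect_equal(pooledRate(tabs[[cat]]), 1)
  }
})

test_that("category-level ROC uses the category max Z against any-deduction labels", {
  cfg <- small_config(seed = 43, n_exp = 60, upcode_items = 2)
  sim <- simulateClaimSet(cfg)
  model <- calibrateNormModel(sim$norm)
  scores <- scoreClaimSet(sim$experimental, model)
  roc <- categoryROC(scores, sim$experimental, by_year = FALSE)
  expect_true(all(roc$auc >= 0 & roc$auc <= 1))
  ## recompute one stratum by hand
  if (nrow(roc)) {
    cat <- roc$category[1]
    items <- feeSchema(sim$experimental)$item_id[
      feeSchema(sim$experimental)$category == cat]
    cells <- residualCells(scores)
    ded <- deductions(sim$experimental)
    agg <- lapply(split(cells[cells$item_id %in% items, ],
                        cells$case_id[cells$item_id %in% items]),
                  function(cc) c(max(cc$z),
                                 any(ded[items, cc$case_id[1]])))
    sc <- sapply(agg, `[`, 1); lab <- sapply(agg, `[`, 2) == 1
    expect_equal(roc$auc[1], auc(aucMannWhitney(sc, lab)))
  }
})
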