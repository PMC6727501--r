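test_that("residualZ is the standardized residual with the sign of O - E", {
  expect_equal(residualZ(0.5, 0.5), 0)
  expect_equal(residualZ(0.9, 0.1), 0.8 / 0.3)
  expect_equal(residualZ(0.1, 0.9), -0.8 / 0.3)   # antisymmetric
  expect_error(residualZ(0.5, 1), "inside")
})

test_that("outfit mean-square averages squared residuals", {
  expect_equal(outfitMNSQ(c(0, 0, 0)), 0)
  expect_equal(outfitMNSQ(c(1, -1, 2)), 2)
  expect_equal(outfitMNSQ(3.62), 13.1044)
  expect_error(outfitMNSQ(numeric(0)), "at least one")
})

test_that("flagItems applies a strict threshold on the chosen side", {
  cells <- data.frame(item_id = c("a", "b", "c"), z = c(3.62, 2.0, -3.0))
  expect_equal(flagItems(cells), "a")                      # strict: 2.0 not flagged
  expect_equal(flagItems(cells, side = "two"), c("a", "c"))
  expect_equal(flagItems(cells, threshold = 4), character(0))
})

test_that("a self-consistent case scores zero residuals everywhere", {
  ## fees placed exactly at E(theta, delta) on the normalised scale
  sim <- simulateClaimSet(small_config(seed = 9))
  model <- calibrateNormModel(sim$norm)
  it <- itemTable(model)
  theta <- 0.3
  O <- expectedScore(theta, it$delta)
  ## invert the normalisation exactly: these O all lie inside (eps, 1-eps)
  fee <- setNames(it$min + O * (it$max - it$min), it$item_id)
  sc <- scoreCase(fee, model, tol = 1e-10)
  expect_equal(sc$status, "scored")
  expect_lt(max(abs(sc$cells$z)), 1e-4)
  expect_lt(sc$outfit_mnsq, 1e-8)
  expect_length(sc$flagged_items, 0)
  expect_equal(sc$ability$theta, theta, tolerance = 1e-4)
})

test_that("inflating one item's fee drives its Z above the threshold", {
  ## a low-fee case whose hardest (smallest-fee) item is inflated far above
  ## the norm maximum: the residual on that item dominates the case
  sim <- simulateClaimSet(small_config(seed = 10, upcode_rate = 0))
  model <- calibrateNormModel(sim$norm)
  it <- itemTable(model)
  theta <- -1.5
  fee <- setNames(it$min + expectedScore(theta, it$delta) * (it$max - it$min),
                  it$item_id)
  target <- it$item_id[which.max(it$delta)]
  base <- scoreCase(fee, model)
  fee[target] <- 50 * it$max[it$item_id == target]
  inflated <- scoreCase(fee, model)
  zt <- inflated$cells$z[inflated$cells$item_id == target]
  expect_equal(max(inflated$cells$z), zt)        # the case maximum
  expect_gt(zt, 2)
  expect_gt(zt, base$cells$z[base$cells$item_id == target])
  expect_true(target %in% inflated$flagged_items)
  expect_true(inflated$case_flagged)
})

test_that("cases with no observed modelled items are unscorable, not errors", {
  sim <- simulateClaimSet(small_config(seed = 12))
  model <- calibrateNormModel(sim$norm)
  fee <- rep(NA_real_, nrow(fees(sim$norm)))
  names(fee) <- rownames(fees(sim$norm))
  sc <- scoreCase(fee, model)
  expect_equal(sc$status, "unscorable")
  expect_false(sc$case_flagged)
})

test_that("scoring a claim set yields one residual cell per observed fee", {
  cfg <- simConfig(n_exp = 194, n_norm = 120, p_miss = 0, seed = 4)
  sim <- simulateClaimSet(cfg)
  model <- calibrateNormModel(sim$norm)
  scores <- scoreClaimSet(sim$experimental, model)
  ## complete 194 x 17 data: every cell scored
  expect_equal(nrow(residualCells(scores)), 194L * 17L)
  expect_equal(nrow(caseSummary(scores)), 194L)
  expect_true(validObject(scores))
  ## cells equal the observed-fee count in general (missingness conservation)
  cfg2 <- small_config(seed = 13)
  sim2 <- simulateClaimSet(cfg2)
  model2 <- calibrateNormModel(sim2$norm)
  scores2 <- scoreClaimSet(sim2$experimental, model2)
  modelled <- fees(sim2$experimental)[itemTable(model2)$item_id, , drop = FALSE]
  expect_equal(nrow(residualCells(scores2)), sum(!is.na(modelled)))
})

test_that("unknown DRGs are skipped while the rest score; empty sets stay empty", {
  sim <- simulateClaimSet(small_config(seed = 14))
  model <- calibrateNormModel(sim$norm)
  claims <- sim$experimental
  info <- caseInfo(claims)
  info$drg[1] <- "DRG999"
  mixed <- raschDRG:::claimSet(fees(claims), info, feeSchema(claims),
                               role = "experimental",
                               deducted = deductions(claims))
  scores <- scoreClaimSet(mixed, model)
  expect_equal(skippedCases(scores)$case_id, info$case_id[1])
  expect_equal(nrow(caseSummary(scores)), nrow(info) - 1L)

  empty <- raschDRG:::claimSet(
    matrix(numeric(0), nrow(fees(claims)), 0),
    data.frame(case_id = character(), drg = character(), year = integer()),
    feeSchema(claims), role = "experimental")
  scores0 <- scoreClaimSet(empty, model)
  expect_equal(nrow(caseSummary(scores0)), 0L)
  expect_equal(nrow(residualCells(scores0)), 0L)
})

test_that("residuals conserve the score condition at the fitted ability", {
  sim <- simulateClaimSet(small_config(seed = 15))
  model <- calibrateNormModel(sim$norm)
  scores <- scoreClaimSet(sim$experimental, model)
  cells <- residualCells(scores)
  for (cid in unique(cells$case_id)[1:10]) {
    cc <- cells[cells$case_id == cid, ]
    expect_lt(abs(sum(cc$O - cc$E)), 1e-3)
    expect_lt(abs(sum(cc$z * sqrt(cc$var))), 1e-3)
  }
})

test_that("injected up-coding strictly raises the injected item's Z (paired)", {
  cfg <- small_config(seed = 16, upcode_rate = 1, upcode_items = 1)
  base_cfg <- small_config(seed = 16, upcode_rate = 0)
  sim <- simulateClaimSet(cfg)
  base <- simulateClaimSet(base_cfg)
  model <- calibrateNormModel(base$norm)
  with_inj <- scoreClaimSet(sim$experimental, model)
  without <- scoreClaimSet(base$experimental, model)
  ci <- residualCells(with_inj); cb <- residualCells(without)
  up <- sim$truth$upcoded
  expect_gt(nrow(up), 0)
  for (r in seq_len(nrow(up))) {
    zi <- ci$z[ci$case_id == up$case_id[r] & ci$item_id == up$item_id[r]]
    zb <- cb$z[cb$case_id == up$case_id[r] & cb$item_id == up$item_id[r]]
    if (up$x_after[r] > up$x_before[r]) expect_gt(zi, zb)
  }
})
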