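test_that("expectedScore follows the logistic form and its monotonicities", {
  expect_equal(expectedScore(0, 0), 0.5)
  expect_equal(expectedScore(1, 0), exp(1) / (1 + exp(1)))
  ## worked dashboard case: low-ability case on a moderately easy item
  expect_equal(expectedScore(-3.74, -0.53), 0.03879113, tolerance = 1e-6)
  th <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(expectedScore(th, 0)) > 0))     # increasing in theta
  expect_true(all(diff(expectedScore(0, th)) < 0))     # decreasing in delta
  ## overflow-safe at extreme logits
  expect_equal(expectedScore(800, 0), 1)
  expect_equal(expectedScore(-800, 0), 0)
})

test_that("cellVariance is E(1-E), maximal at one quarter", {
  expect_equal(cellVariance(0.5), 0.25)
  expect_equal(cellVariance(0.1), 0.09)
  expect_equal(cellVariance(0.9), 0.09)     # symmetric
  expect_error(cellVariance(0), "inside")
  expect_error(cellVariance(1), "inside")
})

test_that("single-item ability matches the closed form theta = delta + logit(O)", {
  expect_equal(estimateAbility(c(i = 0.5), c(i = 0))$theta, 0, tolerance = 1e-6)
  est <- estimateAbility(c(i = 0.7310586), c(i = 0), tol = 1e-10)
  expect_equal(est$theta, 1, tolerance = 1e-6)
  for (O in c(0.05, 0.3, 0.5, 0.8, 0.95)) {
    for (d in c(-2, 0, 1.5)) {
      est <- estimateAbility(c(i = O), c(i = d), tol = 1e-10, max_iter = 500)
      expect_equal(est$theta, d + qlogis(O), tolerance = 1e-6)
    }
  }
})

test_that("multi-item ability solves the score condition and matches bisection", {
  deltas <- c(a = -2, b = -1, c = 0, d = 1, e = 2)
  obs <- c(a = 0.9, b = 0.8, c = 0.5, d = 0.3, e = 0.2)
  est <- estimateAbility(obs, deltas)
  expect_true(est$converged)
  oracle <- bisect_theta(obs, deltas)
  expect_equal(est$theta, oracle, tolerance = 1e-3)
  ## score-condition fixed point
  E <- expectedScore(est$theta, deltas)
  expect_lt(abs(sum(obs - E)), 1e-4 * sum(cellVariance(E)))
  ## standard error is 1/sqrt(sum of cell variances)
  expect_equal(est$se, 1 / sqrt(sum(cellVariance(E))))
})

test_that("ability estimation agrees with the bisection oracle on random instances", {
  set.seed(11)
  for (rep in 1:30) {
    k <- sample(2:10, 1)
    deltas <- setNames(rnorm(k, 0, 1.5), paste0("i", seq_len(k)))
    obs <- setNames(runif(k, 0.01, 0.99), names(deltas))
    est <- estimateAbility(obs, deltas, max_iter = 500)
    expect_equal(est$theta, bisect_theta(obs, deltas), tolerance = 1e-3)
  }
})

test_that("ability is translation-equivariant and monotone in the observations", {
  deltas <- c(a = -1, b = 0.4, c = 1.2)
  obs <- c(a = 0.7, b = 0.45, c = 0.2)
  base <- estimateAbility(obs, deltas, tol = 1e-10, max_iter = 1000)$theta
  for (const in c(-2, 0.5, 3)) {
    shifted <- estimateAbility(obs, deltas + const, tol = 1e-10,
                               max_iter = 1000)$theta
    expect_equal(shifted, base + const, tolerance = 1e-6)
  }
  ## raising any single observation never lowers the estimate
  for (j in seq_along(obs)) {
    bumped <- obs
    bumped[j] <- min(0.99, bumped[j] + 0.2)
    expect_gte(estimateAbility(bumped, deltas, tol = 1e-10,
                               max_iter = 1000)$theta, base - 1e-8)
  }
})

test_that("ability estimation rejects empty or boundary input and flags non-convergence", {
  expect_error(estimateAbility(numeric(0), c(i = 0)), "at least one")
  expect_error(estimateAbility(c(i = 1), c(i = 0)), "inside")
  expect_error(estimateAbility(c(i = 0.5, j = 0.5), c(i = 0)), "j")
  est <- estimateAbility(c(i = 0.995), c(i = 0), max_iter = 2)
  expect_false(est$converged)
})

test_that("calibration centres difficulties and resolves mirror-image items", {
  set.seed(21)
  O1 <- runif(40, 0.15, 0.85)
  x <- cbind(a = O1, b = 1 - O1)      # mirror-image score columns
  fit <- calibrateItems(x)
  expect_true(fit$converged)
  expect_equal(mean(fit$delta), 0, tolerance = 1e-10)
  expect_equal(fit$delta[["a"]], -fit$delta[["b"]], tolerance = 1e-4)
  ## indistinguishable items land at equal difficulty
  y <- cbind(a = O1, b = O1)
  fit2 <- calibrateItems(y)
  expect_equal(unname(fit2$delta), c(0, 0), tolerance = 1e-8)
})

test_that("calibration is invariant to case order and validates its input", {
  set.seed(22)
  cfg <- small_config(seed = 22)
  sim <- simulateClaimSet(cfg)
  b <- computeBounds(sim$norm, cfg$drg)
  x <- t(fees(sim$norm))
  for (j in seq_len(ncol(x))) {
    o <- !is.na(x[, j])
    x[o, j] <- normalizeFee(x[o, j], b$min[j], b$max[j])
  }
  fit <- calibrateItems(x)
  perm <- sample(nrow(x))
  fit_perm <- calibrateItems(x[perm, ])
  expect_equal(fit_perm$delta, fit$delta, tolerance = 1e-3)

  expect_error(calibrateItems(x[1, , drop = FALSE]), "2 cases")
  expect_error(calibrateItems(x[, 1, drop = FALSE]), "2 items")
  bad <- x
  bad[, 1] <- 0.4                     # zero-variance item
  expect_error(calibrateItems(bad), "zero-variance")
  disc <- matrix(runif(12, 0.2, 0.8), 4, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  disc[1:2, 3] <- NA; disc[3:4, 1:2] <- NA   # item c shares no case with a, b
  expect_error(calibrateItems(disc), "disconnected")
})

test_that("calibrateNormModel produces a valid, convergent model from claims", {
  sim <- simulateClaimSet(small_config(seed = 5))
  model <- calibrateNormModel(sim$norm)
  expect_s4_class(model, "NormModel")
  expect_true(validObject(model))
  expect_true(calibrationInfo(model)$converged)
  expect_equal(mean(difficulties(model)), 0, tolerance = 1e-9)
  expect_true(all(itemTable(model)$se > 0))
  ## degenerate and unobserved items are excluded, never calibrated
  expect_true(all(!itemTable(model)$item_id %in% excludedItems(model)$item_id))
})
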