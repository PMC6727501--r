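## Shared fixtures: everything is generated in code at test time.

## A tiny 4-item schema for hand-checkable cases.
tiny_schema <- function() {
  feeItemSchema(data.frame(
    item_id = c("D01", "D02", "M01", "E01"),
    label = c("drug A", "drug B", "material", "examination"),
    category = c("drug", "drug", "material", "examination")))
}

## Write a long-format claims CSV from a data.frame of rows.
write_claims_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

## Small, fast simulation config for unit tests.
small_config <- function(seed = 7, ...) {
  args <- utils::modifyList(list(n_norm = 60L, n_exp = 30L, n_items = 8L,
                                 seed = seed), list(...))
  do.call(simConfig, args)
}

## Independent bisection oracle for the ability score equation
## sum_i (O_i - E_i(theta)) = 0; E is monotone in theta so the root is
## bracketed and unique.
bisect_theta <- function(obs, deltas, lo = -30, hi = 30, tol = 1e-9) {
  f <- function(th) sum(obs - plogis(th - deltas))
  stopifnot(f(lo) > 0 || abs(f(lo)) < tol, f(hi) < 0 || abs(f(hi)) < tol)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## O(n^2) pair-counting oracle for the Mann-Whitney AUC.
auc_pair_count <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
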