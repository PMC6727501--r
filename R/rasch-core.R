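#' Expected score under the continuous-response Rasch model
#'
#' The model-expected normalised fee for a case of ability \code{theta} on an
#' item of difficulty \code{delta}:
#' \deqn{E = \frac{e^{\theta-\delta}}{1+e^{\theta-\delta}}.}
#' Strictly increasing in theta, decreasing in delta; computed overflow-safely
#' via the logistic CDF.
#'
#' @param theta ability in logits.
#' @param delta item difficulty in logits.
#' @return expected score(s) in (0, 1); inputs recycle as usual.
#' @examples
#' expectedScore(0, 0)    # 0.5
#' expectedScore(1, 0)    # e/(1+e)
#' @export
expectedScore <- function(theta, delta) {
  stopifnot(all(is.finite(theta)), all(is.finite(delta)))
  stats::plogis(theta - delta)
}

#' Model variance of a cell
#'
#' Bernoulli-form variance \code{E(1-E)} of a normalised-fee cell, the
#' denominator of the Newton ability update and of the standardized residual.
#' Maximal (0.25) at E = 0.5.
#'
#' @param E expected score(s), strictly inside (0, 1).
#' @return variance(s) \code{E * (1 - E)}.
#' @export
cellVariance <- function(E) {
  if (any(E <= 0 | E >= 1))
    stop("expected scores must lie strictly inside (0, 1)")
  E * (1 - E)
}

#' Estimate a case's ability from its observed items
#'
#' Maximum-likelihood ability for one case given known item difficulties,
#' using only the items the case actually has (non-missing) normalised fees
#' on -- zero-fee items contribute nothing. The estimate solves the score
#' condition \eqn{\sum_i (O_i - E_i(\theta)) = 0} by Newton-Raphson:
#' \deqn{\theta \leftarrow \theta + \frac{\sum_i (O_i - E_i)}{\sum_i E_i(1-E_i)},}
#' the multi-item form of the single-cell update (with one item the two
#' coincide and the closed form is \eqn{\theta = \delta + \mathrm{logit}(O)}).
#' Each step is capped at \code{step_cap} logits to prevent divergence from
#' poor starts.
#'
#' @param obs named numeric vector of observed normalised scores in (0, 1);
#'   names are item ids matched against \code{deltas} (unnamed vectors are
#'   matched positionally).
#' @param deltas named numeric vector of item difficulties (logits).
#' @param start starting value, default 0 logits.
#' @param tol convergence tolerance on the Newton step (logits), default 1e-4.
#' @param max_iter maximum iterations, default 100.
#' @param step_cap maximum absolute step per iteration (logits), default 1.
#' @return list with \code{theta} (logits), \code{se} (= \eqn{1/\sqrt{\sum_i
#'   Var_i}}), \code{n_items_used}, \code{converged}, \code{iterations}.
#'   Non-convergence returns \code{converged = FALSE} rather than an error.
#' @examples
#' estimateAbility(c(D01 = 0.5), c(D01 = 0))$theta          # 0
#' estimateAbility(c(D01 = 0.7310586), c(D01 = 0))$theta    # ~1
#' @export
estimateAbility <- function(obs, deltas, start = 0, tol = 1e-4,
                            max_iter = 100L, step_cap = 1) {
  if (length(obs) == 0L) stop("at least one observed item is required")
  if (any(obs <= 0 | obs >= 1))
    stop("observed scores must lie strictly inside (0, 1)")
  if (!is.null(names(obs)) && !is.null(names(deltas))) {
    miss <- setdiff(names(obs), names(deltas))
    if (length(miss))
      stop("no difficulty for item(s): ", paste(miss, collapse = ", "))
    d <- deltas[names(obs)]
  } else {
    if (length(obs) != length(deltas))
      stop("unnamed obs and deltas must have equal length")
    d <- deltas
  }
  theta <- start
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- stats::plogis(theta - d)
    V <- E * (1 - E)
    step <- sum(obs - E) / sum(V)
    step <- max(min(step, step_cap), -step_cap)
    theta <- theta + step
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  E <- stats::plogis(theta - d)
  list(theta = theta,
       se = 1 / sqrt(sum(E * (1 - E))),
       n_items_used = length(obs),
       converged = converged,
       iterations = it)
}

## Bipartite connectivity of the observation pattern: every item must share a
## case, directly or transitively, with every other item, or the difficulty
## scale cannot be linked. mask is a logical cases x items matrix.
.check_connected <- function(mask) {
  k <- ncol(mask)
  reached <- rep(FALSE, k)
  reached[1L] <- TRUE
  repeat {
    cases <- rowSums(mask[, reached, drop = FALSE]) > 0
    newly <- colSums(mask[cases, , drop = FALSE]) > 0 & !reached
    if (!any(newly)) break
    reached <- reached | newly
  }
  if (!all(reached))
    stop("item(s) disconnected from the rest of the design: ",
         paste(colnames(mask)[!reached], collapse = ", "))
  invisible(TRUE)
}

#' Calibrate item difficulties on a norm matrix
#'
#' Joint maximum-likelihood (JMLE) calibration of the continuous-response
#' Rasch model on a cases x items matrix of normalised scores (NA = missing).
#' Each sweep (a) re-estimates every case ability by Newton-Raphson given the
#' current difficulties, (b) applies one mirrored Newton step per item,
#' \eqn{\delta_i \leftarrow \delta_i - \sum_n (O_{ni}-E_{ni}) / \sum_n
#' Var_{ni}} over the cases observing the item, and (c) re-centres the
#' difficulties to mean zero (the identifiability constraint). Sweeps stop
#' when the largest parameter change falls below \code{tol}. Deterministic
#' given the input; permutation of case order changes nothing beyond
#' tolerance.
#'
#' @param x numeric matrix, cases in rows, items in columns, entries
#'   normalised scores in (0, 1) or NA for missing. Column names are item
#'   ids.
#' @param tol convergence tolerance on the largest parameter update, default
#'   1e-4.
#' @param max_iter maximum sweeps, default 100.
#' @param step_cap maximum absolute Newton step (logits), default 1.
#' @return list with \code{delta} (named, mean-centred), \code{se} (=
#'   \eqn{1/\sqrt{\sum_n Var_{ni}}}), \code{n_obs} per item, \code{theta}
#'   (per-case abilities at exit), \code{iterations}, \code{max_change},
#'   \code{converged}. Non-convergence warns and returns the last state.
#' @seealso [calibrateNormModel()] for the ClaimSet-level wrapper.
#' @export
calibrateItems <- function(x, tol = 1e-4, max_iter = 100L, step_cap = 1) {
  stopifnot(is.matrix(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("calibration needs at least 2 cases")
  if (k < 2L) stop("calibration needs at least 2 items")
  obs <- !is.na(x)
  if (any(x[obs] <= 0 | x[obs] >= 1))
    stop("normalised scores must lie strictly inside (0, 1)")
  n_obs <- colSums(obs)
  if (any(n_obs < 2L))
    stop("item(s) observed by fewer than 2 cases: ",
         paste(colnames(x)[n_obs < 2L], collapse = ", "))
  if (any(rowSums(obs) < 1L))
    stop("case(s) with no observed items: ",
         paste(which(rowSums(obs) < 1L), collapse = ", "))
  v <- apply(x, 2, function(col) stats::var(col[!is.na(col)]))
  if (any(v == 0))
    stop("zero-variance item(s), exclude before calibration: ",
         paste(colnames(x)[v == 0], collapse = ", "))
  .check_connected(obs)

  M <- obs * 1         # numeric mask
  xz <- x; xz[!obs] <- 0
  theta <- rep(0, n)
  delta <- rep(0, k)
  max_change <- Inf
  sweep <- 0L
  while (sweep < max_iter) {
    sweep <- sweep + 1L
    delta_old <- delta; theta_old <- theta
    ## (a) inner Newton on all abilities, vectorised across cases
    for (i in seq_len(max_iter)) {
      E <- stats::plogis(outer(theta, delta, "-"))
      V <- E * (1 - E)
      step <- rowSums(M * (xz - E)) / rowSums(M * V)
      step <- pmax(pmin(step, step_cap), -step_cap)
      theta <- theta + step
      if (max(abs(step)) < tol) break
    }
    ## (b) one mirrored Newton step per item
    E <- stats::plogis(outer(theta, delta, "-"))
    V <- E * (1 - E)
    dstep <- colSums(M * (xz - E)) / colSums(M * V)
    dstep <- pmax(pmin(dstep, step_cap), -step_cap)
    delta <- delta - dstep
    ## (c) identifiability: centre difficulties
    delta <- delta - mean(delta)
    max_change <- max(abs(delta - delta_old), abs(theta - theta_old))
    if (max_change < tol) break
  }
  converged <- max_change < tol
  if (!converged)
    warning("calibration did not converge in ", max_iter,
            " sweeps (max change ", signif(max_change, 3), ")")
  E <- stats::plogis(outer(theta, delta, "-"))
  V <- E * (1 - E)
  list(delta = stats::setNames(delta, colnames(x)),
       se = stats::setNames(1 / sqrt(colSums(M * V)), colnames(x)),
       n_obs = stats::setNames(as.integer(n_obs), colnames(x)),
       theta = theta,
       iterations = sweep,
       max_change = max_change,
       converged = converged)
}

#' Calibrate a norm model for one DRG from claims
#'
#' ClaimSet-level calibration pipeline: subset the norm group to one DRG,
#' derive min--max normalisation bounds ([computeBounds()]), drop unobserved
#' and degenerate items, normalise the observed fees ([normalizeFee()]) and
#' run the JMLE calibration ([calibrateItems()]). The result packages
#' difficulties, standard errors, bounds and the calibration report as a
#' [NormModel-class] ready for [scoreClaimSet()].
#'
#' @param norm a norm-role [ClaimSet-class].
#' @param drg DRG code; defaults to the single DRG present.
#' @param eps boundary clamp for normalisation, default 0.005.
#' @param tol,max_iter,step_cap passed to [calibrateItems()].
#' @return a [NormModel-class].
#' @export
calibrateNormModel <- function(norm, drg = NULL, eps = 0.005, tol = 1e-4,
                               max_iter = 100L, step_cap = 1) {
  stopifnot(is(norm, "ClaimSet"))
  drgs <- unique(caseInfo(norm)$drg)
  if (is.null(drg)) {
    if (length(drgs) != 1L)
      stop("claims contain ", length(drgs), " DRGs; specify one")
    drg <- drgs
  }
  sel <- caseInfo(norm)$drg == drg
  if (sum(sel) < 2L) stop("need at least 2 norm cases for DRG ", drg)
  b <- suppressWarnings(computeBounds(norm, drg))
  schema <- feeSchema(norm)
  excluded <- data.frame(item_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  unobserved <- setdiff(schema$item_id, b$item_id)
  if (length(unobserved))
    excluded <- rbind(excluded, data.frame(item_id = unobserved,
                                           reason = "never observed"))
  if (any(b$degenerate)) {
    excluded <- rbind(excluded,
                      data.frame(item_id = b$item_id[b$degenerate],
                                 reason = "degenerate (all fees equal)"))
    b <- b[!b$degenerate, , drop = FALSE]
  }
  if (nrow(b) < 2L)
    stop("fewer than 2 usable items for DRG ", drg)
  fee <- fees(norm)[b$item_id, sel, drop = FALSE]
  x <- t(fee)     # cases x items for calibration
  for (j in seq_len(ncol(x))) {
    o <- !is.na(x[, j])
    x[o, j] <- normalizeFee(x[o, j], b$min[j], b$max[j], eps = eps)
  }
  fit <- calibrateItems(x, tol = tol, max_iter = max_iter,
                        step_cap = step_cap)
  items <- data.frame(item_id = b$item_id,
                      delta = unname(fit$delta),
                      se = unname(fit$se),
                      n_obs = unname(fit$n_obs),
                      min = b$min, max = b$max,
                      row.names = NULL, stringsAsFactors = FALSE)
  new("NormModel", drg = drg, items = items, excluded = excluded,
      calibration = list(eps = eps, tol = tol, max_iter = as.integer(max_iter),
                         step_cap = step_cap,
                         iterations = fit$iterations,
                         max_change = fit$max_change,
                         converged = fit$converged, centered = TRUE),
      schema = schema)
}
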