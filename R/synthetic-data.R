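#' Configuration for the synthetic claims generator
#'
#' Defines the study conditions the generator emulates: a norm group of 300
#' clean cases and an experimental group of 194 audited cases on a 17-item
#' fee schema within one DRG, with item difficulties and case abilities drawn
#' from standard normals, Beta-distributed normalised fees around the model
#' expectation, 10\% missing cells, and one up-coded item injected per
#' experimental case at a shift of 0.4 on the normalised scale.
#'
#' @param n_norm norm-group cases, default 300.
#' @param n_exp experimental-group cases, default 194.
#' @param n_items fee items, default 17 (uses [defaultFeeSchema()] when 17,
#'   a generic generated schema otherwise).
#' @param sigma_delta,sigma_theta SDs of the difficulty and ability normals,
#'   default 1 logit each.
#' @param precision Beta precision m: a cell's normalised fee is drawn from
#'   Beta(E m, (1-E) m) with mean E and variance E(1-E)/(1+m); default 9.
#' @param p_miss per-cell missing probability, default 0.1.
#' @param upcode_rate fraction of experimental cases up-coded, default 1
#'   (every audited case has at least one deducted item).
#' @param upcode_items items up-coded per selected case, default 1.
#' @param upcode_shift shift added on the normalised scale, in (0, 1],
#'   default 0.4.
#' @param fee_lo,fee_span currency mapping: fee = lo + x * span per item;
#'   scalars or per-item vectors. Defaults 100 and 2000.
#' @param drg DRG code stamped on the generated cases, default "DRG001".
#' @param eps upper clamp for up-coded normalised values, default 0.005.
#' @param seed master seed; four independent substreams (parameters, noise,
#'   missingness, injection) are derived from it so that toggling injection
#'   does not perturb the base data.
#' @return validated list of class \code{"SimConfig"}.
#' @seealso [simulateClaimSet()]
#' @export
simConfig <- function(n_norm = 300L, n_exp = 194L, n_items = 17L,
                      sigma_delta = 1, sigma_theta = 1, precision = 9,
                      p_miss = 0.1, upcode_rate = 1, upcode_items = 1L,
                      upcode_shift = 0.4, fee_lo = 100, fee_span = 2000,
                      drg = "DRG001", eps = 0.005, seed = 1L) {
  cfg <- list(n_norm = as.integer(n_norm), n_exp = as.integer(n_exp),
              n_items = as.integer(n_items), sigma_delta = sigma_delta,
              sigma_theta = sigma_theta, precision = precision,
              p_miss = p_miss, upcode_rate = upcode_rate,
              upcode_items = as.integer(upcode_items),
              upcode_shift = upcode_shift,
              fee_lo = rep_len(fee_lo, n_items),
              fee_span = rep_len(fee_span, n_items),
              drg = drg, eps = eps, seed = as.integer(seed))
  bad <- character()
  if (cfg$n_norm < 2L) bad <- c(bad, "n_norm must be >= 2")
  if (cfg$n_exp < 2L) bad <- c(bad, "n_exp must be >= 2")
  if (cfg$n_items < 2L) bad <- c(bad, "n_items must be >= 2")
  if (cfg$precision <= 0) bad <- c(bad, "precision must be > 0")
  if (cfg$p_miss < 0 || cfg$p_miss > 1) bad <- c(bad, "p_miss must lie in [0, 1]")
  if (cfg$upcode_rate < 0 || cfg$upcode_rate > 1)
    bad <- c(bad, "upcode_rate must lie in [0, 1]")
  if (cfg$upcode_items < 1L) bad <- c(bad, "upcode_items must be >= 1")
  if (cfg$upcode_shift <= 0 || cfg$upcode_shift > 1)
    bad <- c(bad, "upcode_shift must lie in (0, 1]")
  if (any(cfg$fee_span <= 0)) bad <- c(bad, "fee_span must be positive")
  if (any(cfg$fee_lo <= 0)) bad <- c(bad, "fee_lo must be positive")
  if (length(bad)) stop("invalid SimConfig: ", paste(bad, collapse = "; "))
  cfg$schema <- if (cfg$n_items == 17L) defaultFeeSchema() else
    feeItemSchema(data.frame(
      item_id = sprintf("I%02d", seq_len(cfg$n_items)),
      label = sprintf("fee item %d", seq_len(cfg$n_items)),
      category = rep_len(c("drug", "material", "examination", "other"),
                         cfg$n_items)))
  class(cfg) <- "SimConfig"
  cfg
}

## Substream seeds: one per purpose, derived once from the master seed.
.sim_streams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, 4),
                  c("params", "noise", "missing", "injection"))
}

## One group's normalised-value matrix (cases x items) with Beta noise.
.sim_group <- function(theta, delta, m) {
  E <- stats::plogis(outer(theta, delta, "-"))
  x <- matrix(stats::rbeta(length(E), E * m, (1 - E) * m),
              nrow(E), ncol(E))
  ## keep strictly inside (0,1) so every fee is positive and finite
  pmin(pmax(x, 1e-9), 1 - 1e-9)
}

#' Generate a synthetic DRG claim set with known truth
#'
#' Draws item difficulties and case abilities, simulates each cell's
#' normalised fee from a Beta distribution with mean equal to the Rasch
#' expectation \eqn{E(\theta_n, \delta_i)} and precision \code{m}
#' (variance \eqn{E(1-E)/(1+m)}), knocks out cells as missing, maps
#' normalised values to currency (fee = lo + x span), and -- unless
#' \code{upcode_rate} is 0 -- injects up-coding into the experimental group
#' via [injectUpcoding()], exporting the injected cells as the
#' \code{deducted} audit labels.
#'
#' Cases are split evenly across years 2015/2016. Fully reproducible from
#' the config seed; the four randomness sources (parameters, noise,
#' missingness, injection) use independent substreams.
#'
#' @param config a [simConfig()] list.
#' @return list with \code{norm} (ClaimSet, role "norm"), \code{experimental}
#'   (ClaimSet, role "experimental", with a \code{deducted} assay), and
#'   \code{truth}: delta, theta_norm, theta_exp, the pre-injection normalised
#'   matrices x_norm/x_exp, missing masks, and the up-coded (case, item)
#'   table.
#' @export
simulateClaimSet <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  streams <- .sim_streams(config$seed)
  k <- config$n_items
  items <- config$schema$item_id

  set.seed(streams["params"])
  delta <- stats::rnorm(k, 0, config$sigma_delta)
  delta <- delta - mean(delta)               # truth on the identified scale
  names(delta) <- items
  theta_norm <- stats::rnorm(config$n_norm, 0, config$sigma_theta)
  theta_exp <- stats::rnorm(config$n_exp, 0, config$sigma_theta)

  set.seed(streams["noise"])
  x_norm <- .sim_group(theta_norm, delta, config$precision)
  x_exp <- .sim_group(theta_exp, delta, config$precision)

  set.seed(streams["missing"])
  miss_norm <- matrix(stats::runif(length(x_norm)) < config$p_miss,
                      nrow(x_norm), ncol(x_norm))
  miss_exp <- matrix(stats::runif(length(x_exp)) < config$p_miss,
                     nrow(x_exp), ncol(x_exp))
  if (all(miss_norm) || all(miss_exp))
    stop("no scorable cases: every cell is missing (p_miss too high)")

  to_fees <- function(x, miss) {
    fee <- t(sweep(sweep(x, 2, config$fee_span, "*"), 2, config$fee_lo, "+"))
    fee[t(miss)] <- NA_real_
    fee                                       # items x cases
  }
  years <- function(n) rep(c(2015L, 2016L), length.out = n)
  norm_info <- data.frame(case_id = sprintf("N%04d", seq_len(config$n_norm)),
                          drg = config$drg, year = years(config$n_norm))
  exp_info <- data.frame(case_id = sprintf("E%04d", seq_len(config$n_exp)),
                         drg = config$drg, year = years(config$n_exp))
  norm <- claimSet(to_fees(x_norm, miss_norm), norm_info, config$schema,
                   role = "norm")
  experimental <- claimSet(
    to_fees(x_exp, miss_exp), exp_info, config$schema,
    role = "experimental",
    deducted = matrix(FALSE, k, config$n_exp))
  truth <- list(delta = delta, theta_norm = theta_norm,
                theta_exp = theta_exp, x_norm = x_norm, x_exp = x_exp,
                miss_norm = miss_norm, miss_exp = miss_exp,
                upcoded = data.frame(case_id = character(),
                                     item_id = character(),
                                     x_before = numeric(),
                                     x_after = numeric(),
                                     stringsAsFactors = FALSE),
                streams = streams, config = config)
  if (config$upcode_rate > 0) {
    inj <- injectUpcoding(experimental, truth, config)
    experimental <- inj$claims
    truth <- inj$truth
  }
  list(norm = norm, experimental = experimental, truth = truth)
}

#' Inject up-coding into an experimental claim set
#'
#' For a fraction \code{upcode_rate} of experimental cases, raises
#' \code{upcode_items} randomly chosen observed items on the normalised
#' scale, \eqn{x' = \min(1-\epsilon, x + \Delta)}, maps the shifted value
#' back to currency, and records the cell in the truth's up-coded table and
#' in the \code{deducted} assay (the simulated audit label). Selection draws
#' on the dedicated injection substream, so the base data are identical with
#' and without injection.
#'
#' @param claims experimental-role [ClaimSet-class] from
#'   [simulateClaimSet()].
#' @param truth the matching truth list.
#' @param config the [simConfig()] used to generate them.
#' @return list(claims, truth), updated.
#' @export
injectUpcoding <- function(claims, truth, config) {
  stopifnot(is(claims, "ClaimSet"), claimRole(claims) == "experimental")
  if (config$upcode_shift <= 0) stop("upcode_shift must be positive")
  set.seed(truth$streams["injection"])
  fee <- fees(claims)
  ded <- deductions(claims)
  if (is.null(ded)) ded <- matrix(FALSE, nrow(fee), ncol(fee),
                                  dimnames = dimnames(fee))
  n_exp <- ncol(fee)
  n_up <- round(config$upcode_rate * n_exp)
  sel_cases <- sort(sample.int(n_exp, n_up))
  rows <- list()
  for (j in sel_cases) {
    observed <- which(!is.na(fee[, j]))
    if (!length(observed)) next
    pick <- observed[sample.int(length(observed),
                                min(config$upcode_items, length(observed)))]
    for (i in pick) {
      x0 <- (fee[i, j] - config$fee_lo[i]) / config$fee_span[i]
      x1 <- min(1 - config$eps, x0 + config$upcode_shift)
      fee[i, j] <- config$fee_lo[i] + x1 * config$fee_span[i]
      ded[i, j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = colnames(fee)[j], item_id = rownames(fee)[i],
        x_before = x0, x_after = x1, stringsAsFactors = FALSE)
    }
  }
  truth$upcoded <- rbind(truth$upcoded, do.call(rbind, rows))
  info <- caseInfo(claims)
  out <- claimSet(fee, info, feeSchema(claims), role = "experimental",
                  deducted = ded)
  list(claims = out, truth = truth)
}

#' Write the simulation truth to CSV
#'
#' Two-part plain-text export: the up-coded cell table (case_id, item_id,
#' x_before, x_after) to \code{file}, and the true item difficulties to
#' \code{delta_file} when given.
#'
#' @param truth truth list from [simulateClaimSet()].
#' @param file path for the up-coded cell table.
#' @param delta_file optional path for item_id, delta.
#' @return \code{file}, invisibly.
#' @export
writeTruth <- function(truth, file, delta_file = NULL) {
  utils::write.csv(truth$upcoded, file, row.names = FALSE, quote = FALSE)
  if (!is.null(delta_file))
    utils::write.csv(data.frame(item_id = names(truth$delta),
                                delta = unname(truth$delta)),
                     delta_file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
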