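#' Default 17-item fee schema
#'
#' The fee-item schema used when none is supplied: 17 inpatient fee items in
#' the categories drug, material, examination and other (the latter covering
#' room, nursing, psychiatry and similar per-case fees). Item codes are
#' generic; real deployments substitute their own schema with
#' [feeItemSchema()].
#'
#' @return data.frame with columns item_id, label, category.
#' @examples
#' defaultFeeSchema()
#' @export
defaultFeeSchema <- function() {
  feeItemSchema(data.frame(
    item_id = c("D01", "D02", "D03", "D04",
                "M01", "M02", "M03", "M04",
                "E01", "E02", "E03", "E04",
                "O01", "O02", "O03", "O04", "O05"),
    label = c("antibiotic drug fee", "general drug fee", "injection drug fee",
              "chemotherapy drug fee",
              "surgical material fee", "dressing material fee",
              "implant material fee", "blood plasma fee",
              "laboratory examination fee", "radiology examination fee",
              "pathology examination fee", "functional examination fee",
              "accommodation (room) fee", "psychiatry fee", "nursing fee",
              "treatment fee", "anesthesia fee"),
    category = c(rep("drug", 4), rep("material", 4), rep("examination", 4),
                 rep("other", 5)),
    stringsAsFactors = FALSE))
}

#' Validate a fee-item schema
#'
#' @param schema data.frame with columns item_id, label, category; item ids
#'   must be unique and non-empty, categories one of drug, material,
#'   examination, other.
#' @return the validated schema (invisibly unchanged).
#' @export
feeItemSchema <- function(schema) {
  stopifnot(is.data.frame(schema))
  need <- c("item_id", "label", "category")
  if (!all(need %in% colnames(schema)))
    stop("schema needs columns ", paste(need, collapse = ", "))
  if (nrow(schema) == 0L) stop("schema must be non-empty")
  if (anyDuplicated(schema$item_id))
    stop("duplicate item_id in schema: ",
         paste(unique(schema$item_id[duplicated(schema$item_id)]), collapse = ", "))
  bad <- setdiff(unique(schema$category),
                 c("drug", "material", "examination", "other"))
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "))
  schema[need]
}

## Build a ClaimSet from an items x cases fee matrix. Zero fees are converted
## to NA here so that downstream code only ever sees positive or missing.
claimSet <- function(fee, case_info, schema, role,
                     deducted = NULL) {
  schema <- feeItemSchema(schema)
  stopifnot(is.matrix(fee), nrow(fee) == nrow(schema),
            ncol(fee) == nrow(case_info))
  fee[!is.na(fee) & fee == 0] <- NA_real_
  rownames(fee) <- schema$item_id
  colnames(fee) <- case_info$case_id
  assays <- list(fee = fee)
  if (!is.null(deducted)) {
    stopifnot(is.logical(deducted), dim(deducted) == dim(fee))
    dimnames(deducted) <- dimnames(fee)
    assays$deducted <- deducted
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(label = schema$label, category = schema$category,
                        row.names = schema$item_id),
    colData = DataFrame(case_id = case_info$case_id, drg = case_info$drg,
                        year = as.integer(case_info$year),
                        row.names = case_info$case_id))
  new("ClaimSet", se, role = role)
}

#' Read claims from a delimited file
#'
#' Reads long-format claims (one row per case-item) and pivots them into a
#' [ClaimSet-class]. Expected columns: \code{case_id}, \code{drg},
#' \code{year}, \code{item}, \code{fee} and optionally \code{deducted}
#' (0/1). A fee of zero, or an absent (case, item) row, is recorded as
#' missing: no expenditure on an item means the item was not claimed.
#'
#' Malformed rows are reported with their line numbers (header = line 1):
#' unknown item codes and negative fees are validation errors, not silently
#' dropped.
#'
#' @param file path to a comma-delimited UTF-8 file with a header row.
#' @param schema fee-item schema; defaults to [defaultFeeSchema()].
#' @param role \code{"norm"} or \code{"experimental"}.
#' @return a [ClaimSet-class]; empty input yields an empty ClaimSet.
#' @seealso [writeClaims()]
#' @export
readClaims <- function(file, schema = defaultFeeSchema(),
                       role = c("norm", "experimental")) {
  role <- match.arg(role)
  schema <- feeItemSchema(schema)
  empty <- claimSet(matrix(numeric(0), nrow(schema), 0),
                    data.frame(case_id = character(), drg = character(),
                               year = integer()),
                    schema, role)
  if (file.size(file) == 0L) return(empty)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("case_id", "drg", "year", "item", "fee")
  if (!all(need %in% names(df)))
    stop("claims file needs columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(empty)
  df$year <- as.integer(df$year)
  line <- seq_len(nrow(df)) + 1L   # header occupies line 1
  bad_item <- !df$item %in% schema$item_id
  if (any(bad_item))
    stop("unknown item code(s) ",
         paste(unique(df$item[bad_item]), collapse = ", "),
         " at line(s) ", paste(line[bad_item], collapse = ", "))
  fee_num <- suppressWarnings(as.numeric(df$fee))
  bad_fee <- is.na(fee_num) & !is.na(df$fee) | (!is.na(fee_num) & fee_num < 0)
  if (any(bad_fee))
    stop("invalid (non-numeric or negative) fee at line(s) ",
         paste(line[bad_fee], collapse = ", "))
  df$fee <- fee_num
  dup <- duplicated(df[c("case_id", "item")])
  if (any(dup))
    stop("duplicate (case_id, item) rows at line(s) ",
         paste(line[dup], collapse = ", "))

  cases <- unique(df[c("case_id", "drg", "year")])
  if (anyDuplicated(cases$case_id))
    stop("case_id appears with conflicting drg/year: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))
  fee <- matrix(NA_real_, nrow(schema), nrow(cases),
                dimnames = list(schema$item_id, cases$case_id))
  fee[cbind(df$item, df$case_id)] <- df$fee
  fee[!is.na(fee) & fee == 0] <- NA_real_   # zero fee means missing
  ded <- NULL
  if ("deducted" %in% names(df)) {
    ded <- matrix(FALSE, nrow(schema), nrow(cases),
                  dimnames = dimnames(fee))
    ded[cbind(df$item, df$case_id)] <- df$deducted %in% c(1, "1", TRUE, "TRUE")
  }
  claimSet(fee, cases, schema, role, deducted = ded)
}

#' Write claims to a delimited file
#'
#' Inverse of [readClaims()]: writes one row per observed (case, item) cell,
#' with a \code{deducted} 0/1 column when the set carries audit labels.
#' Missing cells are not written (reading the file back reproduces the set).
#'
#' @param x a [ClaimSet-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeClaims <- function(x, file) {
  fee <- fees(x)
  ded <- deductions(x)
  info <- caseInfo(x)
  obs <- which(!is.na(fee), arr.ind = TRUE)
  ## stable case-major ordering so repeated writes are byte-identical
  obs <- obs[order(obs[, "col"], obs[, "row"]), , drop = FALSE]
  df <- data.frame(
    case_id = colnames(fee)[obs[, "col"]],
    drg = info$drg[obs[, "col"]],
    year = info$year[obs[, "col"]],
    item = rownames(fee)[obs[, "row"]],
    fee = fee[obs],
    stringsAsFactors = FALSE)
  if (!is.null(ded)) df$deducted <- as.integer(ded[obs])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Normalisation bounds from a norm group
#'
#' Per-item minimum and maximum fee over the non-missing cells of the norm
#' group for one DRG; these bounds define the min--max transformation of raw
#' fees onto the unit interval. Items never observed in the norm group are
#' dropped from the bounds with a warning; items whose observed fees are all
#' equal are flagged degenerate (they carry no information and are excluded
#' from modelling).
#'
#' @param norm a norm-role [ClaimSet-class].
#' @param drg DRG code to subset on.
#' @return data.frame with columns item_id, min, max, n_obs, degenerate.
#' @export
computeBounds <- function(norm, drg) {
  stopifnot(is(norm, "ClaimSet"))
  sel <- caseInfo(norm)$drg == drg
  if (sum(sel) < 2L)
    stop("need at least 2 norm cases for DRG ", drg)
  fee <- fees(norm)[, sel, drop = FALSE]
  n_obs <- rowSums(!is.na(fee))
  unobserved <- rownames(fee)[n_obs == 0L]
  if (length(unobserved))
    warning("item(s) never observed in the norm group, dropped from bounds: ",
            paste(unobserved, collapse = ", "))
  keep <- n_obs > 0L
  b <- data.frame(
    item_id = rownames(fee)[keep],
    min = apply(fee[keep, , drop = FALSE], 1, min, na.rm = TRUE),
    max = apply(fee[keep, , drop = FALSE], 1, max, na.rm = TRUE),
    n_obs = n_obs[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  b$degenerate <- b$min == b$max
  b
}

#' Min-max normalise a fee to the unit interval
#'
#' Maps a raw fee to \code{(fee - min)/(max - min)}, clamped to
#' \code{[eps, 1 - eps]}. The clamp keeps extreme scores away from 0 and 1,
#' where the logistic likelihood degenerates (an ability estimated from a
#' single boundary score would diverge); fees outside the norm-group range
#' (as up-coded fees typically are) are clamped, not rejected.
#'
#' @param fee raw fee(s), non-missing.
#' @param min,max normalisation bounds for the item (min < max).
#' @param eps boundary clamp, default 0.005.
#' @return normalised score(s) in \code{[eps, 1 - eps]}, monotone
#'   non-decreasing in fee.
#' @examples
#' normalizeFee(300, 100, 500)   # 0.5
#' normalizeFee(100, 100, 500)   # clamped to 0.005
#' @export
normalizeFee <- function(fee, min, max, eps = 0.005) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(min >= max))
    stop("degenerate bounds (min >= max): the item carries no information")
  if (any(is.na(fee))) stop("fee must be non-missing")
  pmin(pmax((fee - min) / (max - min), eps), 1 - eps)
}

## ---- norm-model JSON serialisation ----

.norm_model_format <- "raschDRG-norm-model/1"

#' Write / read a calibrated norm model
#'
#' Lossless JSON round-trip of a [NormModel-class]: DRG code, per-item
#' difficulties with standard errors and normalisation bounds, excluded
#' items, the fee-item schema and the calibration report. Numbers are written
#' at full precision so that \code{readNormModel(writeNormModel(m))}
#' reproduces \code{m} exactly. Files carry a format tag; a missing or
#' foreign tag, or missing fields, raise an explicit schema error rather than
#' a silent partial load.
#'
#' @param model a [NormModel-class].
#' @param path file path.
#' @return `writeNormModel()`: the path, invisibly. `readNormModel()`: a
#'   [NormModel-class].
#' @export
writeNormModel <- function(model, path) {
  stopifnot(is(model, "NormModel"))
  validObject(model)
  payload <- list(
    format = .norm_model_format,
    drg = model@drg,
    schema = model@schema,
    items = model@items,
    excluded = model@excluded,
    calibration = model@calibration)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname writeNormModel
#' @export
readNormModel <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot parse norm-model file '", path, "': ",
                             conditionMessage(e)))
  if (!identical(payload$format, .norm_model_format))
    stop("not a norm-model file (format tag ",
         deparse(payload$format), ", expected ",
         deparse(.norm_model_format), ")")
  need <- c("drg", "schema", "items", "excluded", "calibration")
  miss <- setdiff(need, names(payload))
  if (length(miss))
    stop("norm-model file is missing field(s): ", paste(miss, collapse = ", "))
  items <- as.data.frame(payload$items)
  items$n_obs <- as.integer(items$n_obs)
  excluded <- as.data.frame(payload$excluded)
  if (nrow(excluded) == 0L)
    excluded <- data.frame(item_id = character(), reason = character())
  new("NormModel", drg = payload$drg,
      items = items,
      excluded = excluded,
      calibration = payload$calibration,
      schema = as.data.frame(payload$schema))
}
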