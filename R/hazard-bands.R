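# Canonical endpoint enumeration. Order matters: it is the deterministic
# tie-break for selecting a driving point of departure.
ENDPOINTS <- c("acute_oral", "stot_se", "dermal_sens", "stot_re",
               "carcinogenicity", "reproductive")

CANONICAL_METRIC <- c(
  acute_oral      = "ATE",
  stot_se         = "NOAEL",
  dermal_sens     = "concentration_percent",
  stot_re         = "NOAEL",
  carcinogenicity = "T25",
  reproductive    = "ED10"
)

POD_TYPES <- c("NOAEL", "NOEL", "LOEL", "ATE", "T25", "ED10",
               "concentration_percent")

# NOAEL/NOEL/LOEL are generic dose descriptors and are accepted as
# surrogates for any dose-based metric (the worked assessments band NOELs
# against ED10 and T25 limits). Metric-specific types are only valid against
# their own endpoint's table.
DOSE_SURROGATES <- c("NOAEL", "NOEL", "LOEL")

TIERS <- c("tier1_insilico", "tier2_invitro", "tier3_targeted_invivo",
           "conventional")

#' Potency band table for one hazard endpoint
#'
#' A band table maps a point of departure to a hazard category by a sequence
#' of strictly increasing upper dose limits. Values at or below the first
#' limit fall in the first (most severe) category; values above the last
#' limit fall in `overflow_category`; an explicit no-response result maps to
#' `no_response_category` (`NA` meaning "not classified").
#'
#' @param endpoint Endpoint id, one of
#'   `acute_oral`, `stot_se`, `dermal_sens`, `stot_re`, `carcinogenicity`,
#'   `reproductive`.
#' @param thresholds Strictly increasing upper band limits (mg/kg/day, or
#'   percent for `dermal_sens`).
#' @param categories Strictly increasing integer categories, one per
#'   threshold.
#' @param overflow_category Category for values above the last threshold.
#' @param no_response_category Category for a no-response result; `NA` means
#'   not classified.
#' @return An object of class `potency_band_table`.
#' @seealso [default_band_tables()] for the shipped CLP-derived defaults.
#' @export
potency_band_table <- function(endpoint, thresholds, categories,
                               overflow_category, no_response_category = NA) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1,
            length(categories) == length(thresholds))
  if (any(diff(thresholds) <= 0)) {
    stop("band thresholds must be strictly increasing", call. = FALSE)
  }
  if (any(thresholds <= 0)) stop("band thresholds must be positive", call. = FALSE)
  categories <- as.integer(categories)
  if (any(diff(categories) <= 0)) {
    stop("band categories must be strictly increasing", call. = FALSE)
  }
  structure(
    list(endpoint = endpoint,
         thresholds = as.numeric(thresholds),
         categories = categories,
         overflow_category = as.integer(overflow_category),
         no_response_category = if (is.na(no_response_category)) NA_integer_
                                else as.integer(no_response_category)),
    class = "potency_band_table"
  )
}

#' @export
print.potency_band_table <- function(x, ...) {
  unit <- if (x$endpoint == "dermal_sens") "%" else " mg/kg/day"
  cat("<potency band table> ", x$endpoint,
      " (", CANONICAL_METRIC[[x$endpoint]], ")\n", sep = "")
  lo <- c(0, x$thresholds[-length(x$thresholds)])
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  category %d: (%s, %s]%s\n", x$categories[i],
                format(lo[i]), format(x$thresholds[i]), unit))
  }
  cat(sprintf("  category %d: > %s%s\n", x$overflow_category,
              format(max(x$thresholds)), unit))
  if (!is.na(x$no_response_category)) {
    cat(sprintf("  no response: category %d\n", x$no_response_category))
  } else {
    cat("  no response: not classified\n")
  }
  invisible(x)
}

#' Default CLP-derived potency band tables
#'
#' The shipped constants: per-endpoint ordered dose limits (mg/kg/day;
#' percent for dermal sensitisation) mapping points of departure to hazard
#' categories. STOT-SE/STOT-RE categories 3 and 4 extend the CLP category
#' 1/2 dose ranges so that every endpoint spans four potency bands; the
#' carcinogenicity and reproductive-toxicity bands are the high/medium/low
#' potency limits of the specific concentration limit (SCL) scheme, with a
#' no-response result left unclassified.
#'
#' @return Named list of [potency_band_table()] objects, one per endpoint.
#' @examples
#' default_band_tables()$stot_re
#' @export
default_band_tables <- function() {
  list(
    acute_oral = potency_band_table("acute_oral",
                                    c(5, 50, 300, 2000), 1:4, 5L),
    stot_se = potency_band_table("stot_se",
                                 c(300, 2000, 5000), 1:3, 4L),
    dermal_sens = potency_band_table("dermal_sens",
                                     c(0.1, 10, 100), 1:3, 4L,
                                     no_response_category = 4L),
    stot_re = potency_band_table("stot_re",
                                 c(10, 100, 1000), 1:3, 4L),
    carcinogenicity = potency_band_table("carcinogenicity",
                                         c(1, 100), 1:2, 3L),
    reproductive = potency_band_table("reproductive",
                                      c(4, 400), 1:2, 3L)
  )
}

#' Point-of-departure record
#'
#' One study (or assay + extrapolation) result anchoring hazard
#' classification and DNEL derivation for one endpoint at one tier.
#'
#' @param endpoint Endpoint id.
#' @param pod_type One of `NOAEL`, `NOEL`, `LOEL`, `ATE`, `T25`, `ED10`,
#'   `concentration_percent`.
#' @param value Dose value: a number, `c(lo, hi)` or a [dose_interval()].
#'   Interpreted in `units`.
#' @param tier Assessment tier: `tier1_insilico`, `tier2_invitro`,
#'   `tier3_targeted_invivo` or `conventional`.
#' @param units One of `mg/kg/day`, `ug/kg/day`, `uM`, `percent`. Doses are
#'   normalised to mg/kg/day on construction; `uM` values are flagged as
#'   pre-IVIVE and must be converted with [oral_equivalent_dose()] before
#'   classification or DNEL derivation.
#' @param no_response Logical: the study showed no relevant response (no
#'   dose value is carried in that case).
#' @param study_note Free-text provenance.
#' @return An object of class `pod_record`.
#' @export
pod_record <- function(endpoint, pod_type, value = NULL, tier,
                       units = "mg/kg/day", no_response = FALSE,
                       study_note = NULL) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  pod_type <- match.arg(pod_type, POD_TYPES)
  tier <- match.arg(tier, TIERS)
  units <- normalise_units(units)
  if (no_response) {
    value <- NULL
  } else {
    if (is.null(value)) stop("a pod_record needs a value unless no_response", call. = FALSE)
    value <- as_dose_interval(value)
    if (units == "ug/kg/day") {
      value <- value / 1000
      units <- "mg/kg/day"
    }
    if (value$lo <= 0) {
      stop("point of departure must be positive (use no_response for a clean study)",
           call. = FALSE)
    }
    if (units == "percent" && endpoint != "dermal_sens") {
      stop("percent units are only valid for dermal_sens", call. = FALSE)
    }
    if (endpoint == "dermal_sens" && units != "percent") {
      stop("dermal_sens points of departure are concentrations in percent",
           call. = FALSE)
    }
  }
  structure(
    list(endpoint = endpoint, pod_type = pod_type, value = value,
         tier = tier, units = units, no_response = isTRUE(no_response),
         study_note = study_note),
    class = "pod_record"
  )
}

normalise_units <- function(units) {
  u <- c("mg/kg/day" = "mg/kg/day",
         "ug/kg/day" = "ug/kg/day", "µg/kg/day" = "ug/kg/day",
         "uM" = "uM", "µM" = "uM",
         "percent" = "percent", "%" = "percent")
  if (!units %in% names(u)) {
    stop(sprintf("unsupported units '%s' (allowed: mg/kg/day, ug/kg/day, uM, percent)",
                 units), call. = FALSE)
  }
  unname(u[[units]])
}

is_pre_ivive <- function(pod) !pod$no_response && identical(pod$units, "uM")

#' @export
print.pod_record <- function(x, ...) {
  val <- if (x$no_response) "no response" else paste(format(x$value), x$units)
  cat("<pod record> ", x$endpoint, " ", x$pod_type, " ", val,
      " [", x$tier, "]\n", sep = "")
  invisible(x)
}

#' Classify a point of departure into a hazard category
#'
#' Looks the health-protective lower end of the PoD interval up in the
#' endpoint's band table. A value exactly on a shared band limit is assigned
#' to the more severe (lower-numbered) category; a no-response record
#' returns the table's no-response category (`NA` = not classified).
#'
#' @param band_table A [potency_band_table()] for the record's endpoint.
#' @param pod A [pod_record()]. Its `pod_type` must be the endpoint's
#'   canonical metric or a generic dose descriptor (NOAEL/NOEL/LOEL) used as
#'   a surrogate; classifying e.g. a T25 against the STOT-RE table is an
#'   error.
#' @return An object of class `hazard_endpoint_result` with fields
#'   `endpoint`, `category` (integer or `NA` for not classified),
#'   `driving_pod` and `override_applied`.
#' @examples
#' bt <- default_band_tables()
#' classify_endpoint(bt$stot_re, pod_record("stot_re", "NOAEL", 4,
#'                                          tier = "tier3_targeted_invivo"))
#' @export
classify_endpoint <- function(band_table, pod) {
  stopifnot(inherits(band_table, "potency_band_table"),
            inherits(pod, "pod_record"))
  if (!identical(band_table$endpoint, pod$endpoint)) {
    stop(sprintf("endpoint mismatch: band table is for %s, record is for %s",
                 band_table$endpoint, pod$endpoint), call. = FALSE)
  }
  canonical <- CANONICAL_METRIC[[pod$endpoint]]
  metric_ok <- identical(pod$pod_type, canonical) ||
    (pod$pod_type %in% DOSE_SURROGATES && canonical != "concentration_percent")
  if (!metric_ok) {
    stop(sprintf("metric mismatch: cannot classify a %s against the %s (%s) bands",
                 pod$pod_type, pod$endpoint, canonical), call. = FALSE)
  }
  if (pod$no_response) {
    return(hazard_endpoint_result(pod$endpoint, band_table$no_response_category, pod))
  }
  if (is_pre_ivive(pod)) {
    stop("point of departure is in µM; convert with oral_equivalent_dose() first",
         call. = FALSE)
  }
  value <- pod$value$lo
  idx <- which(value <= band_table$thresholds)
  category <- if (length(idx)) band_table$categories[[min(idx)]]
              else band_table$overflow_category
  hazard_endpoint_result(pod$endpoint, category, pod)
}

hazard_endpoint_result <- function(endpoint, category, driving_pod,
                                   override_applied = FALSE, note = NULL) {
  structure(
    list(endpoint = endpoint,
         category = if (is.na(category)) NA_integer_ else as.integer(category),
         driving_pod = driving_pod,
         override_applied = isTRUE(override_applied),
         note = note),
    class = "hazard_endpoint_result"
  )
}

#' @export
print.hazard_endpoint_result <- function(x, ...) {
  cat("<hazard result> ", x$endpoint, ": category ",
      if (is.na(x$category)) "not classified" else x$category,
      if (x$override_applied) " (expert override)" else "", "\n", sep = "")
  invisible(x)
}

#' Map an SCL potency band to a hazard category
#'
#' High potency maps to category 1, medium to 2, low to 3.
#'
#' @param potency_band One of `"high"`, `"medium"`, `"low"`.
#' @return Integer hazard category.
#' @export
potency_to_category <- function(potency_band) {
  potency_band <- match.arg(potency_band, c("high", "medium", "low"))
  c(high = 1L, medium = 2L, low = 3L)[[potency_band]]
}

#' Derive a DNEL from a point of departure
#'
#' Divides the PoD interval by the uncertainty factor (default 100: 10 for
#' interspecies times 10 for intraspecies variability). No rounding is
#' applied here; display rounding is a report-layer concern
#' ([format_dose()]).
#'
#' @param pod A [pod_record()] carrying a positive dose in mg/kg/day.
#' @param uncertainty_factor Positive divisor, default 100.
#' @return An object of class `dnel` with fields `value` (a
#'   [dose_interval()]), `uncertainty_factor`, `source_pod`, `tier`.
#' @examples
#' derive_dnel(pod_record("stot_re", "NOAEL", 4, tier = "tier3_targeted_invivo"))
#' @export
derive_dnel <- function(pod, uncertainty_factor = 100) {
  stopifnot(inherits(pod, "pod_record"))
  if (!is.numeric(uncertainty_factor) || uncertainty_factor <= 0) {
    stop("uncertainty_factor must be positive", call. = FALSE)
  }
  if (pod$no_response) {
    stop("no DNEL can be derived from a no-response record", call. = FALSE)
  }
  if (is_pre_ivive(pod)) {
    stop("point of departure is in µM; convert with oral_equivalent_dose() first",
         call. = FALSE)
  }
  if (pod$endpoint == "dermal_sens") {
    stop("dermal sensitisation concentrations do not yield a systemic DNEL",
         call. = FALSE)
  }
  structure(
    list(value = pod$value / uncertainty_factor,
         uncertainty_factor = uncertainty_factor,
         source_pod = pod,
         tier = pod$tier,
         override_applied = FALSE,
         note = NULL),
    class = "dnel"
  )
}

#' @export
print.dnel <- function(x, ...) {
  cat("<DNEL> ", format_dose(x$value), " mg/kg/day (PoD ",
      if (is.null(x$source_pod)) "expert-assigned" else
        paste0(x$source_pod$pod_type, " ", format(x$source_pod$value)),
      ", UF ", x$uncertainty_factor,
      if (x$override_applied) ", expert override" else "", ")\n", sep = "")
  invisible(x)
}

#' Select the driving point of departure at a tier
#'
#' Among the systemic records (dermal sensitisation is excluded: its metric
#' is a concentration, not a dose) at the requested tier, returns the record
#' with the minimal lower bound -- the health-protective choice that anchors
#' the tier's DNEL. Ties break deterministically by endpoint order
#' (`acute_oral`, `stot_se`, `stot_re`, `carcinogenicity`, `reproductive`).
#'
#' @param records List of [pod_record()] objects.
#' @param tier Tier to select within.
#' @return The driving [pod_record()].
#' @export
select_driving_pod <- function(records, tier) {
  tier <- match.arg(tier, TIERS)
  keep <- Filter(function(r) {
    inherits(r, "pod_record") && identical(r$tier, tier) &&
      r$endpoint != "dermal_sens" && !r$no_response && !is_pre_ivive(r)
  }, records)
  if (!length(keep)) {
    stop(sprintf("no systemic point of departure available at tier '%s'", tier),
         call. = FALSE)
  }
  lows <- vapply(keep, function(r) r$value$lo, numeric(1))
  ord <- vapply(keep, function(r) match(r$endpoint, ENDPOINTS), numeric(1))
  keep[[order(lows, ord)[1L]]]
}
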