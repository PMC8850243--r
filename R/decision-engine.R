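MATRIX_COLOURS <- c("green", "amber", "red")
EXPOSURE_CATEGORIES <- c("A", "B", "C", "D", "E")

#' Default hazard-by-exposure decision matrix
#'
#' The red/amber/green matrix combining hazard severity (rows: category 1
#' most severe to category 4 / not classified) with exposure category
#' (columns A highest to E lowest). Green indicates an adequate margin of
#' exposure, amber a borderline margin requiring an explicit
#' margin-of-exposure comparison, red an inadequate margin. The default
#' cell map is anchored to the worked assessments (a category 1 hazard at
#' category B exposure is red; at D, amber; at E, green; a category 2
#' hazard at category A is red; and Category A exposure is only green for
#' substances confirmed clean at the limit dose). Any user-supplied map is
#' validated for monotonicity at load: stepping towards lower exposure or
#' lower hazard severity never worsens the colour.
#'
#' @param cells 4x5 character matrix of colours with rows `"1"`..`"4"` and
#'   columns `"A"`..`"E"`; defaults to the anchored map.
#' @return A `matrix_config` object.
#' @export
matrix_config <- function(cells = NULL) {
  if (is.null(cells)) {
    cells <- rbind(
      "1" = c("red",   "red",   "red",   "amber", "green"),
      "2" = c("red",   "amber", "amber", "green", "green"),
      "3" = c("amber", "amber", "green", "green", "green"),
      "4" = c("amber", "green", "green", "green", "green")
    )
    colnames(cells) <- EXPOSURE_CATEGORIES
  }
  cells <- as.matrix(cells)
  if (!identical(dim(cells), c(4L, 5L))) {
    stop("matrix config must be 4 hazard rows x 5 exposure columns", call. = FALSE)
  }
  if (is.null(rownames(cells))) rownames(cells) <- as.character(1:4)
  if (is.null(colnames(cells))) colnames(cells) <- EXPOSURE_CATEGORIES
  if (!all(cells %in% MATRIX_COLOURS)) {
    stop("matrix cells must be 'green', 'amber' or 'red'", call. = FALSE)
  }
  sev <- matrix(match(cells, MATRIX_COLOURS), nrow = nrow(cells))
  if (any(apply(sev, 1, diff) > 0)) {
    stop("matrix not monotone: moving towards exposure E must never worsen the colour",
         call. = FALSE)
  }
  if (any(apply(sev, 2, diff) > 0)) {
    stop("matrix not monotone: moving towards lower hazard severity must never worsen the colour",
         call. = FALSE)
  }
  structure(list(cells = cells), class = "matrix_config")
}

#' @export
print.matrix_config <- function(x, ...) {
  cat("<decision matrix> (rows: hazard category; columns: exposure category)\n")
  print(x$cells, quote = FALSE)
  invisible(x)
}

matrix_hazard_row <- function(hazard_category) {
  # category 4, category 5 (acute oral) and "not classified" share the
  # lowest-severity row
  if (is.na(hazard_category) || hazard_category >= 4L) "4"
  else as.character(hazard_category)
}

#' Look a hazard/exposure pair up in the decision matrix
#'
#' @param hazard_category Integer 1--5 or `NA` (not classified); categories
#'   4+ and not-classified share the lowest-severity row.
#' @param exposure_category `"A"`..`"E"`.
#' @param config A [matrix_config()].
#' @param limit_dose_cleared Logical: a tier-3 or conventional limit-dose
#'   study confirmed no relevant toxicity at or above the limit dose. Only
#'   then is Category A exposure green for an unclassified substance;
#'   otherwise the A cell of the lowest-severity row is amber.
#' @return `"green"`, `"amber"` or `"red"`.
#' @examples
#' matrix_lookup(1, "B") # red
#' matrix_lookup(1, "E") # green
#' @export
matrix_lookup <- function(hazard_category, exposure_category,
                          config = matrix_config(),
                          limit_dose_cleared = FALSE) {
  stopifnot(inherits(config, "matrix_config"))
  exposure_category <- match.arg(exposure_category, EXPOSURE_CATEGORIES)
  row <- matrix_hazard_row(hazard_category)
  colour <- config$cells[row, exposure_category]
  if (row == "4" && exposure_category == "A" && limit_dose_cleared) {
    colour <- "green"
  }
  unname(colour)
}

#' Tier-dependent confidence multipliers for the margin of exposure
#'
#' A tier-2 (in vitro + IVIVE) hazard assessment carries one to two
#' additional orders of magnitude of uncertainty over targeted in vivo
#' work, so its DNEL must clear the exposure by an extra factor before a
#' use is accepted. The default multiplier of 10 for tier 2 is the minimum
#' consistent with the worked assessments (a raw margin of 1.5 at tier 2
#' was judged insufficient; a margin of 10 at tier 3 sufficient); tier 3
#' and conventional assessments use 1.
#'
#' @param tier2_invitro,tier3_targeted_invivo,conventional,tier1_insilico
#'   Required-margin multipliers (>= 1) per tier.
#' @return Named numeric vector of multipliers.
#' @export
tier_confidence <- function(tier2_invitro = 10, tier3_targeted_invivo = 1,
                            conventional = 1, tier1_insilico = 100) {
  out <- c(tier1_insilico = tier1_insilico, tier2_invitro = tier2_invitro,
           tier3_targeted_invivo = tier3_targeted_invivo,
           conventional = conventional)
  if (any(out < 1)) stop("confidence multipliers must be >= 1", call. = FALSE)
  out
}

#' Margin-of-exposure verdict
#'
#' Compares the full DNEL and exposure intervals:
#'
#' * `acceptable` -- the exposure range lies at or below the whole DNEL
#'   range (`exposure.hi <= dnel.lo`) *and* clears it by the tier's
#'   confidence multiplier (`exposure.hi <= dnel.lo / multiplier`);
#' * `insufficient_confidence` -- the raw intervals would be acceptable but
#'   the confidence multiplier flips the outcome: the data, not the
#'   chemical, are the obstacle, so the signal is to escalate the hazard
#'   tier rather than reject;
#' * `unacceptable` -- the exposure range lies entirely above the DNEL
#'   range (`exposure.lo > dnel.hi`);
#' * `borderline` -- the ranges overlap.
#'
#' The verdict is invariant under common positive rescaling of both
#' intervals, and raising a multiplier can never move a verdict towards
#' acceptable. A zero exposure is acceptable with infinite margin.
#'
#' @param dnel DNEL as a [dose_interval()] (or coercible), mg/kg/day, or a
#'   `dnel` object.
#' @param exposure Exposure as a [dose_interval()] (or coercible),
#'   mg/kg/day.
#' @param multiplier Required-margin multiplier for the DNEL's tier, see
#'   [tier_confidence()].
#' @return List with `moe` (`dnel.lo / exposure.hi`) and `verdict`.
#' @examples
#' moe_verdict(0.04, c(0.002, 0.004))                  # acceptable
#' moe_verdict(c(0.36, 3.6), c(0.5, 1.45))             # borderline
#' moe_verdict(0.006, 0.004, multiplier = 10)          # insufficient_confidence
#' @export
moe_verdict <- function(dnel, exposure, multiplier = 1) {
  if (inherits(dnel, "dnel")) dnel <- dnel$value
  if (is.null(dnel)) stop("missing DNEL: no margin of exposure can be computed",
                          call. = FALSE)
  dnel <- as_dose_interval(dnel)
  exposure <- as_dose_interval(exposure)
  if (dnel$lo <= 0) stop("DNEL must be positive", call. = FALSE)
  stopifnot(multiplier >= 1)
  if (exposure$hi == 0) {
    return(list(moe = Inf, verdict = "acceptable"))
  }
  moe <- dnel$lo / exposure$hi
  verdict <-
    if (exposure$hi <= dnel$lo) {
      if (exposure$hi <= dnel$lo / multiplier) "acceptable"
      else "insufficient_confidence"
    } else if (exposure$lo > dnel$hi) {
      "unacceptable"
    } else {
      "borderline"
    }
  list(moe = moe, verdict = verdict)
}

#' Recommend the next assessment action for a decision record
#'
#' * green cell, or an acceptable margin: `accept`;
#' * red cell: `refine_exposure` when a finer exposure estimate is
#'   available, otherwise `reject`;
#' * amber with `insufficient_confidence`: `escalate_hazard_tier` when a
#'   higher hazard tier is available, otherwise `compare_moe` (the decision
#'   rests on the borderline comparison);
#' * amber with a borderline margin: refine whichever side has headroom
#'   (exposure first), else `compare_moe`;
#' * amber with an unacceptable margin: treated like red.
#'
#' @param colour Matrix colour for the cell.
#' @param verdict Margin-of-exposure verdict (`NULL` for green/red cells).
#' @param exposure_refinable A finer exposure estimate exists.
#' @param hazard_refinable A higher hazard tier exists.
#' @return One of `accept`, `reject`, `refine_exposure`,
#'   `escalate_hazard_tier`, `compare_moe`.
#' @export
recommend_next <- function(colour, verdict = NULL, exposure_refinable = FALSE,
                           hazard_refinable = FALSE) {
  colour <- match.arg(colour, MATRIX_COLOURS)
  if (colour == "green" || identical(verdict, "acceptable")) return("accept")
  if (colour == "red" || identical(verdict, "unacceptable")) {
    return(if (exposure_refinable) "refine_exposure" else "reject")
  }
  # amber
  if (identical(verdict, "insufficient_confidence")) {
    return(if (hazard_refinable) "escalate_hazard_tier" else "compare_moe")
  }
  if (exposure_refinable) "refine_exposure"
  else if (hazard_refinable) "escalate_hazard_tier"
  else "compare_moe"
}

#' Hazard profile of a substance at one tier
#'
#' Classifies every endpoint with data at the tier (one result per
#' endpoint, driven by the record with the lowest health-protective bound),
#' applies any expert category overrides recorded in the dossier, and
#' derives the tier DNEL from the driving systemic point of departure (or
#' takes an expert-assigned DNEL override, which is disclosed as such).
#'
#' @param dossier A [substance_dossier()].
#' @param tier Assessment tier.
#' @param bands Band tables, defaults to [default_band_tables()].
#' @param uncertainty_factor DNEL uncertainty factor, default 100.
#' @return A `hazard_profile` with fields `substance_id`, `tier`,
#'   `endpoint_results` (named list of `hazard_endpoint_result`) and `dnel`
#'   (`NULL` when no systemic record exists at the tier).
#' @export
hazard_profile <- function(dossier, tier, bands = default_band_tables(),
                           uncertainty_factor = 100) {
  stopifnot(inherits(dossier, "substance_dossier"))
  tier <- match.arg(tier, TIERS)
  records <- Filter(function(r) identical(r$tier, tier), dossier$pod_records)

  results <- list()
  for (ep in intersect(ENDPOINTS, unique(vapply(records, `[[`, "", "endpoint")))) {
    ep_recs <- Filter(function(r) identical(r$endpoint, ep), records)
    responders <- Filter(function(r) !r$no_response, ep_recs)
    driving <- if (length(responders)) {
      lows <- vapply(responders, function(r) r$value$lo, numeric(1))
      responders[[which.min(lows)]]
    } else {
      ep_recs[[1L]]
    }
    results[[ep]] <- classify_endpoint(bands[[ep]], driving)
  }

  for (ov in dossier$overrides) {
    if (!identical(ov$tier, tier)) next
    base <- results[[ov$endpoint]]
    results[[ov$endpoint]] <- hazard_endpoint_result(
      ov$endpoint, ov$category,
      driving_pod = if (is.null(base)) NULL else base$driving_pod,
      override_applied = TRUE, note = ov$note)
  }

  dnel <- NULL
  dnel_ov <- Filter(function(o) identical(o$tier, tier), dossier$dnel_overrides)
  if (length(dnel_ov)) {
    ov <- dnel_ov[[1L]]
    dnel <- structure(
      list(value = as_dose_interval(ov$value),
           uncertainty_factor = uncertainty_factor,
           source_pod = NULL, tier = tier,
           override_applied = TRUE, note = ov$note),
      class = "dnel")
  } else {
    systemic <- Filter(function(r) r$endpoint != "dermal_sens" && !r$no_response,
                       records)
    if (length(systemic)) {
      dnel <- derive_dnel(select_driving_pod(records, tier), uncertainty_factor)
    }
  }

  structure(list(substance_id = dossier$substance_id, tier = tier,
                 endpoint_results = results, dnel = dnel),
            class = "hazard_profile")
}

#' @export
print.hazard_profile <- function(x, ...) {
  cat("<hazard profile> ", x$substance_id, " @ ", x$tier, "\n", sep = "")
  for (r in x$endpoint_results) {
    cat(sprintf("  %-16s category %s%s\n", r$endpoint,
                if (is.na(r$category)) "not classified" else r$category,
                if (r$override_applied) " (override)" else ""))
  }
  if (!is.null(x$dnel)) {
    cat("  DNEL ", format_dose(x$dnel$value), " mg/kg/day",
        if (x$dnel$override_applied) " (expert-assigned)" else "", "\n", sep = "")
  } else {
    cat("  DNEL: none derivable at this tier\n")
  }
  invisible(x)
}

#' Most severe hazard category relevant to an exposure duration
#'
#' Returns the lowest (most severe) category among the duration-relevant
#' endpoints of a hazard profile (one-day: STOT-SE; up to 3 months:
#' STOT-RE + reproductive; beyond: STOT-RE + carcinogenicity +
#' reproductive). Not-classified results count as the lowest severity.
#' Returns `NA` (treated as the lowest-severity matrix row) when no
#' relevant endpoint has data -- a data gap the caller should surface.
#'
#' @param profile A [hazard_profile()].
#' @param duration Duration class.
#' @return Integer category or `NA`.
#' @export
severity_for_duration <- function(profile, duration) {
  stopifnot(inherits(profile, "hazard_profile"))
  duration <- match.arg(duration, DURATIONS)
  relevant <- DURATION_ENDPOINTS[[duration]]
  cats <- vapply(profile$endpoint_results[
    intersect(names(profile$endpoint_results), relevant)],
    `[[`, integer(1), "category")
  if (!length(cats) || all(is.na(cats))) return(NA_integer_)
  min(cats, na.rm = TRUE)
}
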