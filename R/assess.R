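#' Assessment configuration
#'
#' Bundles the tunable constants of the engine: band tables, limit doses,
#' matrix, tier-confidence multipliers, DNEL uncertainty factor,
#' boundary-derivation strategy and the Cramer fallback switch.
#'
#' @param bands Band tables ([default_band_tables()]).
#' @param limits Limit doses ([limit_doses()]).
#' @param matrix Decision matrix ([matrix_config()]); user-supplied maps
#'   are monotonicity-validated on construction.
#' @param confidence Tier-confidence multipliers ([tier_confidence()]).
#' @param uncertainty_factor DNEL / boundary uncertainty factor.
#' @param boundary_strategy Passed to [derive_boundaries()].
#' @param assume_cramer_iii Passed to [assign_ttc()].
#' @return An `assessment_config` list.
#' @export
assessment_config <- function(bands = default_band_tables(),
                              limits = limit_doses(),
                              matrix = matrix_config(),
                              confidence = tier_confidence(),
                              uncertainty_factor = 100,
                              boundary_strategy = "driving_endpoint",
                              assume_cramer_iii = FALSE) {
  stopifnot(inherits(matrix, "matrix_config"), inherits(limits, "limit_doses"),
            uncertainty_factor > 0)
  structure(list(bands = bands, limits = limits, matrix = matrix,
                 confidence = confidence,
                 uncertainty_factor = uncertainty_factor,
                 boundary_strategy = boundary_strategy,
                 assume_cramer_iii = assume_cramer_iii),
            class = "assessment_config")
}

#' Run a tiered safety assessment
#'
#' Deterministically replays the assessment steps present in the inputs:
#' for every exposure scenario, a Tier-0 TTC screen first (a pass
#' terminates that scenario with Category E and a green decision), then one
#' decision record per planned (exposure step x hazard tier) pair --
#' exposure category, most severe duration-relevant hazard category, matrix
#' colour, margin-of-exposure verdict wherever the cell is amber, and a
#' recommended next action. The engine recommends refinements but never
#' fabricates them: only steps present in the scenario plan are evaluated.
#'
#' @param dossier A [substance_dossier()].
#' @param scenarios A `scenario_set` ([scenario_set()] or
#'   [read_scenarios()]) carrying the duration class, the ordered plan of
#'   (exposure step, hazard tier) pairs, and per-scenario exposure
#'   estimates.
#' @param config An [assessment_config()].
#' @return An `assessment_trajectory`: `substance_id`, `ttc`, `boundaries`,
#'   `profiles` (hazard profile per tier used), `records` (one data frame
#'   row per scenario per step) and `terminal` (named per-scenario terminal
#'   state: `accept`, `reject`, or an open state such as `borderline`).
#' @export
assess <- function(dossier, scenarios, config = assessment_config()) {
  stopifnot(inherits(dossier, "substance_dossier"),
            inherits(scenarios, "scenario_set"))
  if (!length(scenarios$scenarios)) {
    stop("scenario set is empty: nothing to assess", call. = FALSE)
  }
  if (!length(scenarios$plan)) {
    stop("scenario plan is empty: no assessment steps to replay", call. = FALSE)
  }
  duration <- scenarios$duration
  ttc <- assign_ttc(dossier$ttc_flags,
                    assume_cramer_iii = config$assume_cramer_iii)
  boundaries <- derive_boundaries(duration, bands = config$bands,
                                  limits = config$limits, ttc = ttc$ttc_mg,
                                  uncertainty_factor = config$uncertainty_factor,
                                  strategy = config$boundary_strategy)

  tiers_used <- unique(vapply(scenarios$plan, `[[`, "", "hazard_tier"))
  profiles <- lapply(stats::setNames(tiers_used, tiers_used), function(tier) {
    hazard_profile(dossier, tier, bands = config$bands,
                   uncertainty_factor = config$uncertainty_factor)
  })
  dossier_tiers <- unique(vapply(dossier$pod_records, `[[`, "", "tier"))

  records <- list()
  terminal <- character(0)

  for (sc in scenarios$scenarios) {
    step_doses <- function(step_id) {
      d <- sc$doses[[step_id]]
      if (is.null(d)) {
        stop(sprintf("scenario '%s' has no exposure estimate for step '%s'",
                     sc$scenario_id, step_id), call. = FALSE)
      }
      to_systemic_dose(d$value, route = sc$route,
                       absorption = sc$absorption, units = d$units,
                       inhaled_volume = sc$inhaled_volume)
    }

    first_dose <- step_doses(scenarios$plan[[1L]]$exposure_step)
    screen <- tier0_screen(first_dose, ttc)
    if (screen$passes) {
      records[[length(records) + 1L]] <- data.frame(
        scenario_id = sc$scenario_id, refinement_step = 0L,
        exposure_step = scenarios$plan[[1L]]$exposure_step,
        hazard_tier = "tier0_ttc",
        exposure_category = "E", hazard_category = NA_integer_,
        colour = "green", moe = screen$margin, verdict = "acceptable",
        recommendation = "accept", data_gap = FALSE,
        stringsAsFactors = FALSE)
      terminal[[sc$scenario_id]] <- "accept"
      next
    }

    n_steps <- length(scenarios$plan)
    for (i in seq_len(n_steps)) {
      step <- scenarios$plan[[i]]
      sys_dose <- step_doses(step$exposure_step)
      exp_res <- categorise_dose(sys_dose, boundaries, sc$scenario_id)
      profile <- profiles[[step$hazard_tier]]

      relevant <- DURATION_ENDPOINTS[[duration]]
      data_gap <- !any(relevant %in% names(profile$endpoint_results))
      hcat <- severity_for_duration(profile, duration)

      colour <- matrix_lookup(
        hcat, exp_res$category, config$matrix,
        limit_dose_cleared = isTRUE(dossier$limit_dose_clearance[[duration]]))

      remaining <- if (i < n_steps) scenarios$plan[(i + 1L):n_steps] else list()
      exposure_refinable <- any(vapply(
        remaining, function(s) !identical(s$exposure_step, step$exposure_step),
        logical(1)))
      remaining_tiers <- vapply(remaining, `[[`, "", "hazard_tier")
      higher_in_dossier <- dossier_tiers[
        match(dossier_tiers, TIERS) > match(step$hazard_tier, TIERS)]
      hazard_refinable <- any(remaining_tiers != step$hazard_tier) ||
        length(higher_in_dossier) > 0

      multiplier <- unname(config$confidence[[step$hazard_tier]])
      moe <- NA_real_
      verdict <- switch(colour, green = "acceptable", red = "unacceptable",
                        amber = NA_character_)
      if (!is.null(profile$dnel)) {
        mv <- moe_verdict(profile$dnel, sys_dose, multiplier)
        moe <- mv$moe
        if (colour == "amber") verdict <- mv$verdict
      } else if (colour == "amber") {
        # amber forces a margin-of-exposure comparison; without a DNEL the
        # only honest outcome is to demand better hazard data
        verdict <- "insufficient_confidence"
      }

      records[[length(records) + 1L]] <- data.frame(
        scenario_id = sc$scenario_id, refinement_step = i,
        exposure_step = step$exposure_step, hazard_tier = step$hazard_tier,
        exposure_category = exp_res$category, hazard_category = hcat,
        colour = colour, moe = moe, verdict = verdict,
        recommendation = recommend_next(colour, verdict, exposure_refinable,
                                        hazard_refinable),
        data_gap = data_gap, stringsAsFactors = FALSE)
    }

    last <- records[[length(records)]]
    terminal[[sc$scenario_id]] <-
      if (identical(last$verdict, "acceptable")) "accept"
      else if (last$colour == "red") "reject"
      else if (identical(last$verdict, "unacceptable")) "reject"
      else last$verdict
  }

  structure(
    list(substance_id = dossier$substance_id, duration = duration,
         ttc = ttc, boundaries = boundaries, profiles = profiles,
         records = do.call(rbind, records), terminal = as.list(terminal)),
    class = "assessment_trajectory")
}

#' @export
print.assessment_trajectory <- function(x, ...) {
  cat("<assessment trajectory> ", x$substance_id, " (", x$duration, ")\n",
      sep = "")
  print(x$records[, c("scenario_id", "refinement_step", "hazard_tier",
                      "exposure_category", "hazard_category", "colour",
                      "verdict", "recommendation")],
        row.names = FALSE)
  cat("terminal states:\n")
  for (id in names(x$terminal)) cat("  ", id, ": ", x$terminal[[id]], "\n",
                                    sep = "")
  invisible(x)
}
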