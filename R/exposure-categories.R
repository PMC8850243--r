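DURATIONS <- c("one_day", "short_term", "long_term")

# Endpoints whose bands are relevant to each exposure duration. One-day
# boundaries come from STOT-SE alone; repeat-dose durations add the
# reproductive-toxicity (ED10) bands and, beyond 3 months, carcinogenicity
# (T25). Acute-oral ATE bands classify hazard but never set exposure
# boundaries.
DURATION_ENDPOINTS <- list(
  one_day    = "stot_se",
  short_term = c("stot_re", "reproductive"),
  long_term  = c("stot_re", "carcinogenicity", "reproductive")
)

#' Limit doses used for the Category A boundary
#'
#' The highest exposure category is anchored to study limit doses -- the
#' upper dosing limits accepted on practical and ethical grounds: 2000
#' mg/kg for single-dose lethality studies, 1000 mg/kg for repeat-dose
#' studies. The one-day Category A boundary uses the top of the STOT-SE
#' band range (5000 mg/kg) divided by the uncertainty factor, which
#' reproduces the published 50 mg/kg lower limit.
#'
#' @param single_dose_limit Single-dose study limit dose, mg/kg.
#' @param repeat_dose_limit Repeat-dose study limit dose, mg/kg.
#' @param stot_se_top_band Upper end of the extended STOT-SE band range,
#'   mg/kg.
#' @return A `limit_doses` list.
#' @export
limit_doses <- function(single_dose_limit = 2000, repeat_dose_limit = 1000,
                        stot_se_top_band = 5000) {
  stopifnot(single_dose_limit > 0, repeat_dose_limit > 0, stot_se_top_band > 0)
  structure(list(single_dose_limit = single_dose_limit,
                 repeat_dose_limit = repeat_dose_limit,
                 stot_se_top_band = stot_se_top_band),
            class = "limit_doses")
}

#' Derive duration-specific exposure category boundaries
#'
#' Reconstructs the A--E exposure category limits for one exposure duration
#' from the CLP band tables, the limit doses and the substance-specific TTC,
#' all divided by the uncertainty factor:
#'
#' 1. The Category A lower limit is the duration-appropriate limit dose /
#'    UF (one-day uses the STOT-SE top band; repeat durations the
#'    repeat-dose limit dose).
#' 2. Among the duration-relevant endpoints, the endpoint with the lowest
#'    category-1 upper limit drives the inner boundaries (default
#'    `strategy = "driving_endpoint"`): B/C = its category-2 limit / UF,
#'    C/D = its category-1 limit / UF. This is the rule that reproduces the
#'    published limits (STOT-SE for one-day, ED10 for short-term, T25 for
#'    long-term); `strategy = "elementwise_min"` instead takes the minimum
#'    limit across the relevant endpoints at each boundary, which is
#'    strictly more conservative for short-term exposure.
#' 3. The D/E boundary is the substance TTC.
#'
#' @param duration `one_day`, `short_term` (repeat dosing up to 3 months) or
#'   `long_term` (beyond 3 months).
#' @param bands Named list of band tables, as [default_band_tables()].
#' @param limits A [limit_doses()] object.
#' @param ttc Substance TTC in mg/kg/day (note: TTC values are usually
#'   quoted in µg/kg/day; see [assign_ttc()], whose result carries the
#'   converted `ttc_mg`).
#' @param uncertainty_factor Positive divisor applied to every animal-study
#'   limit, default 100.
#' @param strategy Boundary-derivation rule, see Details.
#' @return An `exposure_boundaries` object with fields `duration`,
#'   `a_lower`, `b_interval`, `c_interval`, `d_interval`, `e_upper` (the
#'   TTC) and a `derivation_trace` data frame recording the source of every
#'   boundary.
#' @examples
#' ttc <- assign_ttc(ttc_flags(cramer_class = "III"))
#' derive_boundaries("long_term", ttc = ttc$ttc_mg)
#' @export
derive_boundaries <- function(duration, bands = default_band_tables(),
                              limits = limit_doses(), ttc,
                              uncertainty_factor = 100,
                              strategy = c("driving_endpoint",
                                           "elementwise_min")) {
  duration <- match.arg(duration, DURATIONS)
  strategy <- match.arg(strategy)
  stopifnot(is.numeric(ttc), length(ttc) == 1L, ttc > 0)
  if (!is.numeric(uncertainty_factor) || uncertainty_factor <= 0) {
    stop("uncertainty_factor must be positive", call. = FALSE)
  }
  relevant <- DURATION_ENDPOINTS[[duration]]
  missing_ep <- setdiff(relevant, names(bands))
  if (length(missing_ep)) {
    stop(sprintf("missing band table(s): %s", paste(missing_ep, collapse = ", ")),
         call. = FALSE)
  }
  cat1 <- vapply(bands[relevant], function(b) b$thresholds[[1L]], numeric(1))
  cat2 <- vapply(bands[relevant], function(b) b$thresholds[[2L]], numeric(1))

  a_source <- if (duration == "one_day") {
    list(limit = limits$stot_se_top_band, label = "stot_se_top_band")
  } else {
    list(limit = limits$repeat_dose_limit, label = "repeat_dose_limit")
  }
  a_lower <- a_source$limit / uncertainty_factor

  if (strategy == "driving_endpoint") {
    drv <- relevant[[which.min(cat1)]]
    bc_src <- drv; cd_src <- drv
    bc_limit <- cat2[[drv]]; cd_limit <- cat1[[drv]]
  } else {
    bc_src <- relevant[[which.min(cat2)]]
    cd_src <- relevant[[which.min(cat1)]]
    bc_limit <- min(cat2); cd_limit <- min(cat1)
  }
  bc <- bc_limit / uncertainty_factor
  cd <- cd_limit / uncertainty_factor

  if (!(ttc < cd)) {
    stop(sprintf(
      "substance TTC (%g mg/kg/day) must lie below the C/D boundary (%g mg/kg/day)",
      ttc, cd), call. = FALSE)
  }
  if (!(cd < bc && bc < a_lower)) {
    stop("derived boundaries are not strictly decreasing; check band tables and limits",
         call. = FALSE)
  }

  trace <- data.frame(
    boundary = c("A_lower", "B/C", "C/D", "D/E"),
    source = c(a_source$label,
               paste0(bc_src, " category-2 upper limit"),
               paste0(cd_src, " category-1 upper limit"),
               "substance TTC"),
    source_limit = c(a_source$limit, bc_limit, cd_limit, ttc),
    factor = c(uncertainty_factor, uncertainty_factor, uncertainty_factor, 1),
    value = c(a_lower, bc, cd, ttc),
    stringsAsFactors = FALSE
  )

  structure(
    list(duration = duration,
         a_lower = a_lower,
         b_interval = dose_interval(bc, a_lower),
         c_interval = dose_interval(cd, bc),
         d_interval = dose_interval(ttc, cd),
         e_upper = ttc,
         uncertainty_factor = uncertainty_factor,
         strategy = strategy,
         derivation_trace = trace),
    class = "exposure_boundaries"
  )
}

#' @export
print.exposure_boundaries <- function(x, ...) {
  cat("<exposure boundaries> ", x$duration, " (UF ", x$uncertainty_factor,
      ", ", x$strategy, ")\n", sep = "")
  cat(sprintf("  A: > %s mg/kg/day\n", format(x$a_lower)))
  cat(sprintf("  B: %s mg/kg/day\n", format(x$b_interval)))
  cat(sprintf("  C: %s mg/kg/day\n", format(x$c_interval)))
  cat(sprintf("  D: %s mg/kg/day (lower bound = TTC)\n", format(x$d_interval)))
  cat(sprintf("  E: < %s mg/kg/day (TTC)\n", format(x$e_upper)))
  invisible(x)
}

#' Assign an exposure dose to a category
#'
#' Categorises by the upper end of the systemic dose interval (the
#' health-protective end of an exposure range). A dose exactly on a
#' boundary takes the higher-exposure (earlier-letter) category; any dose
#' strictly below the TTC -- including zero -- is Category E.
#'
#' @param systemic_dose Oral-equivalent dose: number, `c(lo, hi)` or
#'   [dose_interval()], mg/kg/day.
#' @param boundaries An `exposure_boundaries` object from
#'   [derive_boundaries()].
#' @param scenario_id Optional label carried through to the result.
#' @return An `exposure_category_result` with fields `scenario_id`,
#'   `category` (`"A"`..`"E"`), `systemic_dose` and `boundary_set_used`.
#' @export
categorise_dose <- function(systemic_dose, boundaries, scenario_id = NULL) {
  stopifnot(inherits(boundaries, "exposure_boundaries"))
  dose <- as_dose_interval(systemic_dose)
  hi <- dose$hi
  category <-
    if (hi >= boundaries$a_lower) "A"
    else if (hi >= boundaries$b_interval$lo) "B"
    else if (hi >= boundaries$c_interval$lo) "C"
    else if (hi >= boundaries$e_upper) "D"
    else "E"
  structure(
    list(scenario_id = scenario_id, category = category,
         systemic_dose = dose, boundary_set_used = boundaries),
    class = "exposure_category_result"
  )
}

#' @export
print.exposure_category_result <- function(x, ...) {
  cat("<exposure category> ",
      if (!is.null(x$scenario_id)) paste0(x$scenario_id, ": "), "Category ",
      x$category, " (dose ", format(x$systemic_dose), " mg/kg/day, ",
      x$boundary_set_used$duration, ")\n", sep = "")
  invisible(x)
}

#' Convert an external exposure to an oral-equivalent systemic dose
#'
#' Multiplies the external dose by the route-specific absorption fraction.
#' Worst-case defaults of 1.0 match screening practice (100 % absorption by
#' all routes). Inhalation exposures given as an air concentration in mg/m³
#' are first converted to mg/kg/day via the daily inhaled volume and body
#' weight (default 60 kg, the TTC reference individual).
#'
#' @param dose External dose: number, `c(lo, hi)` or [dose_interval()].
#' @param route `oral`, `dermal` or `inhalation`.
#' @param absorption Named list of fractions in `[0, 1]` per route.
#' @param units `"mg/kg/day"` or `"mg/m3"` (inhalation only).
#' @param body_weight Body weight in kg, default 60.
#' @param inhaled_volume Daily inhaled volume in m³/day; required when
#'   `units = "mg/m3"`.
#' @return A [dose_interval()] in mg/kg/day.
#' @examples
#' to_systemic_dose(1, "inhalation", units = "mg/m3", inhaled_volume = 10)
#' @export
to_systemic_dose <- function(dose, route = c("oral", "dermal", "inhalation"),
                             absorption = list(oral = 1, dermal = 1,
                                               inhalation = 1),
                             units = "mg/kg/day", body_weight = 60,
                             inhaled_volume = NULL) {
  route <- match.arg(route)
  stopifnot(body_weight > 0)
  frac <- absorption[[route]]
  if (is.null(frac)) frac <- 1
  if (!is.numeric(frac) || frac < 0 || frac > 1) {
    stop("absorption fractions must lie in [0, 1]", call. = FALSE)
  }
  dose <- as_dose_interval(dose)
  if (identical(units, "mg/m3")) {
    if (route != "inhalation") {
      stop("mg/m3 units are only valid for the inhalation route", call. = FALSE)
    }
    if (is.null(inhaled_volume)) {
      stop("an inhalation concentration requires inhaled_volume (m3/day)",
           call. = FALSE)
    }
    stopifnot(inhaled_volume > 0)
    dose <- dose_interval(dose$lo * inhaled_volume / body_weight,
                          dose$hi * inhaled_volume / body_weight)
  } else if (!identical(units, "mg/kg/day")) {
    stop(sprintf("unsupported exposure units '%s'", units), call. = FALSE)
  }
  dose_interval(dose$lo * frac, dose$hi * frac)
}
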