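TTC_VALUES_UG <- c(
  genotox_alert = 0.0025,
  op_carbamate  = 0.3,
  cramer_III    = 1.5,
  cramer_II     = 9.0,
  cramer_I      = 30
)

#' Structural flags controlling the TTC assignment
#'
#' @param genotoxic_alert Structural alert for genotoxicity present.
#' @param op_or_carbamate Organophosphate or carbamate.
#' @param cramer_class Cramer structural class: `"I"`, `"II"`, `"III"` or
#'   `"unknown"`.
#' @param in_ttc_domain Whether the structure is within the TTC
#'   applicability domain; no TTC may be assigned outside it.
#' @return A `ttc_flags` list.
#' @export
ttc_flags <- function(genotoxic_alert = FALSE, op_or_carbamate = FALSE,
                      cramer_class = "unknown", in_ttc_domain = TRUE) {
  cramer_class <- match.arg(cramer_class, c("I", "II", "III", "unknown"))
  structure(list(genotoxic_alert = isTRUE(genotoxic_alert),
                 op_or_carbamate = isTRUE(op_or_carbamate),
                 cramer_class = cramer_class,
                 in_ttc_domain = isTRUE(in_ttc_domain)),
            class = "ttc_flags")
}

#' Assign the substance-specific threshold of toxicological concern
#'
#' The TTC is a generic exposure level, derived for a 60 kg individual with
#' uncertainty factors already included, below which risk to health is
#' considered negligible. The assigned value follows the most conservative
#' applicable basis: a structural alert for genotoxicity (0.0025 µg/kg/day)
#' takes precedence over the organophosphate/carbamate value (0.3), which
#' takes precedence over the Cramer class values (III: 1.5, II: 9.0,
#' I: 30 µg/kg/day). The same TTC is used for all exposure durations; it is
#' conservative for short-term exposure by an unquantifiable margin.
#'
#' @param flags A [ttc_flags()] object.
#' @param assume_cramer_iii If `TRUE`, an unknown Cramer class without alert
#'   flags falls back to the conservative Cramer III value instead of
#'   erroring.
#' @return A `ttc_assignment` with fields `ttc_value` (µg/kg/day), `ttc_mg`
#'   (mg/kg/day) and `basis`.
#' @examples
#' assign_ttc(ttc_flags(cramer_class = "I"))
#' assign_ttc(ttc_flags(genotoxic_alert = TRUE, cramer_class = "I"))
#' @export
assign_ttc <- function(flags, assume_cramer_iii = FALSE) {
  stopifnot(inherits(flags, "ttc_flags"))
  if (!flags$in_ttc_domain) {
    stop("substance is outside the TTC applicability domain; no TTC can be assigned",
         call. = FALSE)
  }
  basis <-
    if (flags$genotoxic_alert) "genotox_alert"
    else if (flags$op_or_carbamate) "op_carbamate"
    else if (flags$cramer_class == "III") "cramer_III"
    else if (flags$cramer_class == "II") "cramer_II"
    else if (flags$cramer_class == "I") "cramer_I"
    else if (assume_cramer_iii) "cramer_III"
    else stop(paste("Cramer class is unknown and no alert flag applies;",
                    "set assume_cramer_iii = TRUE for the conservative default"),
              call. = FALSE)
  value <- TTC_VALUES_UG[[basis]]
  structure(list(ttc_value = value, ttc_mg = value / 1000, basis = basis),
            class = "ttc_assignment")
}

#' @export
print.ttc_assignment <- function(x, ...) {
  cat("<TTC> ", format(x$ttc_value), " ug/kg/day (basis: ", x$basis, ")\n",
      sep = "")
  invisible(x)
}

#' Tier-0 screen against the TTC
#'
#' The lowest assessment tier assumes every chemical has the potency of the
#' most potent member of its structural class: if the exposure lies strictly
#' below the class TTC, the assessment terminates with exposure Category E
#' and a green decision, with no hazard data required. A dose exactly equal
#' to the TTC fails the screen (health-protective strict inequality).
#'
#' @param systemic_dose Oral-equivalent dose (mg/kg/day): number, `c(lo,
#'   hi)` or [dose_interval()].
#' @param ttc A `ttc_assignment` from [assign_ttc()].
#' @return List with `passes` (logical) and `margin` (`ttc / dose.hi`;
#'   `Inf` for a zero dose).
#' @export
tier0_screen <- function(systemic_dose, ttc) {
  stopifnot(inherits(ttc, "ttc_assignment"))
  dose <- as_dose_interval(systemic_dose)
  margin <- if (dose$hi == 0) Inf else ttc$ttc_mg / dose$hi
  list(passes = dose$hi < ttc$ttc_mg, margin = margin)
}
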