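#' Kinetic parameters for steady-state reverse dosimetry
#'
#' @param molecular_weight Molecular weight, g/mol.
#' @param systemic_clearance Whole-body systemic clearance, L/h/kg body
#'   weight.
#' @param fraction_absorbed Oral absorption fraction in `[0, 1]`, default 1.
#' @param fraction_unbound Plasma fraction unbound in `[0, 1]`, default 1;
#'   only used when free-concentration matching is requested.
#' @return A `kinetic_parameters` list.
#' @export
kinetic_parameters <- function(molecular_weight, systemic_clearance,
                               fraction_absorbed = 1, fraction_unbound = 1) {
  stopifnot(molecular_weight > 0, systemic_clearance > 0,
            fraction_absorbed > 0, fraction_absorbed <= 1,
            fraction_unbound > 0, fraction_unbound <= 1)
  structure(list(molecular_weight = molecular_weight,
                 systemic_clearance = systemic_clearance,
                 fraction_absorbed = fraction_absorbed,
                 fraction_unbound = fraction_unbound),
            class = "kinetic_parameters")
}

#' In vitro to in vivo conversion specification
#'
#' Two pluggable modes translate in vitro threshold concentrations (µM)
#' into oral-equivalent doses (mg/kg/day):
#'
#' * `fixed_factor` -- a supplied linear factor in (mg/kg/day)/µM. The
#'   packaged worked examples use factors back-calculated from their
#'   published concentration/dose pairs; these are fixture data, not a
#'   kinetic model.
#' * `steady_state` -- simple reverse dosimetry at steady state: the daily
#'   oral dose that sustains the target plasma concentration given the
#'   systemic clearance, `dose = conc * CL * 24 * MW / 1000 /
#'   fraction_absorbed`. By default the in vitro concentration is matched to
#'   the *total* plasma concentration; free-concentration matching (divide
#'   by `fraction_unbound`) is opt-in at conversion time.
#'
#' @param mode `"fixed_factor"` or `"steady_state"`.
#' @param factor Conversion factor, (mg/kg/day)/µM; `fixed_factor` mode
#'   only.
#' @param params A [kinetic_parameters()] object; `steady_state` mode only.
#' @return A `conversion_spec`.
#' @export
conversion_spec <- function(mode = c("steady_state", "fixed_factor"),
                            factor = NULL, params = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_factor") {
    if (is.null(factor) || !is.numeric(factor) || factor <= 0) {
      stop("fixed_factor mode requires a positive conversion factor", call. = FALSE)
    }
    if (!is.null(params)) {
      stop("fixed_factor mode takes no kinetic parameters", call. = FALSE)
    }
  } else {
    if (!inherits(params, "kinetic_parameters")) {
      stop("steady_state mode requires kinetic_parameters()", call. = FALSE)
    }
    if (!is.null(factor)) {
      stop("steady_state mode takes no fixed factor", call. = FALSE)
    }
  }
  structure(list(mode = mode, factor = factor, params = params),
            class = "conversion_spec")
}

#' Convert an in vitro concentration to an oral-equivalent dose
#'
#' Both conversion modes are linear and monotone in the concentration, so
#' interval endpoints convert independently.
#'
#' @param conc In vitro point-of-departure concentration in µM: number,
#'   `c(lo, hi)` or [dose_interval()] (here carrying µM, not mg/kg/day).
#' @param spec A [conversion_spec()].
#' @param match_free_concentration If `TRUE` (steady-state mode), match the
#'   in vitro concentration to the free plasma concentration by dividing by
#'   the fraction unbound; default is total-concentration matching.
#' @return A [dose_interval()] in mg/kg/day.
#' @examples
#' oral_equivalent_dose(c(6, 60), conversion_spec("fixed_factor", factor = 6))
#' oral_equivalent_dose(1, conversion_spec("steady_state",
#'   params = kinetic_parameters(molecular_weight = 150,
#'                               systemic_clearance = 1)))
#' @export
oral_equivalent_dose <- function(conc, spec, match_free_concentration = FALSE) {
  stopifnot(inherits(spec, "conversion_spec"))
  conc <- as_dose_interval(conc)
  k <- if (spec$mode == "fixed_factor") {
    spec$factor
  } else {
    p <- spec$params
    f <- p$systemic_clearance * 24 * p$molecular_weight / 1000 / p$fraction_absorbed
    if (match_free_concentration) f <- f / p$fraction_unbound
    f
  }
  dose_interval(conc$lo * k, conc$hi * k)
}

#' Convert a pre-IVIVE point-of-departure record
#'
#' Applies [oral_equivalent_dose()] to a [pod_record()] whose value is in
#' µM, returning an equivalent record in mg/kg/day with the original
#' concentration preserved in the study note.
#'
#' @param pod A [pod_record()] with `units = "uM"`.
#' @param spec A [conversion_spec()].
#' @param ... Passed to [oral_equivalent_dose()].
#' @return A [pod_record()] in mg/kg/day.
#' @export
convert_pod <- function(pod, spec, ...) {
  stopifnot(inherits(pod, "pod_record"))
  if (!is_pre_ivive(pod)) {
    stop("pod_record is not a pre-IVIVE concentration in µM", call. = FALSE)
  }
  dose <- oral_equivalent_dose(pod$value, spec, ...)
  note <- paste0(
    if (!is.null(pod$study_note)) paste0(pod$study_note, "; ") else "",
    "IVIVE from ", format(pod$value), " uM (", spec$mode, ")")
  pod_record(pod$endpoint, pod$pod_type, c(dose$lo, dose$hi), tier = pod$tier,
             units = "mg/kg/day", study_note = note)
}
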