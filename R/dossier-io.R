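DOSSIER_SCHEMA_VERSION <- 1L

DOSSIER_FIELDS <- c("schema_version", "substance_id", "name", "identifiers",
                    "ttc", "pod_records", "overrides", "dnel_overrides",
                    "limit_dose_clearance")
POD_FIELDS <- c("endpoint", "pod_type", "value", "units", "tier",
                "no_response", "study_note", "ivive")
SCENARIO_SET_FIELDS <- c("schema_version", "duration", "plan", "scenarios")
SCENARIO_FIELDS <- c("scenario_id", "route", "population", "estimation_tiers",
                     "doses", "absorption", "inhaled_volume")

#' Substance dossier
#'
#' The structured input of the engine: identity, TTC flags, points of
#' departure grouped by tier (with pre-IVIVE µM records already converted
#' on construction), expert category/DNEL overrides (each carrying a
#' mandatory provenance note) and per-duration limit-dose clearance flags.
#'
#' @param substance_id,name Identifying strings.
#' @param ttc_flags A [ttc_flags()] object.
#' @param pod_records List of [pod_record()] objects; records in µM must
#'   carry an attached `conversion` ([conversion_spec()]) or be converted
#'   beforehand.
#' @param overrides List of expert endpoint-category overrides, each a list
#'   with `endpoint`, `tier`, `category` (integer or `"not_classified"`)
#'   and a non-empty `note`.
#' @param dnel_overrides List of expert-assigned DNELs, each with `tier`,
#'   `value` and a non-empty `note`.
#' @param limit_dose_clearance Named logical list per duration class:
#'   a tier-3+/conventional limit-dose study confirmed no relevant
#'   toxicity (supports the Category-A green cell for unclassified
#'   substances).
#' @param identifiers Optional named list of opaque identifier strings
#'   (CAS, SMILES, ...); stored, never parsed.
#' @return A `substance_dossier`.
#' @export
substance_dossier <- function(substance_id, name = substance_id, ttc_flags,
                              pod_records = list(), overrides = list(),
                              dnel_overrides = list(),
                              limit_dose_clearance = list(),
                              identifiers = list()) {
  stopifnot(is.character(substance_id), nzchar(substance_id),
            inherits(ttc_flags, "ttc_flags"))
  for (r in pod_records) {
    if (!inherits(r, "pod_record")) {
      stop("pod_records must be a list of pod_record() objects", call. = FALSE)
    }
  }
  seen <- character(0)
  for (ov in overrides) {
    if (!all(c("endpoint", "tier", "category", "note") %in% names(ov)) ||
        is.null(ov$note) || !nzchar(ov$note)) {
      stop("every category override needs endpoint, tier, category and a provenance note",
           call. = FALSE)
    }
    ov$endpoint <- match.arg(ov$endpoint, ENDPOINTS)
    ov$tier <- match.arg(ov$tier, TIERS)
    key <- paste(ov$endpoint, ov$tier)
    if (key %in% seen) {
      stop(sprintf("duplicate override for %s", key), call. = FALSE)
    }
    seen <- c(seen, key)
  }
  dnel_overrides <- lapply(dnel_overrides, function(ov) {
    if (!all(c("tier", "value", "note") %in% names(ov)) ||
        is.null(ov$note) || !nzchar(ov$note)) {
      stop("every DNEL override needs tier, value and a provenance note",
           call. = FALSE)
    }
    ov$tier <- match.arg(ov$tier, TIERS)
    ov$value <- as.numeric(as_dose_interval(ov$value))
    ov
  })
  ldc <- stats::setNames(as.list(rep(FALSE, length(DURATIONS))), DURATIONS)
  for (d in names(limit_dose_clearance)) {
    d <- match.arg(d, DURATIONS)
    ldc[[d]] <- isTRUE(limit_dose_clearance[[d]])
  }
  structure(
    list(schema_version = DOSSIER_SCHEMA_VERSION,
         substance_id = substance_id, name = name,
         identifiers = identifiers, ttc_flags = ttc_flags,
         pod_records = pod_records, overrides = overrides,
         dnel_overrides = dnel_overrides, limit_dose_clearance = ldc),
    class = "substance_dossier")
}

#' @export
print.substance_dossier <- function(x, ...) {
  cat("<substance dossier> ", x$substance_id,
      if (!identical(x$name, x$substance_id)) paste0(" (", x$name, ")"),
      "\n", sep = "")
  cat("  TTC basis flags: genotox=", x$ttc_flags$genotoxic_alert,
      ", OP/carbamate=", x$ttc_flags$op_or_carbamate,
      ", Cramer ", x$ttc_flags$cramer_class, "\n", sep = "")
  tiers <- vapply(x$pod_records, `[[`, "", "tier")
  for (t in intersect(TIERS, unique(tiers))) {
    cat("  ", t, ": ", sum(tiers == t), " PoD record(s)\n", sep = "")
  }
  if (length(x$overrides)) {
    cat("  ", length(x$overrides), " expert category override(s)\n", sep = "")
  }
  if (length(x$dnel_overrides)) {
    cat("  ", length(x$dnel_overrides), " expert DNEL override(s)\n", sep = "")
  }
  invisible(x)
}

#' Exposure scenario set
#'
#' A duration class, the ordered assessment plan, and the per-scenario
#' exposure estimates keyed by exposure step.
#'
#' @param duration Duration class shared by the scenarios.
#' @param plan Ordered list of steps, each `list(exposure_step =,
#'   hazard_tier =)`; these are the only steps [assess()] will replay.
#' @param scenarios List of scenarios, each with `scenario_id`, `route`,
#'   `doses` (named list: exposure step -> `list(value =, units =)`), and
#'   optional `population`, `absorption`, `inhaled_volume`.
#' @return A `scenario_set`.
#' @export
scenario_set <- function(duration, plan, scenarios) {
  duration <- match.arg(duration, DURATIONS)
  plan <- lapply(plan, function(s) {
    stopifnot(!is.null(s$exposure_step), !is.null(s$hazard_tier))
    s$hazard_tier <- match.arg(s$hazard_tier, TIERS)
    s[c("exposure_step", "hazard_tier")]
  })
  scenarios <- lapply(scenarios, function(sc) {
    if (is.null(sc$scenario_id) || !nzchar(sc$scenario_id)) {
      stop("every scenario needs a scenario_id", call. = FALSE)
    }
    sc$route <- match.arg(sc$route %||% "oral", c("oral", "dermal", "inhalation"))
    if (is.null(sc$absorption)) {
      sc$absorption <- list(oral = 1, dermal = 1, inhalation = 1)
    }
    sc$doses <- lapply(sc$doses, function(d) {
      if (is.numeric(d)) d <- list(value = d, units = "mg/kg/day")
      if (is.null(d$units)) d$units <- "mg/kg/day"
      if (!d$units %in% c("mg/kg/day", "ug/kg/day", "mg/m3")) {
        stop(sprintf("unsupported exposure units '%s'", d$units), call. = FALSE)
      }
      if (identical(d$units, "ug/kg/day")) {
        d$value <- d$value / 1000
        d$units <- "mg/kg/day"
      }
      v <- as_dose_interval(d$value)
      list(value = c(v$lo, v$hi), units = d$units)
    })
    sc
  })
  structure(list(schema_version = DOSSIER_SCHEMA_VERSION, duration = duration,
                 plan = plan, scenarios = scenarios),
            class = "scenario_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_structured <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

check_fields <- function(x, allowed, what) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown %s field(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

check_schema_version <- function(x, what) {
  v <- x$schema_version
  if (is.null(v) || !identical(as.integer(v), DOSSIER_SCHEMA_VERSION)) {
    stop(sprintf("%s schema_version must be %d", what, DOSSIER_SCHEMA_VERSION),
         call. = FALSE)
  }
}

dossier_from_list <- function(x) {
  check_schema_version(x, "dossier")
  check_fields(x, DOSSIER_FIELDS, "dossier")
  if (is.null(x$substance_id)) stop("dossier needs a substance_id", call. = FALSE)
  tf <- x$ttc %||% list()
  check_fields(tf, c("genotoxic_alert", "op_or_carbamate", "cramer_class",
                     "in_domain"), "ttc")
  flags <- ttc_flags(genotoxic_alert = tf$genotoxic_alert %||% FALSE,
                     op_or_carbamate = tf$op_or_carbamate %||% FALSE,
                     cramer_class = tf$cramer_class %||% "unknown",
                     in_ttc_domain = tf$in_domain %||% TRUE)
  pods <- lapply(x$pod_records %||% list(), function(p) {
    check_fields(p, POD_FIELDS, "pod_record")
    rec <- pod_record(endpoint = p$endpoint, pod_type = p$pod_type,
                      value = if (is.null(p$value)) NULL else unlist(p$value),
                      tier = p$tier, units = p$units %||% "mg/kg/day",
                      no_response = p$no_response %||% FALSE,
                      study_note = p$study_note)
    if (is_pre_ivive(rec)) {
      iv <- p$ivive
      if (is.null(iv)) {
        stop(sprintf("µM record for %s/%s has no ivive conversion spec",
                     p$endpoint, p$tier), call. = FALSE)
      }
      spec <- if (identical(iv$mode, "fixed_factor")) {
        conversion_spec("fixed_factor", factor = iv$factor)
      } else {
        conversion_spec("steady_state",
                        params = do.call(kinetic_parameters, iv$params))
      }
      rec <- convert_pod(rec, spec)
    }
    rec
  })
  substance_dossier(
    substance_id = x$substance_id, name = x$name %||% x$substance_id,
    ttc_flags = flags, pod_records = pods,
    overrides = lapply(x$overrides %||% list(), function(ov) {
      if (identical(ov$category, "not_classified")) ov$category <- NA_integer_
      ov
    }),
    dnel_overrides = lapply(x$dnel_overrides %||% list(), function(ov) {
      ov$value <- unlist(ov$value)
      ov
    }),
    limit_dose_clearance = x$limit_dose_clearance %||% list(),
    identifiers = x$identifiers %||% list())
}

#' Read a substance dossier from YAML or JSON
#'
#' Validates the schema (unknown fields are rejected with field-level
#' messages), normalises all dose units to mg/kg/day and applies the
#' attached IVIVE conversion to any µM record, so the returned dossier is
#' in canonical form.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A [substance_dossier()].
#' @export
read_dossier <- function(path) {
  dossier_from_list(read_structured(path))
}

dossier_to_list <- function(dossier) {
  list(
    schema_version = DOSSIER_SCHEMA_VERSION,
    substance_id = dossier$substance_id,
    name = dossier$name,
    identifiers = dossier$identifiers,
    ttc = list(genotoxic_alert = dossier$ttc_flags$genotoxic_alert,
               op_or_carbamate = dossier$ttc_flags$op_or_carbamate,
               cramer_class = dossier$ttc_flags$cramer_class,
               in_domain = dossier$ttc_flags$in_ttc_domain),
    pod_records = lapply(dossier$pod_records, function(r) {
      out <- list(endpoint = r$endpoint, pod_type = r$pod_type, tier = r$tier,
                  units = r$units)
      if (r$no_response) out$no_response <- TRUE
      else out$value <- c(r$value$lo, r$value$hi)
      if (!is.null(r$study_note)) out$study_note <- r$study_note
      out
    }),
    overrides = lapply(dossier$overrides, function(ov) {
      if (is.na(ov$category)) ov$category <- "not_classified"
      ov[c("endpoint", "tier", "category", "note")]
    }),
    dnel_overrides = lapply(dossier$dnel_overrides, function(ov) {
      ov$value <- as.numeric(as_dose_interval(ov$value))
      ov[c("tier", "value", "note")]
    }),
    limit_dose_clearance = dossier$limit_dose_clearance
  )
}

#' Write a substance dossier
#'
#' Writes the canonical form (all doses in mg/kg/day, µM records already
#' converted); `read_dossier(write_dossier(d, path))` is the identity on
#' canonical dossiers.
#'
#' @param dossier A [substance_dossier()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_dossier <- function(dossier, path) {
  stopifnot(inherits(dossier, "substance_dossier"))
  x <- dossier_to_list(dossier)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' Read an exposure scenario set from YAML or JSON
#'
#' @param path File path.
#' @return A [scenario_set()].
#' @export
read_scenarios <- function(path) {
  x <- read_structured(path)
  scenario_set_from_list(x)
}

scenario_set_from_list <- function(x) {
  check_schema_version(x, "scenario set")
  check_fields(x, SCENARIO_SET_FIELDS, "scenario set")
  for (sc in x$scenarios %||% list()) check_fields(sc, SCENARIO_FIELDS, "scenario")
  scenario_set(duration = x$duration, plan = x$plan %||% list(),
               scenarios = x$scenarios %||% list())
}
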