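#' Render an assessment trajectory as a report
#'
#' `markdown` produces a human-readable report: the derived exposure
#' boundaries with their derivation trace, a hazard table per tier
#' (categories and DNEL, the analogue of the published comparison tables),
#' a per-step decision table per scenario, a text decision matrix with
#' scenario markers, and explicit disclosure of every expert override.
#' Doses are displayed at `sigfigs` significant figures; the `json` twin
#' carries the exact unrounded numbers and re-parses to the trajectory's
#' canonical list form.
#'
#' @param trajectory An `assessment_trajectory` from [assess()].
#' @param format `"markdown"` or `"json"`.
#' @param sigfigs Display precision for the markdown report.
#' @return A character scalar (the document).
#' @export
render_report <- function(trajectory, format = c("markdown", "json"),
                          sigfigs = 2) {
  stopifnot(inherits(trajectory, "assessment_trajectory"))
  format <- match.arg(format)
  if (is.null(trajectory$records) || !nrow(trajectory$records)) {
    stop("cannot render an empty trajectory", call. = FALSE)
  }
  if (format == "json") {
    return(jsonlite::toJSON(trajectory_to_list(trajectory),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  render_markdown_report(trajectory, sigfigs)
}

#' Canonical list form of a trajectory
#'
#' The exact-value representation serialised by the JSON report;
#' `jsonlite::fromJSON(render_report(x, "json"), simplifyVector = FALSE)`
#' equals this list.
#'
#' @param trajectory An `assessment_trajectory`.
#' @return A plain list of plain types.
#' @export
trajectory_to_list <- function(trajectory) {
  rec <- trajectory$records
  list(
    substance_id = trajectory$substance_id,
    duration = trajectory$duration,
    ttc = list(value_ug_kg_day = trajectory$ttc$ttc_value,
               basis = trajectory$ttc$basis),
    boundaries = list(
      a_lower = trajectory$boundaries$a_lower,
      b_interval = as.numeric(trajectory$boundaries$b_interval),
      c_interval = as.numeric(trajectory$boundaries$c_interval),
      d_interval = as.numeric(trajectory$boundaries$d_interval),
      e_upper = trajectory$boundaries$e_upper),
    dnel = lapply(trajectory$profiles, function(p) {
      if (is.null(p$dnel)) NULL else list(
        value = as.numeric(p$dnel$value),
        uncertainty_factor = p$dnel$uncertainty_factor,
        expert_assigned = p$dnel$override_applied)
    }),
    records = lapply(seq_len(nrow(rec)), function(i) {
      r <- as.list(rec[i, ])
      r$hazard_category <- if (is.na(r$hazard_category)) "not_classified"
                           else r$hazard_category
      if (is.na(r$moe)) r$moe <- NULL
      else if (is.infinite(r$moe)) r$moe <- "Inf"
      r
    }),
    terminal = as.list(trajectory$terminal)
  )
}

fmt_display <- function(x, sigfigs) {
  paste0(format_dose(as_dose_interval(x), sigfigs), " mg/kg/day")
}

render_markdown_report <- function(trajectory, sigfigs) {
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  b <- trajectory$boundaries

  push("# Tiered safety assessment: ", trajectory$substance_id)
  push("")
  push("Duration class: ", trajectory$duration,
       ". TTC: ", format(trajectory$ttc$ttc_value), " ug/kg/day (",
       trajectory$ttc$basis, ").")
  push("")
  push("## Exposure category boundaries")
  push("")
  push("| Category | Dose range |")
  push("|---|---|")
  push("| A | > ", fmt_display(b$a_lower, sigfigs), " |")
  push("| B | ", fmt_display(b$b_interval, sigfigs), " |")
  push("| C | ", fmt_display(b$c_interval, sigfigs), " |")
  push("| D | ", fmt_display(b$d_interval, sigfigs), " |")
  push("| E | < ", fmt_display(b$e_upper, sigfigs), " (TTC) |")
  push("")
  push("Derivation trace:")
  push("")
  tr <- b$derivation_trace
  push("| Boundary | Source | Source limit | Factor | Value (mg/kg/day) |")
  push("|---|---|---|---|---|")
  for (i in seq_len(nrow(tr))) {
    push("| ", tr$boundary[i], " | ", tr$source[i], " | ",
         format(tr$source_limit[i]), " | ", format(tr$factor[i]), " | ",
         format(tr$value[i]), " |")
  }
  push("")

  push("## Hazard profile by tier")
  push("")
  eps <- unique(unlist(lapply(trajectory$profiles,
                              function(p) names(p$endpoint_results))))
  tiers <- names(trajectory$profiles)
  push("| Endpoint | ", paste(tiers, collapse = " | "), " |")
  push("|", paste(rep("---|", length(tiers) + 1), collapse = ""))
  for (ep in eps) {
    cells <- vapply(tiers, function(t) {
      r <- trajectory$profiles[[t]]$endpoint_results[[ep]]
      if (is.null(r)) "-"
      else paste0(if (is.na(r$category)) "not classified" else r$category,
                  if (r$override_applied) "*" else "")
    }, "")
    push("| ", ep, " | ", paste(cells, collapse = " | "), " |")
  }
  dnel_cells <- vapply(tiers, function(t) {
    d <- trajectory$profiles[[t]]$dnel
    if (is.null(d)) "-"
    else paste0(fmt_display(d$value, sigfigs), if (d$override_applied) "*")
  }, "")
  push("| DNEL | ", paste(dnel_cells, collapse = " | "), " |")
  push("")

  overrides <- list()
  for (t in tiers) {
    p <- trajectory$profiles[[t]]
    for (r in p$endpoint_results) {
      if (r$override_applied) {
        overrides[[length(overrides) + 1L]] <-
          paste0(t, " / ", r$endpoint, " category: ", r$note)
      }
    }
    if (!is.null(p$dnel) && p$dnel$override_applied) {
      overrides[[length(overrides) + 1L]] <-
        paste0(t, " DNEL expert-assigned: ", p$dnel$note)
    }
  }
  if (length(overrides)) {
    push("Expert overrides (*):")
    push("")
    for (o in overrides) push("* ", o)
    push("")
  }

  push("## Decision trajectory")
  push("")
  rec <- trajectory$records
  push("| Scenario | Step | Exposure step | Hazard tier | Exp. cat | Haz. cat | Colour | MoE | Verdict | Next |")
  push("|", paste(rep("---|", 10), collapse = ""))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    push("| ", r$scenario_id, " | ", r$refinement_step, " | ", r$exposure_step,
         " | ", r$hazard_tier, " | ", r$exposure_category, " | ",
         if (is.na(r$hazard_category)) "NC" else r$hazard_category, " | ",
         r$colour, " | ",
         if (is.na(r$moe)) "-" else format(signif(r$moe, sigfigs)), " | ",
         r$verdict, " | ", r$recommendation, " |")
  }
  push("")

  push("## Matrix positions (final step)")
  push("")
  push(render_matrix_text(trajectory))
  push("")
  push("## Terminal states")
  push("")
  for (id in names(trajectory$terminal)) {
    push("* ", id, ": ", trajectory$terminal[[id]])
  }
  paste(out, collapse = "\n")
}

render_matrix_text <- function(trajectory) {
  cfg <- matrix_config()
  rec <- trajectory$records
  last <- rec[!duplicated(rec$scenario_id, fromLast = TRUE), ]
  marks <- matrix("", 4, 5, dimnames = dimnames(cfg$cells))
  for (i in seq_len(nrow(last))) {
    row <- matrix_hazard_row(last$hazard_category[i])
    col <- last$exposure_category[i]
    marks[row, col] <- paste0(marks[row, col], "(", i, ")")
  }
  lines <- c(paste0("Hazard |", paste(sprintf(" %-14s", EXPOSURE_CATEGORIES),
                                      collapse = "|")))
  lines <- c(lines, paste(rep("-", nchar(lines[1])), collapse = ""))
  for (r in rownames(cfg$cells)) {
    cells <- vapply(EXPOSURE_CATEGORIES, function(cc) {
      sprintf(" %-14s", paste0(cfg$cells[r, cc], marks[r, cc]))
    }, "")
    lines <- c(lines, paste0(sprintf("%-6s", r), " |",
                             paste(cells, collapse = "|")))
  }
  keys <- vapply(seq_len(nrow(last)), function(i) {
    paste0("(", i, ") ", last$scenario_id[i])
  }, "")
  paste(c("```", lines, keys, "```"), collapse = "\n")
}
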