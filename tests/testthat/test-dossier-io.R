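test_that("dossiers round-trip through YAML and JSON in canonical form", {
  g <- generate_random_dossier(101)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_dossier(g$dossier, path)
    back <- read_dossier(path)
    expect_equal(back, g$dossier)
    # write-read-write is stable byte-for-byte
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_dossier(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("schema violations are rejected with field-level messages", {
  base <- list(schema_version = 1, substance_id = "X",
               ttc = list(cramer_class = "I"))
  write_one <- function(x) {
    path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    yaml::write_yaml(x, path)
    path
  }
  bad_field <- base
  bad_field$tonnage <- 100
  expect_error(read_dossier(write_one(bad_field)), "unknown dossier field.*tonnage")
  bad_units <- base
  bad_units$pod_records <- list(list(endpoint = "stot_re", pod_type = "NOAEL",
                                     value = 5, units = "mg/L",
                                     tier = "conventional"))
  expect_error(read_dossier(write_one(bad_units)), "unsupported units 'mg/L'")
  bad_version <- base
  bad_version$schema_version <- 99
  expect_error(read_dossier(write_one(bad_version)), "schema_version")
  no_note <- base
  no_note$overrides <- list(list(endpoint = "stot_re", tier = "conventional",
                                 category = 1))
  expect_error(read_dossier(write_one(no_note)), "provenance note")
  um_no_ivive <- base
  um_no_ivive$pod_records <- list(list(endpoint = "stot_re", pod_type = "NOEL",
                                       value = 5, units = "uM",
                                       tier = "tier2_invitro"))
  expect_error(read_dossier(write_one(um_no_ivive)), "ivive")
})

test_that("micro-dose units normalise to mg/kg/day on input", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, substance_id = "U",
                        ttc = list(cramer_class = "III"),
                        pod_records = list(list(
                          endpoint = "stot_re", pod_type = "NOAEL",
                          value = 500, units = "ug/kg/day",
                          tier = "conventional"))),
                   path)
  d <- read_dossier(path)
  expect_identical(d$pod_records[[1]]$units, "mg/kg/day")
  expect_equal(d$pod_records[[1]]$value$lo, 0.5)
})

test_that("the generator is deterministic and leaves the caller's RNG alone", {
  a <- generate_random_dossier(7)
  b <- generate_random_dossier(7)
  expect_equal(a, b)
  expect_false(isTRUE(all.equal(a, generate_random_dossier(8))))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_random_dossier(7))
  expect_identical(runif(1), before)
  expect_error(generate_random_dossier(1, pod_range = c(2, 2)), "degenerate")
})

test_that("generated inputs cover every exposure and hazard category", {
  bt <- default_band_tables()
  seen_exp <- character(0)
  seen_haz <- integer(0)
  ttc <- assign_ttc(ttc_flags(genotoxic_alert = TRUE))
  b <- derive_boundaries("long_term", ttc = ttc$ttc_mg)
  for (seed in 1:300) {
    g <- generate_random_dossier(seed)
    for (r in g$dossier$pod_records) {
      res <- classify_endpoint(bt[[r$endpoint]], r)
      seen_haz <- union(seen_haz, res$category)
    }
    for (sc in g$scenarios$scenarios) {
      dose <- sc$doses$step1$value
      seen_exp <- union(seen_exp, categorise_dose(dose, b)$category)
    }
    if (all(c("A", "B", "C", "D", "E") %in% seen_exp) &&
        all(1:4 %in% seen_haz)) break
  }
  expect_true(all(c("A", "B", "C", "D", "E") %in% seen_exp))
  expect_true(all(1:4 %in% seen_haz))
})

test_that("generated dossiers satisfy the engine invariants end to end", {
  # cross-module property sweep on seeded synthetic cases
  cd_limit <- c(one_day = 3, short_term = 0.04, long_term = 0.01)
  for (seed in 1:150) {
    g <- generate_random_dossier(seed)
    ttc <- assign_ttc(g$dossier$ttc_flags)
    # a TTC at or above the duration's C/D boundary (e.g. Cramer I, 0.03
    # mg/kg/day, against the long-term boundary of 0.01) collapses the D
    # band and must be refused, not silently mis-categorised
    if (ttc$ttc_mg >= cd_limit[[g$scenarios$duration]]) {
      expect_error(assess(g$dossier, g$scenarios), "C/D boundary")
      next
    }
    tr <- assess(g$dossier, g$scenarios)
    expect_true(all(tr$records$colour %in% c("green", "amber", "red")))
    # amber rows always carry an explicit verdict (MoE forced)
    amber <- tr$records[tr$records$colour == "amber", ]
    expect_false(any(is.na(amber$verdict)))
    # tier-0 passes are green Category E accepts
    t0 <- tr$records[tr$records$hazard_tier == "tier0_ttc", ]
    if (nrow(t0)) {
      expect_true(all(t0$colour == "green" & t0$exposure_category == "E"))
    }
    # every scenario reaches a terminal state
    expect_setequal(names(tr$terminal),
                    vapply(g$scenarios$scenarios, `[[`, "", "scenario_id"))
    expect_true(all(unlist(tr$terminal) %in%
                    c("accept", "reject", "borderline",
                      "insufficient_confidence")))
  }
})

test_that("scenario files round-trip and reject unknown fields", {
  g <- generate_random_dossier(55)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, duration = "short_term",
                        plan = list(list(exposure_step = "s1",
                                         hazard_tier = "tier2_invitro")),
                        scenarios = list(list(scenario_id = "a",
                                              route = "oral",
                                              doses = list(s1 = list(
                                                value = c(1, 2),
                                                units = "mg/kg/day"))))),
                   path)
  sc <- read_scenarios(path)
  expect_s3_class(sc, "scenario_set")
  expect_identical(sc$duration, "short_term")
  expect_equal(sc$scenarios[[1]]$doses$s1$value, c(1, 2))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema_version = 1, duration = "short_term",
                        plan = list(), scenarios = list(),
                        company = "acme"), bad)
  expect_error(read_scenarios(bad), "unknown scenario set field")
})

test_that("reports render in both formats and the JSON twin re-parses exactly", {
  fx <- load_fixture("EC1")
  tr <- assess(fx$dossier, fx$scenarios)
  md <- render_report(tr, "markdown")
  expect_match(md, "0.006 mg/kg/day", fixed = TRUE)
  expect_match(md, "0.04 mg/kg/day", fixed = TRUE)
  expect_match(md, "Expert overrides")
  expect_match(md, "Derivation trace")
  js <- render_report(tr, "json")
  reparsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  canonical <- jsonlite::fromJSON(
    jsonlite::toJSON(trajectory_to_list(tr), auto_unbox = TRUE, digits = NA),
    simplifyVector = FALSE)
  expect_identical(reparsed, canonical)
  empty <- tr
  empty$records <- empty$records[0, ]
  expect_error(render_report(empty), "empty trajectory")
})
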