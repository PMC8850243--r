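# Independent oracle: the CLP-derived dose limits written out as literal
# nested conditions, endpoint by endpoint, with the boundary tie going to
# the more severe category. Deliberately not a table scan.
oracle_classify <- function(endpoint, value) {
  switch(endpoint,
    acute_oral = if (value <= 5) 1 else if (value <= 50) 2 else
      if (value <= 300) 3 else if (value <= 2000) 4 else 5,
    stot_se = if (value <= 300) 1 else if (value <= 2000) 2 else
      if (value <= 5000) 3 else 4,
    dermal_sens = if (value <= 0.1) 1 else if (value <= 10) 2 else
      if (value <= 100) 3 else 4,
    stot_re = if (value <= 10) 1 else if (value <= 100) 2 else
      if (value <= 1000) 3 else 4,
    carcinogenicity = if (value <= 1) 1 else if (value <= 100) 2 else 3,
    reproductive = if (value <= 4) 1 else if (value <= 400) 2 else 3
  )
}

band_pod <- function(endpoint, value, tier = "conventional") {
  type <- if (endpoint == "dermal_sens") "concentration_percent" else "NOAEL"
  units <- if (endpoint == "dermal_sens") "percent" else "mg/kg/day"
  pod_record(endpoint, type, value, tier = tier, units = units)
}

test_that("published worked-example classifications reproduce", {
  bt <- default_band_tables()
  # 90-day NOAEL of 4 mg/kg/day: STOT-RE category 1
  r <- classify_endpoint(bt$stot_re, pod_record("stot_re", "NOAEL", 4,
                                                tier = "tier3_targeted_invivo"))
  expect_identical(r$category, 1L)
  # Hershberger NOEL 25 mg/kg against the ED10 medium-potency band (4-400)
  r <- classify_endpoint(bt$reproductive,
                         pod_record("reproductive", "NOEL", 25,
                                    tier = "tier3_targeted_invivo"))
  expect_identical(r$category, 2L)
  # no tumour response: not classified
  r <- classify_endpoint(bt$carcinogenicity,
                         pod_record("carcinogenicity", "T25", tier = "conventional",
                                    no_response = TRUE))
  expect_true(is.na(r$category))
  # dermal sensitisation no-response maps to category 4, not unclassified
  r <- classify_endpoint(bt$dermal_sens,
                         pod_record("dermal_sens", "concentration_percent",
                                    tier = "conventional", no_response = TRUE))
  expect_identical(r$category, 4L)
})

test_that("boundary values take the more severe category and intervals classify by their lower end", {
  bt <- default_band_tables()
  expect_identical(
    classify_endpoint(bt$stot_se, band_pod("stot_se", 300))$category, 1L)
  # every printed band limit of every endpoint lands in the more severe band
  for (ep in names(bt)) {
    for (i in seq_along(bt[[ep]]$thresholds)) {
      lim <- bt[[ep]]$thresholds[i]
      expect_identical(
        classify_endpoint(bt[[ep]], band_pod(ep, lim))$category,
        bt[[ep]]$categories[i],
        label = sprintf("%s at limit %g", ep, lim))
    }
  }
  # a range like 36-360 classifies by its health-protective lower end
  r <- classify_endpoint(bt$carcinogenicity,
                         pod_record("carcinogenicity", "NOEL", c(36, 360),
                                    tier = "tier2_invitro"))
  expect_identical(r$category, 2L)
})

test_that("classification agrees with the brute-force oracle and is monotone", {
  bt <- default_band_tables()
  set.seed(42)
  for (ep in names(bt)) {
    values <- sort(10^runif(10000 %/% length(bt), -4, 4))
    cats <- vapply(values,
                   function(v) classify_endpoint(bt[[ep]], band_pod(ep, v))$category,
                   integer(1))
    expect_identical(cats,
                     vapply(values, function(v) as.integer(oracle_classify(ep, v)),
                            integer(1)),
                     label = paste("oracle agreement for", ep))
    # monotone: a higher PoD never yields a more severe category
    expect_true(all(diff(cats) >= 0), label = paste("monotone for", ep))
  }
})

test_that("metric mismatches and invalid points of departure are rejected", {
  bt <- default_band_tables()
  expect_error(classify_endpoint(
    bt$stot_re, pod_record("carcinogenicity", "T25", 5, tier = "conventional")),
    "endpoint mismatch")
  # a T25 record re-tagged onto the wrong endpoint is a metric mismatch
  expect_error(classify_endpoint(
    bt$stot_re, pod_record("stot_re", "T25", 5, tier = "conventional")),
    "metric mismatch")
  expect_error(pod_record("stot_re", "NOAEL", 0, tier = "conventional"),
               "positive")
  expect_error(pod_record("stot_re", "NOAEL", -4, tier = "conventional"))
})

test_that("SCL potency bands map high/medium/low to categories 1/2/3", {
  expect_identical(potency_to_category("high"), 1L)
  expect_identical(potency_to_category("medium"), 2L)
  expect_identical(potency_to_category("low"), 3L)
  expect_error(potency_to_category("extreme"))
})

test_that("DNEL derivation divides exactly, preserves intervals, and is linear", {
  pod <- pod_record("stot_re", "NOAEL", 4, tier = "tier3_targeted_invivo")
  expect_equal(derive_dnel(pod)$value$lo, 0.04)
  d <- derive_dnel(pod_record("carcinogenicity", "NOEL", c(36, 360),
                              tier = "tier2_invitro"))
  expect_equal(as.numeric(d$value), c(0.36, 3.6))
  # identity at UF 1
  expect_equal(as.numeric(derive_dnel(pod, 1)$value), c(4, 4))
  # linearity: derive_dnel(k * pod) = k * derive_dnel(pod)
  set.seed(7)
  for (k in 10^runif(50, -3, 3)) {
    scaled <- pod_record("stot_re", "NOAEL", c(4 * k, 40 * k),
                         tier = "conventional")
    base <- pod_record("stot_re", "NOAEL", c(4, 40), tier = "conventional")
    expect_equal(as.numeric(derive_dnel(scaled, 100)$value),
                 k * as.numeric(derive_dnel(base, 100)$value))
  }
  expect_error(derive_dnel(pod, 0), "positive")
  expect_error(derive_dnel(pod_record("carcinogenicity", "T25",
                                      tier = "conventional",
                                      no_response = TRUE)),
               "no-response")
  expect_error(derive_dnel(pod_record("stot_re", "NOEL", 5, units = "uM",
                                      tier = "tier2_invitro")),
               "convert")
})

test_that("the driving PoD is the minimal systemic lower bound with endpoint-order tie-break", {
  # the tier-2 record set of the first worked example
  recs <- list(
    pod_record("reproductive", "NOEL", 0.6, tier = "tier2_invitro"),
    pod_record("stot_re", "NOEL", 2, tier = "tier2_invitro"),
    pod_record("carcinogenicity", "NOEL", 2, tier = "tier2_invitro"),
    pod_record("carcinogenicity", "NOEL", 2, tier = "tier2_invitro"))
  expect_identical(select_driving_pod(recs, "tier2_invitro")$endpoint,
                   "reproductive")
  expect_equal(select_driving_pod(recs, "tier2_invitro")$value$lo, 0.6)
  # single record
  expect_identical(select_driving_pod(recs[2], "tier2_invitro")$endpoint,
                   "stot_re")
  # exhaustive tie-break over all systemic endpoint pairs
  systemic <- c("acute_oral", "stot_se", "stot_re", "carcinogenicity",
                "reproductive")
  for (a in systemic) for (b in systemic) {
    if (a == b) next
    pair <- list(pod_record(a, "NOAEL", 1, tier = "conventional"),
                 pod_record(b, "NOAEL", 1, tier = "conventional"))
    expect_identical(select_driving_pod(pair, "conventional")$endpoint,
                     systemic[min(match(c(a, b), systemic))],
                     label = paste("tie", a, b))
  }
  # dermal sensitisation never drives; empty sets error
  derm <- list(pod_record("dermal_sens", "concentration_percent", 0.05,
                          units = "percent", tier = "conventional"))
  expect_error(select_driving_pod(derm, "conventional"), "no systemic")
  expect_error(select_driving_pod(list(), "conventional"), "no systemic")
})

test_that("band tables validate their shape", {
  expect_error(potency_band_table("stot_re", c(10, 5), 1:2, 3L),
               "strictly increasing")
  expect_error(potency_band_table("stot_re", c(10, 100), c(2, 1), 3L),
               "strictly increasing")
  expect_error(potency_band_table("stot_re", c(-1, 10), 1:2, 3L), "positive")
})
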