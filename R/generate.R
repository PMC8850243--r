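#' Generate a random synthetic dossier and scenario set
#'
#' Property-test input generator. Points of departure are drawn
#' log-uniformly over a range spanning every potency band of every
#' endpoint (default 10^-4 to 10^4 mg/kg/day, against band limits running
#' from 1 to 5000), exposure doses log-uniformly over a range spanning
#' every exposure category from below any TTC to above every Category A
#' limit (default 10^-7 to 10^3 mg/kg/day), TTC flags and duration classes
#' are sampled uniformly. The same seed and configuration always produce
#' an identical output (the generator uses its own RNG stream and does not
#' disturb the caller's).
#'
#' @param seed Integer seed (reproducibility contract).
#' @param n_pods Number of PoD records per tier.
#' @param tiers Tiers to populate.
#' @param n_scenarios Number of exposure scenarios.
#' @param pod_range Log10 range (mg/kg/day) for PoD values.
#' @param dose_range Log10 range (mg/kg/day) for exposure doses.
#' @param interval_prob Probability that a PoD or dose is an interval
#'   rather than a point value.
#' @return List with `dossier` (a [substance_dossier()]) and `scenarios`
#'   (a [scenario_set()] with a one-step plan per populated tier).
#' @export
generate_random_dossier <- function(seed, n_pods = 3,
                                    tiers = c("tier2_invitro",
                                              "tier3_targeted_invivo"),
                                    n_scenarios = 3,
                                    pod_range = c(-4, 4),
                                    dose_range = c(-7, 3),
                                    interval_prob = 0.3) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (diff(pod_range) <= 0 || diff(dose_range) <= 0) {
    stop("degenerate generator range", call. = FALSE)
  }
  tiers <- vapply(tiers, match.arg, "", choices = TIERS)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # 6 significant figures: generated doses survive YAML/JSON round trips
  rlog <- function(n, range) signif(10^stats::runif(n, range[1], range[2]), 6)
  rinterval <- function(range) {
    v <- rlog(1, range)
    if (stats::runif(1) < interval_prob) {
      sort(c(v, signif(v * 10^stats::runif(1, 0, 1), 6)))
    } else {
      v
    }
  }

  systemic <- setdiff(ENDPOINTS, "dermal_sens")
  pods <- list()
  for (tier in tiers) {
    eps <- sample(systemic, n_pods, replace = length(systemic) < n_pods)
    for (ep in eps) {
      pods[[length(pods) + 1L]] <- pod_record(
        endpoint = ep,
        pod_type = sample(c(CANONICAL_METRIC[[ep]], "NOAEL", "NOEL"), 1),
        value = rinterval(pod_range), tier = tier,
        study_note = "synthetic (generated)")
    }
  }

  genotox <- stats::runif(1) < 0.25
  op <- stats::runif(1) < 0.25
  cramer <- sample(c("I", "II", "III"), 1)
  dossier <- substance_dossier(
    substance_id = sprintf("SYN-%06d", as.integer(seed) %% 1000000L),
    name = "synthetic test substance",
    ttc_flags = ttc_flags(genotoxic_alert = genotox, op_or_carbamate = op,
                          cramer_class = cramer),
    pod_records = pods)

  duration <- sample(DURATIONS, 1)
  plan <- lapply(tiers, function(t) list(exposure_step = "step1",
                                         hazard_tier = t))
  scenarios <- lapply(seq_len(n_scenarios), function(i) {
    list(scenario_id = sprintf("scenario_%02d", i),
         route = sample(c("oral", "dermal", "inhalation"), 1),
         doses = list(step1 = list(value = rinterval(dose_range),
                                   units = "mg/kg/day")))
  })

  list(dossier = dossier,
       scenarios = scenario_set(duration, plan, scenarios))
}
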