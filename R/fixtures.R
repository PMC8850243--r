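#' Load a packaged worked-example fixture
#'
#' Three fully worked assessments ship with the package as plain-text
#' fixtures under `extdata/`:
#'
#' * `EC1` -- an anti-androgenic chemical (vinclozolin-like) with a potent
#'   specific mode of action, assessed for three long-term uses across
#'   tier-2 in vitro, tier-3 targeted in vivo and conventional hazard data.
#' * `EC2` -- a benzopyrone (coumarin-like) with mild non-specific
#'   toxicity, assessed for drum filling and household cleaning uses with
#'   tier-2 in vitro + IVIVE and conventional data.
#' * `EC3` -- a preservative (phenoxyethanol-like), hazard assessment only
#'   (no exposure scenarios).
#'
#' Each fixture carries the published input values (points of departure,
#' exposure estimates, IVIVE conversions), the expert overrides required
#' where printed results are not derivable by naive banding (each with a
#' provenance note), synthetic representative doses where only a category
#' was printed (labelled as synthetic in the notes), and an `expected`
#' oracle block with the published categories, DNELs, colours and verdicts
#' used by the test suite.
#'
#' @param name `"EC1"`, `"EC2"` or `"EC3"`.
#' @return A `fixture` list with elements `name`, `description`, `dossier`
#'   (a [substance_dossier()]), `scenarios` (a [scenario_set()] or `NULL`)
#'   and `expected` (the oracle list).
#' @examples
#' fx <- load_fixture("EC1")
#' fx$dossier
#' @export
load_fixture <- function(name) {
  name <- match.arg(toupper(name), c("EC1", "EC2", "EC3"))
  path <- system.file("extdata", paste0(tolower(name), ".yaml"),
                      package = "namtier", mustWork = TRUE)
  x <- yaml::read_yaml(path)
  structure(
    list(name = x$name,
         description = x$description,
         dossier = dossier_from_list(x$dossier),
         scenarios = if (length(x$scenarios$scenarios %||% list())) {
           scenario_set_from_list(x$scenarios)
         },
         expected = x$expected),
    class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture> ", x$name, ": ", x$description, "\n", sep = "")
  print(x$dossier)
  if (!is.null(x$scenarios)) {
    cat("  ", length(x$scenarios$scenarios), " scenario(s), ",
        length(x$scenarios$plan), " assessment step(s), duration ",
        x$scenarios$duration, "\n", sep = "")
  } else {
    cat("  hazard assessment only (no exposure scenarios)\n")
  }
  invisible(x)
}

#' List the packaged fixtures
#'
#' @return Character vector of fixture names.
#' @export
list_fixtures <- function() c("EC1", "EC2", "EC3")
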