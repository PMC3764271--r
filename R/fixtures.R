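#' Path to a shipped example file
#'
#' The package ships editable plain-text fixtures: a Sheffield-like generator
#' configuration (population 530,000), a Helsingborg-style cycling run
#' configuration (population circa 100,000) and six environment-domain
#' interventions.
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A path, or a character vector of file names.
#' @export
#' @examples
#' cvd_example()
#' cvd_example("interventions_environment.yaml")
cvd_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cvdoffset")))
  }
  path <- system.file("extdata", file, package = "cvdoffset")
  if (path == "") abort(sprintf("No shipped example file named \"%s\".", file))
  path
}

#' The Helsingborg cycling intervention
#'
#' Investment in commuting cycling infrastructure in a city of circa 100,000:
#' it reaches the 52% of residents who are cyclists or potential cyclists, is
#' 70% controlled by the municipality (influence score 7/10), acts through
#' the exercise channel on strong evidence, and is scored 100%
#' cost-effective at increasing physical activity.
#'
#' @return An [intervention()].
#' @export
helsingborg_intervention <- function() {
  intervention(
    name = "helsingborg-cycling-infrastructure",
    domain = "environment", sub_domain = "transportation_systems",
    reach_fraction = 0.52, distal_impact = 1, municipal_influence = 7,
    effects = tibble(channel = "exercise", intensity = 1, grade = "strong"),
    cost_effectiveness = 1,
    notes = paste("Commuter cycling infrastructure built at scale in year 1;",
                  "cycle-friendly environments support an order of magnitude",
                  "more cycle commuting than typical UK cities."))
}
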