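#' The six municipal intervention domains
#'
#' @return Character vector: education, economy, housing, security,
#'   environment, health_promotion.
#' @export
intervention_domains <- function() {
  c("education", "economy", "housing", "security", "environment",
    "health_promotion")
}

#' Evidence-grade confidence weights
#'
#' The evidence behind each proximal effect is graded moderate, strong or
#' very strong. Grades are numerified as monotone confidence weights that
#' scale the effect's risk-factor deltas; the defaults (0.5, 0.75, 1.0) are a
#' simple monotone choice and are fully configurable.
#'
#' @param moderate,strong,very_strong Weights in (0, 1\], strictly increasing.
#' @return Named numeric vector of weights.
#' @export
evidence_weights <- function(moderate = 0.5, strong = 0.75, very_strong = 1.0) {
  w <- c(moderate = moderate, strong = strong, very_strong = very_strong)
  if (any(w <= 0) || any(w > 1) || !(w[1] < w[2] && w[2] < w[3])) {
    abort("Evidence weights must lie in (0, 1] and increase: moderate < strong < very_strong.")
  }
  w
}

#' Default behaviour-channel table
#'
#' Per-channel risk-factor shifts at unit intensity. The exercise channel
#' lowers SBP, total cholesterol and BMI (the physiological directions are
#' fixed: parasympathetic tone, endothelial function and lipid metabolism all
#' improve with exercise) and nudges HDL up; stress reduction lowers SBP; diet
#' lowers cholesterol, BMI and SBP; smoking cessation lowers smoking
#' prevalence. Magnitudes are literature-plausible placeholders for an
#' unpublished calibration — they ship as editable data and every report
#' prints the table in force.
#'
#' @return Tibble with one row per channel and delta columns `d_sbp` (mmHg),
#'   `d_tc`, `d_hdl` (mmol/L), `d_bmi` (kg/m^2), `d_smoking`, `d_diabetes`
#'   (prevalence fractions).
#' @export
behaviour_channels <- function() {
  tbl <- tibble(
    channel = c("exercise", "air_quality", "stress", "diet",
                "smoking_cessation"),
    d_sbp      = c(-2.0, -0.5, -1.5, -1.0, 0),
    d_tc       = c(-0.10, 0, 0, -0.15, 0),
    d_hdl      = c(0.05, 0, 0, 0.02, 0),
    d_bmi      = c(-0.30, 0, 0, -0.40, 0),
    d_smoking  = c(0, 0, 0, 0, -0.02),
    d_diabetes = c(0, 0, 0, 0, 0))
  validate_channels(tbl)
}

validate_channels <- function(tbl) {
  tbl <- as_tibble(tbl)
  needed <- c("channel", names(delta_field_map()))
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Channel table is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  ex <- tbl[tbl$channel == "exercise", ]
  if (nrow(ex) == 1 &&
      !(ex$d_sbp < 0 && ex$d_tc < 0 && ex$d_bmi < 0)) {
    abort("The exercise channel must shift SBP, cholesterol and BMI downward.")
  }
  st <- tbl[tbl$channel == "stress", ]
  if (nrow(st) == 1 && st$d_sbp == 0) {
    abort("The stress channel must shift SBP.")
  }
  tbl
}

#' Define a municipal intervention
#'
#' An intervention carries the six assessment metrics used to appraise
#' municipal actions: (1) `reach_fraction` — the fraction of the city
#' population affected; (2) `distal_impact` — the estimated impact on distal
#' determinants, scaled to \[0, 1\]; (3) `municipal_influence` — an integer
#' 1-10 score of how much of the intervention the municipality actually
#' controls versus central government and market forces; (4) the proximal
#' `effects` (behaviour channel, intensity, evidence grade); (5) the evidence
#' grade on each effect, numerified via [evidence_weights()]; and (6)
#' `cost_effectiveness`, scaled to \[0, 1\].
#'
#' @param name Intervention label.
#' @param domain One of [intervention_domains()].
#' @param reach_fraction Fraction of the city population affected, \[0, 1\].
#' @param distal_impact Impact on distal determinants, \[0, 1\].
#' @param municipal_influence Integer score in 1..10.
#' @param effects Data frame with columns `channel`, `intensity` (>= 0) and
#'   `grade` (moderate/strong/very_strong); at least one row.
#' @param cost_effectiveness Score in \[0, 1\].
#' @param sub_domain Optional sub-domain label (for environment:
#'   built_environment, transportation_systems, natural_environment).
#' @param notes Free-text governance context.
#' @return A list of class `intervention`.
#' @export
#' @examples
#' cycling <- intervention(
#'   "cycling-infrastructure", "environment",
#'   reach_fraction = 0.52, distal_impact = 1, municipal_influence = 7,
#'   effects = tibble::tibble(channel = "exercise", intensity = 1,
#'                            grade = "strong"),
#'   cost_effectiveness = 1, sub_domain = "transportation_systems")
intervention <- function(name, domain, reach_fraction, distal_impact,
                         municipal_influence, effects, cost_effectiveness,
                         sub_domain = NA_character_, notes = "") {
  if (!domain %in% intervention_domains()) {
    abort(sprintf("Unknown domain \"%s\"; must be one of: %s.",
                  domain, paste(intervention_domains(), collapse = ", ")))
  }
  check_fraction <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("%s must be a single value in [0, 1].", what))
    }
  }
  check_fraction(reach_fraction, "reach_fraction")
  check_fraction(distal_impact, "distal_impact")
  check_fraction(cost_effectiveness, "cost_effectiveness")
  if (!is.numeric(municipal_influence) || length(municipal_influence) != 1 ||
      municipal_influence != round(municipal_influence) ||
      municipal_influence < 1 || municipal_influence > 10) {
    abort("municipal_influence must be an integer score in 1..10.")
  }
  effects <- as_tibble(effects)
  if (nrow(effects) == 0) {
    abort("An intervention needs at least one proximal effect.")
  }
  missing <- setdiff(c("channel", "intensity", "grade"), names(effects))
  if (length(missing) > 0) {
    abort(sprintf("effects is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(effects$intensity < 0)) abort("Effect intensities must be >= 0.")
  bad_grade <- setdiff(effects$grade, c("moderate", "strong", "very_strong"))
  if (length(bad_grade) > 0) {
    abort(sprintf("Unknown evidence grade(s): %s.",
                  paste(bad_grade, collapse = ", ")))
  }
  structure(
    list(name = name, domain = domain, sub_domain = sub_domain,
         reach_fraction = reach_fraction, distal_impact = distal_impact,
         municipal_influence = as.integer(municipal_influence),
         effects = effects, cost_effectiveness = cost_effectiveness,
         notes = notes),
    class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf(
    "<intervention> %s [%s%s]\n  reach %.0f%%, distal impact %.2f, influence %d/10, cost-effectiveness %.2f\n  %d proximal effect(s): %s\n",
    x$name, x$domain,
    if (is.na(x$sub_domain)) "" else paste0("/", x$sub_domain),
    100 * x$reach_fraction, x$distal_impact, x$municipal_influence,
    x$cost_effectiveness, nrow(x$effects),
    paste(sprintf("%s x%.2g (%s)", x$effects$channel, x$effects$intensity,
                  x$effects$grade), collapse = ", ")))
  invisible(x)
}

#' Read interventions from a YAML or JSON file
#'
#' The document is either a single intervention mapping or a list of them,
#' each with fields `name`, `domain`, `sub_domain`, `reach_fraction`,
#' `distal_impact`, `municipal_influence`,
#' `effects: [{channel, intensity, grade}]`, `cost_effectiveness`, `notes`.
#'
#' @param path Path to the file.
#' @return A list of `intervention` objects.
#' @export
read_interventions <- function(path) {
  doc <- read_structured(path)
  if (!is.null(doc$name)) doc <- list(doc)
  lapply(doc, function(d) {
    effects <- d$effects
    if (is.data.frame(effects)) {
      effects <- as_tibble(effects)
    } else {
      effects <- bind_rows(lapply(effects, as_tibble))
    }
    intervention(
      name = d$name, domain = d$domain,
      sub_domain = d$sub_domain %||% NA_character_,
      reach_fraction = d$reach_fraction, distal_impact = d$distal_impact,
      municipal_influence = d$municipal_influence, effects = effects,
      cost_effectiveness = d$cost_effectiveness, notes = d$notes %||% "")
  })
}

#' Persons effectively reached per stratum
#'
#' The deliverable head count combines three of the assessment metrics
#' multiplicatively: `count * reach_fraction * (municipal_influence / 10) *
#' distal_impact`. The influence score enters as the fraction of the
#' intervention the municipality can actually deliver — the reading that
#' makes a 1-10 influence score operative in a quantitative pipeline.
#'
#' @param iv An `intervention`.
#' @param pop A `city_population`.
#' @return The strata tibble with an appended `affected` column (persons,
#'   real-valued expectations); `sum(out$affected)` is the effective reach.
#' @export
effective_population <- function(iv, pop) {
  stopifnot(inherits(iv, "intervention"), inherits(pop, "city_population"))
  mult <- iv$reach_fraction * (iv$municipal_influence / 10) * iv$distal_impact
  mutate(as_tibble(pop), affected = .data$count * mult)
}

#' Combined risk-factor deltas from an intervention's proximal effects
#'
#' Sums, over the intervention's effects, the channel unit-deltas scaled by
#' intensity and by the evidence-grade confidence weight. Linear in both, so
#' a moderate-evidence effect at weight 0.5 contributes exactly half of what
#' the same effect would at weight 1.
#'
#' @param iv An `intervention`.
#' @param channels Behaviour-channel table as in [behaviour_channels()].
#' @param weights Evidence weights as in [evidence_weights()].
#' @return A [risk_deltas()] object.
#' @export
proximal_deltas <- function(iv, channels = behaviour_channels(),
                            weights = evidence_weights()) {
  stopifnot(inherits(iv, "intervention"))
  channels <- validate_channels(channels)
  totals <- stats::setNames(numeric(length(delta_field_map())),
                            names(delta_field_map()))
  for (i in seq_len(nrow(iv$effects))) {
    eff <- iv$effects[i, ]
    row <- channels[channels$channel == eff$channel, ]
    if (nrow(row) != 1) {
      abort(sprintf("Unknown behaviour channel \"%s\"; defined channels: %s.",
                    eff$channel, paste(channels$channel, collapse = ", ")))
    }
    w <- weights[[eff$grade]]
    for (d in names(totals)) {
      totals[d] <- totals[d] + row[[d]] * eff$intensity * w
    }
  }
  do.call(risk_deltas, as.list(totals))
}

#' Score interventions against a population
#'
#' Echoes the six assessment metrics and derives: `effective_reach` (persons
#' deliverably affected), `deliverability` (influence/10 times distal
#' impact), and the weighted proximal intensity summed per channel. All
#' derived values are reproducible from the intervention plus the population
#' total alone.
#'
#' @param interventions An `intervention` or list of them.
#' @param pop A `city_population`.
#' @param channels,weights Channel table and evidence weights in force.
#' @return A tibble with one scorecard row per intervention.
#' @export
score_interventions <- function(interventions, pop,
                                channels = behaviour_channels(),
                                weights = evidence_weights()) {
  if (inherits(interventions, "intervention")) {
    interventions <- list(interventions)
  }
  stopifnot(inherits(pop, "city_population"))
  purrr::map_dfr(interventions, function(iv) {
    eff <- effective_population(iv, pop)
    wint <- iv$effects
    wint$weighted <- wint$intensity * weights[wint$grade]
    per_channel <- summarise(group_by(wint, .data$channel),
                             weighted_intensity = sum(.data$weighted),
                             .groups = "drop")
    tibble(
      name = iv$name, domain = iv$domain, sub_domain = iv$sub_domain,
      reach_fraction = iv$reach_fraction,
      distal_impact = iv$distal_impact,
      municipal_influence = iv$municipal_influence,
      cost_effectiveness = iv$cost_effectiveness,
      deliverability = (iv$municipal_influence / 10) * iv$distal_impact,
      effective_reach = sum(eff$affected),
      proximal_channels = paste(
        sprintf("%s=%.3g", per_channel$channel,
                per_channel$weighted_intensity), collapse = ";"))
  })
}
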