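#' Default unit costs per admission
#'
#' Health-sector cost per acute admission, EUR, for each event category.
#' The source model publishes no tariff, so these are configurable stand-ins
#' in the range of European acute-admission tariffs; every report echoes the
#' table in force.
#'
#' @return Named numeric vector over [event_categories()], EUR.
#' @export
unit_costs <- function() {
  c(heart_attack = 4500, stroke = 6500, heart_failure = 3800,
    acute_hypoglycaemic_attack = 1200, renal_failure = 5200,
    coronary_bypass = 11000)
}

#' Default case-fatality fractions
#'
#' Fraction of acute events that are fatal, per category. Configurable
#' stand-ins (elective coronary bypass is allowed a near-zero fatality);
#' deaths avoided are derived from events avoided through this table rather
#' than a separate mortality model.
#'
#' @return Named numeric vector over [event_categories()], fractions in
#'   \[0, 1\].
#' @export
case_fatality <- function() {
  c(heart_attack = 0.25, stroke = 0.20, heart_failure = 0.10,
    acute_hypoglycaemic_attack = 0.02, renal_failure = 0.15,
    coronary_bypass = 0.03)
}

#' Define a scenario
#'
#' A scenario bundles a population, a (possibly empty) list of interventions
#' and the parameter packs in force. Running it applies each intervention's
#' causal chain — effective reach, proximal deltas, mixture-mean shift — and
#' projects events.
#'
#' @param population A `city_population`.
#' @param interventions List of `intervention` objects (empty = baseline).
#' @param horizon Years, >= 1.
#' @param coefficients Risk coefficient pack.
#' @param split Event-category split.
#' @param channels Behaviour-channel table.
#' @param weights Evidence-grade weights.
#' @param label Scenario label.
#' @return A list of class `cvd_scenario`.
#' @export
scenario <- function(population, interventions = list(), horizon = 5,
                     coefficients = framingham_coefficients(),
                     split = event_split(),
                     channels = behaviour_channels(),
                     weights = evidence_weights(),
                     label = if (length(interventions) == 0) "baseline"
                             else "intervention") {
  stopifnot(inherits(population, "city_population"))
  if (inherits(interventions, "intervention")) {
    interventions <- list(interventions)
  }
  if (!all(vapply(interventions, inherits, logical(1), "intervention"))) {
    abort("interventions must be intervention objects.")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1) {
    abort("horizon must be >= 1 year.")
  }
  structure(
    list(population = population, interventions = interventions,
         horizon = as.integer(horizon), coefficients = coefficients,
         split = validate_split(split), channels = validate_channels(channels),
         weights = weights, label = label),
    class = "cvd_scenario")
}

# Population after applying every intervention's causal chain.
shifted_population <- function(s) {
  pop <- s$population
  for (iv in s$interventions) {
    eff <- effective_population(iv, pop)
    deltas <- proximal_deltas(iv, channels = s$channels, weights = s$weights)
    pop <- apply_deltas(pop, deltas, eff$affected)
  }
  pop
}

#' Run a scenario
#'
#' Pipeline: for each intervention, compute the effectively reached persons
#' per stratum, translate its proximal effects into risk-factor deltas, and
#' shift stratum means by the mixture rule; then project events for the
#' resulting population. With zero interventions this equals the baseline
#' projection exactly.
#'
#' @param s A [scenario()].
#' @return An `event_projection`.
#' @export
run_scenario <- function(s) {
  stopifnot(inherits(s, "cvd_scenario"))
  project_events(shifted_population(s), coefficients = s$coefficients,
                 split = s$split, horizon = s$horizon, scenario = s$label)
}

#' Compare baseline and intervention scenarios
#'
#' Produces the cost-offset triple: events avoided per category and year
#' (baseline minus treated — negative values from harmful interventions are
#' reported, never clipped), deaths avoided via category case fatality, and
#' cumulative health-sector savings via unit costs, undiscounted by default.
#' When the treated scenario carries interventions, per-intervention shares
#' are attributed by leave-one-out marginal contribution. The report echoes
#' every parameter pack in force.
#'
#' @param baseline,treated Scenarios sharing the same population and horizon.
#' @param costs Unit-cost table, EUR per admission.
#' @param fatality Case-fatality table, fractions.
#' @param discount_rate Annual discount rate applied to future savings;
#'   default 0 (undiscounted).
#' @return A list of class `cost_offset_report` with elements `avoided`
#'   (tibble of category, year, events_avoided), `by_category`, totals
#'   (`events_avoided`, `deaths_avoided`, `savings_eur`), `attribution` and
#'   an `assumptions` echo.
#' @export
compare_scenarios <- function(baseline, treated, costs = unit_costs(),
                              fatality = case_fatality(),
                              discount_rate = 0) {
  stopifnot(inherits(baseline, "cvd_scenario"), inherits(treated, "cvd_scenario"))
  if (!identical(as.data.frame(baseline$population),
                 as.data.frame(treated$population))) {
    abort("Scenarios must share the same population.")
  }
  if (baseline$horizon != treated$horizon) {
    abort("Scenarios must share the same horizon.")
  }
  costs <- validate_category_table(costs, "Unit-cost table")
  fatality <- validate_category_table(fatality, "Case-fatality table",
                                      lower = 0, upper = 1)
  if (discount_rate < 0) abort("discount_rate must be >= 0.")
  proj_base <- run_scenario(baseline)
  proj_trt <- run_scenario(treated)
  avoided <- as_tibble(proj_base)
  avoided$events_avoided <- proj_base$events - proj_trt$events
  avoided$events <- NULL
  discount <- (1 + discount_rate) ^ -(avoided$year - 1)
  avoided$savings_eur <- avoided$events_avoided * costs[avoided$category] *
    discount
  by_category <- summarise(
    group_by(avoided, .data$category),
    events_avoided = sum(.data$events_avoided),
    savings_eur = sum(.data$savings_eur), .groups = "drop")
  by_category$deaths_avoided <-
    by_category$events_avoided * fatality[by_category$category]
  attribution <- NULL
  if (length(treated$interventions) > 0) {
    attribution <- attribute_interventions(baseline, treated)
  }
  structure(
    list(
      avoided = select(avoided, "category", "year", "events_avoided",
                       "savings_eur"),
      by_category = by_category,
      events_avoided = sum(avoided$events_avoided),
      deaths_avoided = sum(by_category$deaths_avoided),
      savings_eur = sum(avoided$savings_eur),
      baseline_events = attr(proj_base, "total"),
      treated_events = attr(proj_trt, "total"),
      attribution = attribution,
      assumptions = list(
        horizon_years = baseline$horizon,
        discount_rate = discount_rate,
        savings_are = "cumulative health-sector savings over the horizon",
        excluded_persons = attr(proj_base, "excluded_persons"),
        risk_age_domain = c(30, 89),
        hazard_conversion = "constant hazard: h = -log(1 - p10)/10; annual events = count * (1 - exp(-h))",
        event_split = as.list(baseline$split),
        unit_costs_eur = as.list(costs),
        case_fatality = as.list(fatality),
        evidence_weights = as.list(treated$weights),
        behaviour_channels = as.data.frame(treated$channels))),
    class = "cost_offset_report")
}

#' Attribute avoided events to individual interventions
#'
#' Leave-one-out marginal contributions: for each intervention, the loss in
#' total events avoided when it is removed from the treated scenario. Shares
#' are normalised to sum to the total events avoided (marginals need not sum
#' to the total when interventions overlap through the nonlinear risk
#' equation; the normalisation is reported alongside the raw marginals).
#'
#' @param baseline,treated Scenarios as in [compare_scenarios()].
#' @return Tibble with `name`, `marginal_events`, `share` and
#'   `events_attributed` (shares times the total avoided).
#' @export
attribute_interventions <- function(baseline, treated) {
  stopifnot(inherits(treated, "cvd_scenario"))
  ivs <- treated$interventions
  if (length(ivs) == 0) abort("The treated scenario has no interventions.")
  total_base <- attr(run_scenario(baseline), "total")
  total_full <- attr(run_scenario(treated), "total")
  total_avoided <- total_base - total_full
  # marginal contribution of iv i = avoided(all) - avoided(all \ i)
  avoided_without <- vapply(seq_along(ivs), function(i) {
    reduced <- treated
    reduced$interventions <- ivs[-i]
    total_base - attr(run_scenario(reduced), "total")
  }, numeric(1))
  marginal <- total_avoided - avoided_without
  denom <- sum(marginal)
  share <- if (abs(denom) > 1e-12) marginal / denom
           else rep(1 / length(ivs), length(ivs))
  tibble(
    name = vapply(ivs, function(iv) iv$name, character(1)),
    marginal_events = marginal,
    share = share,
    events_attributed = share * total_avoided)
}

#' @export
print.cost_offset_report <- function(x, ...) {
  cat(sprintf(
    paste0("<cost_offset_report> over %d year(s):\n",
           "  events avoided: %.1f (baseline %.1f -> treated %.1f)\n",
           "  deaths avoided: %.1f\n",
           "  savings: EUR %s\n"),
    x$assumptions$horizon_years, x$events_avoided, x$baseline_events,
    x$treated_events, x$deaths_avoided,
    format(round(x$savings_eur), big.mark = ",")))
  if (!is.null(x$attribution) && nrow(x$attribution) > 1) {
    cat("  attribution:\n")
    for (i in seq_len(nrow(x$attribution))) {
      cat(sprintf("    %s: %.1f%%\n", x$attribution$name[i],
                  100 * x$attribution$share[i]))
    }
  }
  invisible(x)
}
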