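#' Tidy an event projection
#'
#' @param x An `event_projection`.
#' @param ... Unused.
#' @return Tibble of `scenario`, `category`, `year`, `events`.
#' @method tidy event_projection
#' @export
tidy.event_projection <- function(x, ...) {
  mutate(as_tibble(x), scenario = attr(x, "scenario"), .before = 1)
}

#' One-row summary of an event projection
#'
#' @param x An `event_projection`.
#' @param ... Unused.
#' @return Tibble with scenario label, horizon, total expected events,
#'   expected events per year and persons outside the risk-age domain.
#' @method glance event_projection
#' @export
glance.event_projection <- function(x, ...) {
  tibble(
    scenario = attr(x, "scenario"),
    horizon_years = attr(x, "horizon"),
    total_events = attr(x, "total"),
    events_per_year = attr(x, "total") / attr(x, "horizon"),
    excluded_persons = attr(x, "excluded_persons"))
}

#' Tidy a cost-offset report
#'
#' @param x A `cost_offset_report`.
#' @param ... Unused.
#' @return Tibble of `category`, `year`, `events_avoided`, `savings_eur`.
#' @method tidy cost_offset_report
#' @export
tidy.cost_offset_report <- function(x, ...) {
  x$avoided
}

#' One-row summary of a cost-offset report
#'
#' @param x A `cost_offset_report`.
#' @param ... Unused.
#' @return Tibble with the headline triple (events avoided, deaths avoided,
#'   savings) plus baseline/treated totals and the horizon.
#' @method glance cost_offset_report
#' @export
glance.cost_offset_report <- function(x, ...) {
  tibble(
    horizon_years = x$assumptions$horizon_years,
    baseline_events = x$baseline_events,
    treated_events = x$treated_events,
    events_avoided = x$events_avoided,
    deaths_avoided = x$deaths_avoided,
    savings_eur = x$savings_eur)
}

#' Plot an event projection
#'
#' Stacked yearly expected admissions by event category.
#'
#' @param object An `event_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_projection
#' @export
autoplot.event_projection <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$year), y = .data$events,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("Expected acute admissions: %s", attr(object, "scenario")),
      x = "Year", y = "Expected events", fill = "Category") +
    ggplot2::theme_minimal()
}

#' Plot a cost-offset report
#'
#' Events avoided per category, summed over the horizon.
#'
#' @param object A `cost_offset_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cost_offset_report
#' @export
autoplot.cost_offset_report <- function(object, ...) {
  ggplot2::ggplot(object$by_category,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  .data$events_avoided),
                               y = .data$events_avoided)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("Events avoided over %d year(s): %.0f (EUR %s saved)",
                      object$assumptions$horizon_years, object$events_avoided,
                      format(round(object$savings_eur), big.mark = ",")),
      x = NULL, y = "Events avoided") +
    ggplot2::theme_minimal()
}

#' Population pyramid plot
#'
#' @param pop A `city_population`.
#' @return A ggplot object with male counts to the left, female to the right.
#' @export
plot_population_pyramid <- function(pop) {
  stopifnot(inherits(pop, "city_population"))
  d <- mutate(as_tibble(pop),
              band = sprintf("%d-%d", .data$age_lo, .data$age_hi - 1L),
              signed = ifelse(.data$sex == "male", -.data$count, .data$count))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$band, .data$age_lo),
    y = .data$signed, fill = .data$sex)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(v) format(abs(v),
                                                            big.mark = ",")) +
    ggplot2::labs(title = attr(pop, "name"), x = "Age band", y = "Persons",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
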