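#' Default ten-year cardiovascular risk coefficient pack
#'
#' The sex-specific general cardiovascular disease risk function of
#' D'Agostino and colleagues (2008): log-hazard coefficients on ln(age),
#' ln(total cholesterol), ln(HDL), ln(SBP) (separately for treated and
#' untreated hypertension), smoking and diabetes indicators, with the
#' published 10-year baseline survival and mean linear predictor per sex.
#' Packs are data, not code: alternative calibrations load from YAML/JSON via
#' [read_coefficients()] and plug into every downstream operation.
#'
#' Profile cholesterol is in mmol/L; the published coefficients expect mg/dL,
#' so the pack carries the conversion factor (38.67 mg/dL per mmol/L). An
#' optional `lbmi` term is supported for packs that use ln(BMI); the default
#' pack sets it to zero.
#'
#' @return A list of class `risk_coefficients` with elements `male`, `female`
#'   (each containing `coef`, `s0_10`, `mean_lp`) and `tc_mgdl_per_mmol`.
#' @export
framingham_coefficients <- function() {
  new_risk_coefficients(list(
    male = list(
      coef = c(lage = 3.06117, ltc = 1.12370, lhdl = -0.93263,
               lsbp_untreated = 1.93303, lsbp_treated = 1.99881,
               smoking = 0.65451, diabetes = 0.57367, lbmi = 0),
      s0_10 = 0.88936, mean_lp = 23.9802),
    female = list(
      coef = c(lage = 2.32888, ltc = 1.20904, lhdl = -0.70833,
               lsbp_untreated = 2.76157, lsbp_treated = 2.82263,
               smoking = 0.52873, diabetes = 0.69154, lbmi = 0),
      s0_10 = 0.95012, mean_lp = 26.1931),
    tc_mgdl_per_mmol = 38.67))
}

required_coef_names <- function() {
  c("lage", "ltc", "lhdl", "lsbp_untreated", "lsbp_treated",
    "smoking", "diabetes")
}

new_risk_coefficients <- function(x) {
  for (sex in c("male", "female")) {
    p <- x[[sex]]
    if (is.null(p) || is.null(p$coef) || is.null(p$s0_10) ||
        is.null(p$mean_lp)) {
      abort(sprintf("Coefficient pack is missing the %s block.", sex))
    }
    p$coef <- unlist(p$coef)
    missing <- setdiff(required_coef_names(), names(p$coef))
    if (length(missing) > 0) {
      abort(sprintf("Coefficient pack (%s) is missing terms: %s.",
                    sex, paste(missing, collapse = ", ")))
    }
    if (!("lbmi" %in% names(p$coef))) p$coef[["lbmi"]] <- 0
    if (!is.finite(p$s0_10) || p$s0_10 <= 0 || p$s0_10 >= 1) {
      abort(sprintf("Baseline survival for %s must lie in (0, 1).", sex))
    }
    x[[sex]] <- p
  }
  x$tc_mgdl_per_mmol <- x$tc_mgdl_per_mmol %||% 38.67
  structure(x, class = "risk_coefficients")
}

#' Read a coefficient pack from YAML or JSON
#'
#' The document must carry `male` and `female` blocks, each with `coef`
#' (named terms `lage`, `ltc`, `lhdl`, `lsbp_untreated`, `lsbp_treated`,
#' `smoking`, `diabetes`, optional `lbmi`), `s0_10` and `mean_lp`, plus an
#' optional `tc_mgdl_per_mmol` conversion factor.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `risk_coefficients` pack.
#' @export
read_coefficients <- function(path) {
  new_risk_coefficients(read_structured(path))
}

read_structured <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Ten-year cardiovascular risk at stratum means
#'
#' Evaluates the sex-specific risk equation at mean risk-factor levels: the
#' probability is `1 - S0(10)^exp(LP - mean_lp)` with the linear predictor
#' built from ln(age), ln(cholesterol terms) and ln(SBP). Smoking, diabetes
#' and treated-hypertension prevalences enter as fractional indicator values
#' (the expected value of the individual indicator), which is the mean-level
#' application the model is built on: the SBP term is the
#' treated-prevalence-weighted mix of the treated and untreated coefficients.
#'
#' @param data Data frame with columns `age` (years, in \[30, 89\]), `sex`,
#'   `sbp`, `tc`, `hdl`, `smoking`, `diabetes`, `treated_htn` and optionally
#'   `bmi` (used only by packs with a nonzero `lbmi` term).
#' @param coefficients A `risk_coefficients` pack.
#' @return The input as a tibble with an appended `risk10` column in (0, 1).
#' @export
#' @examples
#' ten_year_risk(tibble::tibble(
#'   age = 61, sex = "male", sbp = 130, tc = 5.2, hdl = 1.2,
#'   smoking = 1, diabetes = 0, treated_htn = 0))
ten_year_risk <- function(data, coefficients = framingham_coefficients()) {
  stopifnot(inherits(coefficients, "risk_coefficients"))
  data <- as_tibble(data)
  needed <- c("age", "sex", "sbp", "tc", "hdl", "smoking", "diabetes",
              "treated_htn")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(sprintf("ten_year_risk() needs columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(data$age < 30 | data$age > 89)) {
    abort("age must lie in [30, 89]: the risk equations are not defined outside it.")
  }
  bad <- profile_violations(
    mutate(data, age_lo = as.integer(.data$age), age_hi = as.integer(.data$age) + 1L,
           bmi = if ("bmi" %in% names(data)) .data$bmi else 25))
  if (length(bad) > 0) {
    abort(paste0("Invalid risk-factor profile:\n  ",
                 paste(bad, collapse = "\n  ")))
  }
  mutate(data, risk10 = risk10_vec(data, coefficients))
}

# Vectorised core of the risk equation; assumes validated inputs.
risk10_vec <- function(data, coefficients) {
  out <- numeric(nrow(data))
  fac <- coefficients$tc_mgdl_per_mmol
  bmi <- if ("bmi" %in% names(data)) data$bmi else rep(25, nrow(data))
  for (sex in c("male", "female")) {
    idx <- which(data$sex == sex)
    if (length(idx) == 0) next
    p <- coefficients[[sex]]
    b <- p$coef
    lsbp <- log(data$sbp[idx])
    lp <- b[["lage"]] * log(data$age[idx]) +
      b[["ltc"]] * log(data$tc[idx] * fac) +
      b[["lhdl"]] * log(data$hdl[idx] * fac) +
      ((1 - data$treated_htn[idx]) * b[["lsbp_untreated"]] +
         data$treated_htn[idx] * b[["lsbp_treated"]]) * lsbp +
      b[["smoking"]] * data$smoking[idx] +
      b[["diabetes"]] * data$diabetes[idx] +
      b[["lbmi"]] * log(bmi[idx])
    out[idx] <- 1 - p$s0_10 ^ exp(lp - p$mean_lp)
  }
  out
}

#' Convert ten-year risk to a constant annual hazard
#'
#' Under a constant-hazard assumption, `h = -log(1 - p10) / 10`, so that
#' `1 - exp(-10 h)` recovers the ten-year probability exactly. The one-year
#' event probability is then `1 - exp(-h)`.
#'
#' @param p10 Ten-year risk(s) in \[0, 1).
#' @return Annual hazard(s), per year.
#' @export
#' @examples
#' annual_hazard(0.2)          # -log(0.8) / 10
#' annual_hazard(1 - exp(-1))  # exactly 0.1
annual_hazard <- function(p10) {
  if (any(!is.finite(p10)) || any(p10 < 0) || any(p10 >= 1)) {
    abort("p10 must lie in [0, 1): a ten-year risk of 1 implies infinite hazard.")
  }
  -log(1 - p10) / 10
}

#' Default event-category split
#'
#' Allocation of total expected acute CVD events across the six admission
#' categories. The model's source calibration is unpublished, so this split is
#' an explicit, configurable stand-in with plausible admission shares; every
#' report echoes the split in force.
#'
#' @return Named numeric vector over [event_categories()], summing to 1.
#' @export
event_split <- function() {
  c(heart_attack = 0.30, stroke = 0.25, heart_failure = 0.20,
    acute_hypoglycaemic_attack = 0.08, renal_failure = 0.07,
    coronary_bypass = 0.10)
}

validate_split <- function(split) {
  split <- validate_category_table(split, "Event split", lower = 0, upper = 1)
  if (abs(sum(split) - 1) > 1e-9) {
    abort(sprintf("Event split must sum to 1; it sums to %.12f.", sum(split)))
  }
  split
}

#' Project expected acute events for a population
#'
#' For every stratum whose age-band midpoint lies in the risk equations'
#' domain (\[30, 89\] years), the expected events per year are
#' `count * (1 - exp(-h))` with `h` the annual hazard from the stratum's
#' ten-year risk evaluated at the band midpoint. Strata outside the domain
#' (e.g. an under-30 band) contribute zero events and are reported in the
#' projection's `excluded_persons` attribute — the all-ages total is kept for
#' accounting while the risk arithmetic stays inside its valid range. Events
#' are spread over categories by the split; the population is treated as
#' closed and static, so yearly expectations are constant over the horizon.
#'
#' @param pop A `city_population`.
#' @param coefficients A `risk_coefficients` pack.
#' @param split Event-category split summing to 1.
#' @param horizon Projection horizon in whole years, >= 1.
#' @param scenario Label stored on the projection.
#' @return An `event_projection`: a tibble of (`category`, `year`, `events`)
#'   with attributes `total`, `horizon`, `scenario`, `excluded_persons`.
#' @export
project_events <- function(pop, coefficients = framingham_coefficients(),
                           split = event_split(), horizon = 5,
                           scenario = "baseline") {
  stopifnot(inherits(pop, "city_population"))
  split <- validate_split(split)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != round(horizon)) {
    abort("horizon must be a whole number of years >= 1.")
  }
  horizon <- as.integer(horizon)
  strata <- as_tibble(pop)
  mid <- (strata$age_lo + strata$age_hi) / 2
  in_domain <- mid >= 30 & mid <= 89
  annual_total <- 0
  if (any(in_domain & strata$count > 0)) {
    d <- strata[in_domain, ]
    d$age <- mid[in_domain]
    p10 <- risk10_vec(d, coefficients)
    h <- annual_hazard(p10)
    annual_total <- sum(d$count * (1 - exp(-h)))
  }
  grid <- tidyr::expand_grid(category = event_categories(),
                             year = seq_len(horizon))
  grid$events <- annual_total * split[grid$category]
  structure(as_tibble(grid),
            total = annual_total * horizon,
            horizon = horizon,
            scenario = scenario,
            excluded_persons = sum(strata$count[!in_domain]),
            class = c("event_projection", class(grid)))
}

#' @export
print.event_projection <- function(x, ...) {
  cat(sprintf(
    "<event_projection> %s: %.1f expected events over %d year(s) (%s persons outside the risk-age domain)\n",
    attr(x, "scenario"), attr(x, "total"), attr(x, "horizon"),
    format(attr(x, "excluded_persons"), big.mark = ",")))
  NextMethod()
}

#' Additive risk-factor shifts
#'
#' @param d_sbp Shift in mean systolic blood pressure, mmHg.
#' @param d_tc Shift in mean total cholesterol, mmol/L.
#' @param d_hdl Shift in mean HDL cholesterol, mmol/L.
#' @param d_bmi Shift in mean BMI, kg/m^2.
#' @param d_smoking Shift in smoking prevalence (fraction).
#' @param d_diabetes Shift in diabetes prevalence (fraction).
#' @return A named list of class `risk_deltas`.
#' @export
risk_deltas <- function(d_sbp = 0, d_tc = 0, d_hdl = 0, d_bmi = 0,
                        d_smoking = 0, d_diabetes = 0) {
  x <- list(d_sbp = d_sbp, d_tc = d_tc, d_hdl = d_hdl, d_bmi = d_bmi,
            d_smoking = d_smoking, d_diabetes = d_diabetes)
  if (any(!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1)))) {
    abort("All deltas must be single finite numbers.")
  }
  structure(x, class = "risk_deltas")
}

delta_field_map <- function() {
  c(d_sbp = "sbp", d_tc = "tc", d_hdl = "hdl", d_bmi = "bmi",
    d_smoking = "smoking", d_diabetes = "diabetes")
}

#' Apply risk-factor shifts to part of each stratum
#'
#' When only `affected` of a stratum's `count` persons receive the full shift,
#' the stratum mean moves by `delta * affected / count` — the mixture mean of
#' the shifted and unshifted sub-populations. Shifted profiles must still
#' satisfy the invariant ranges; violations raise an error naming the stratum
#' and field rather than clamping.
#'
#' @param pop A `city_population`.
#' @param deltas A [risk_deltas()] object.
#' @param affected Persons affected per stratum: a single number recycled, or
#'   a vector with one entry per stratum; each entry must not exceed the
#'   stratum count.
#' @return A new `city_population` with shifted means.
#' @export
apply_deltas <- function(pop, deltas, affected) {
  stopifnot(inherits(pop, "city_population"), inherits(deltas, "risk_deltas"))
  strata <- as_tibble(pop)
  n <- nrow(strata)
  if (length(affected) == 1) affected <- rep(affected, n)
  if (length(affected) != n) {
    abort("affected must have one entry per stratum (or be a single number).")
  }
  if (any(!is.finite(affected)) || any(affected < 0)) {
    abort("affected counts must be finite and non-negative.")
  }
  over <- which(affected > strata$count)
  if (length(over) > 0) {
    abort(sprintf(
      "affected exceeds stratum count in stratum [%d,%d) %s (%.1f > %d).",
      strata$age_lo[over[1]], strata$age_hi[over[1]], strata$sex[over[1]],
      affected[over[1]], strata$count[over[1]]))
  }
  coverage <- ifelse(strata$count > 0, affected / strata$count, 0)
  map <- delta_field_map()
  for (d in names(map)) {
    strata[[map[[d]]]] <- strata[[map[[d]]]] + deltas[[d]] * coverage
  }
  bad <- profile_violations(strata)
  if (length(bad) > 0) {
    abort(paste0("Shifted profile breaks invariants (clamping is not applied):\n  ",
                 paste(bad, collapse = "\n  ")))
  }
  city_population(strata, name = attr(pop, "name"))
}
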