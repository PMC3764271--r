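#' Construct a stratified city population
#'
#' A city population is a tibble of non-overlapping age-band-by-sex strata.
#' Each stratum carries a head count and the mean risk-factor profile the risk
#' engine evaluates: systolic blood pressure (mmHg), total and HDL cholesterol
#' (mmol/L), body mass index (kg/m^2), and prevalences of smoking, diabetes and
#' treated hypertension (fractions in \[0, 1\]).
#'
#' @param strata Data frame with columns `age_lo`, `age_hi`, `sex`
#'   (`"female"`/`"male"`), `count`, `sbp`, `tc`, `hdl`, `bmi`, `smoking`,
#'   `diabetes`, `treated_htn`. Age bands are half-open `[age_lo, age_hi)`.
#' @param name Label for the population.
#'
#' @return A tibble of class `city_population` with a `name` attribute;
#'   `population_total()` gives the summed head count.
#' @export
#' @examples
#' pop <- city_population(tibble::tibble(
#'   age_lo = 40, age_hi = 65, sex = "male", count = 1000,
#'   sbp = 130, tc = 5.2, hdl = 1.2, bmi = 27,
#'   smoking = 0.2, diabetes = 0.05, treated_htn = 0.1))
#' population_total(pop)
city_population <- function(strata, name = "city") {
  required <- c("age_lo", "age_hi", "sex", "count", profile_fields())
  missing <- setdiff(required, names(strata))
  if (length(missing) > 0) {
    abort(sprintf("Population is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  strata <- as_tibble(strata)[required]
  if (nrow(strata) == 0) {
    abort("Population must contain at least one stratum.")
  }
  strata$age_lo <- as.integer(strata$age_lo)
  strata$age_hi <- as.integer(strata$age_hi)
  if (any(is.na(strata$age_lo)) || any(is.na(strata$age_hi))) {
    abort("Age band bounds must be integers.")
  }
  if (any(strata$age_lo >= strata$age_hi) ||
      any(strata$age_lo < 0) || any(strata$age_hi > 120)) {
    abort("Age bands must satisfy 0 <= age_lo < age_hi <= 120.")
  }
  if (!all(strata$sex %in% c("female", "male"))) {
    abort("sex must be \"female\" or \"male\".")
  }
  if (any(!is.finite(strata$count)) || any(strata$count < 0) ||
      any(strata$count != round(strata$count))) {
    abort("Stratum counts must be non-negative integers.")
  }
  strata$count <- as.integer(strata$count)
  overlap <- find_overlaps(strata)
  if (!is.null(overlap)) {
    abort(sprintf(
      "Overlapping strata: rows %d and %d both cover ages in [%d,%d) for sex %s.",
      overlap$i, overlap$j, overlap$lo, overlap$hi, overlap$sex))
  }
  bad <- profile_violations(strata)
  if (length(bad) > 0) {
    abort(paste0("Invalid risk-factor profile:\n  ",
                 paste(bad, collapse = "\n  ")))
  }
  structure(strata, name = name,
            class = c("city_population", class(strata)))
}

# First overlapping pair of strata within a sex, or NULL.
find_overlaps <- function(strata) {
  for (s in unique(strata$sex)) {
    idx <- which(strata$sex == s)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        i <- idx[a]; j <- idx[b]
        lo <- max(strata$age_lo[i], strata$age_lo[j])
        hi <- min(strata$age_hi[i], strata$age_hi[j])
        if (lo < hi) return(list(i = i, j = j, lo = lo, hi = hi, sex = s))
      }
    }
  }
  NULL
}

#' Total head count of a population
#'
#' @param pop A `city_population`.
#' @return Integer total of all stratum counts.
#' @export
population_total <- function(pop) {
  stopifnot(inherits(pop, "city_population"))
  sum(pop$count)
}

#' @export
print.city_population <- function(x, ...) {
  cat(sprintf("<city_population> %s: %s persons in %d strata\n",
              attr(x, "name"), format(sum(x$count), big.mark = ","), nrow(x)))
  NextMethod()
}

#' Default age/sex pyramid for a European city
#'
#' Seven 10-year age bands per sex (an under-30 band plus 30-39 through 80-89)
#' with fractions patterned on a large UK city: roughly 40% under 30, a
#' working-age majority, and a female surplus at older ages. Fractions sum to
#' one.
#'
#' @return Tibble with columns `age_lo`, `age_hi`, `sex`, `fraction`.
#' @export
default_pyramid <- function() {
  bands <- tibble(
    age_lo = c(0L, 30L, 40L, 50L, 60L, 70L, 80L),
    age_hi = c(30L, 40L, 50L, 60L, 70L, 80L, 90L))
  male   <- c(0.205, 0.073, 0.065, 0.060, 0.049, 0.033, 0.014)
  female <- c(0.195, 0.072, 0.065, 0.060, 0.051, 0.037, 0.021)
  bind_rows(
    mutate(bands, sex = "male", fraction = male),
    mutate(bands, sex = "female", fraction = female))
}

#' Default risk-factor age ramps
#'
#' Linear mean risk-factor trajectories: the value at age 30 plus a per-decade
#' slope, per sex. Magnitudes follow typical European adult survey levels
#' (mean SBP rising ~5 mmHg per decade, cholesterol ~0.2 mmol/L per decade,
#' declining smoking prevalence with age, rising diabetes and treated
#' hypertension).
#'
#' @return Tibble with columns `sex`, `factor`, `base` (value at age 30) and
#'   `slope` (change per decade of age).
#' @export
default_risk_ramps <- function() {
  tibble(
    sex = rep(c("male", "female"), each = 7),
    factor = rep(profile_fields(), 2),
    base  = c(122, 5.0, 1.25, 26.0, 0.28, 0.030, 0.05,
              116, 4.9, 1.55, 25.0, 0.24, 0.025, 0.05),
    slope = c(4.5, 0.20, 0.00, 0.50, -0.030, 0.020, 0.07,
              5.5, 0.25, 0.00, 0.60, -0.025, 0.018, 0.07))
}

#' Default stratum-level jitter standard deviations
#'
#' Gaussian noise added to stratum mean risk factors when generating synthetic
#' populations, truncated to the profile invariant ranges. These are
#' between-stratum SDs of *means*, so they are much smaller than
#' individual-level SDs.
#'
#' @return Named numeric vector, one SD per risk factor.
#' @export
default_jitter_sd <- function() {
  c(sbp = 2, tc = 0.1, hdl = 0.05, bmi = 0.3,
    smoking = 0.01, diabetes = 0.005, treated_htn = 0.01)
}

#' Configuration for the synthetic population generator
#'
#' @param total_population Total head count to allocate across strata.
#' @param pyramid Tibble of `age_lo`, `age_hi`, `sex`, `fraction`; fractions
#'   must be non-negative and sum to 1 (tolerance 1e-9).
#' @param ramps Either a tibble of linear age ramps as in
#'   [default_risk_ramps()], or a full per-stratum means table carrying the
#'   profile columns alongside `age_lo`, `age_hi`, `sex`.
#' @param jitter_sd Named vector of Gaussian jitter SDs per risk factor; use
#'   zeros to disable jitter.
#' @param seed Master random seed; per-stratum substreams are derived from it
#'   by a stable hash of the stratum key, so counts never depend on the seed
#'   and profiles are reproducible stratum by stratum.
#' @param name Population label.
#'
#' @return A validated list of class `population_config`.
#' @export
population_config <- function(total_population,
                              pyramid = default_pyramid(),
                              ramps = default_risk_ramps(),
                              jitter_sd = default_jitter_sd(),
                              seed = 1L,
                              name = "synthetic-city") {
  if (!is.numeric(total_population) || length(total_population) != 1 ||
      !is.finite(total_population) || total_population < 0 ||
      total_population != round(total_population)) {
    abort("total_population must be a single non-negative integer.")
  }
  pyramid <- as_tibble(pyramid)
  needed <- c("age_lo", "age_hi", "sex", "fraction")
  if (!all(needed %in% names(pyramid))) {
    abort("pyramid needs columns age_lo, age_hi, sex, fraction.")
  }
  bad <- which(!is.finite(pyramid$fraction) | pyramid$fraction < 0)
  if (length(bad) > 0) {
    abort(sprintf("Invalid pyramid fraction in entry [%d,%d) %s: %s.",
                  pyramid$age_lo[bad[1]], pyramid$age_hi[bad[1]],
                  pyramid$sex[bad[1]], format(pyramid$fraction[bad[1]])))
  }
  total_frac <- sum(pyramid$fraction)
  if (abs(total_frac - 1) > 1e-9) {
    abort(sprintf("Pyramid fractions must sum to 1; they sum to %.12f.",
                  total_frac))
  }
  jitter_sd <- jitter_sd[profile_fields()]
  names(jitter_sd) <- profile_fields()
  jitter_sd[is.na(jitter_sd)] <- 0
  structure(
    list(total_population = as.integer(total_population), pyramid = pyramid,
         ramps = as_tibble(ramps), jitter_sd = jitter_sd,
         seed = as.integer(seed), name = name),
    class = "population_config")
}

# Largest-remainder allocation of an integer total over fractions.
# Ties broken by entry order; conserves the total exactly.
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  counts <- base
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    top <- order_rem[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

# Evaluate ramp means at the age-band midpoint, truncated to invariant ranges.
ramp_means <- function(ramps, age_lo, age_hi, sex) {
  mid <- (age_lo + age_hi) / 2
  bounds <- profile_bounds()
  out <- numeric(length(profile_fields()))
  names(out) <- profile_fields()
  for (field in profile_fields()) {
    row <- ramps[ramps$sex == sex & ramps$factor == field, ]
    if (nrow(row) != 1) {
      abort(sprintf("Ramp table needs exactly one (%s, %s) entry.", sex, field))
    }
    v <- row$base + row$slope * (mid - 30) / 10
    out[field] <- min(max(v, bounds[[field]][1]), bounds[[field]][2])
  }
  out
}

#' Generate a synthetic stratified city population
#'
#' Allocates the configured total across the age/sex pyramid by
#' largest-remainder rounding (the total is conserved exactly for every
#' pyramid), evaluates mean risk factors at each band midpoint from the age
#' ramps (or takes them from a per-stratum means table), and adds truncated
#' Gaussian jitter. Each stratum draws its jitter from a substream seeded by a
#' stable hash of (age band, sex) combined with the master seed, so equal
#' configurations produce bit-identical populations.
#'
#' @param config A [population_config()].
#' @return A [city_population()].
#' @export
#' @examples
#' pop <- generate_population(population_config(100000, seed = 7))
#' population_total(pop)
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  pyr <- config$pyramid
  counts <- largest_remainder(pyr$fraction, config$total_population)
  per_stratum_means <- all(profile_fields() %in% names(config$ramps))
  bounds <- profile_bounds()
  rows <- vector("list", nrow(pyr))
  for (i in seq_len(nrow(pyr))) {
    if (per_stratum_means) {
      m <- config$ramps
      hit <- m$age_lo == pyr$age_lo[i] & m$age_hi == pyr$age_hi[i] &
        m$sex == pyr$sex[i]
      if (sum(hit) != 1) {
        abort(sprintf("Means table needs exactly one row for [%d,%d) %s.",
                      pyr$age_lo[i], pyr$age_hi[i], pyr$sex[i]))
      }
      means <- unlist(m[hit, profile_fields()])
    } else {
      means <- ramp_means(config$ramps, pyr$age_lo[i], pyr$age_hi[i],
                          pyr$sex[i])
    }
    sub <- stratum_seed(config$seed, pyr$age_lo[i], pyr$age_hi[i], pyr$sex[i])
    noise <- withr::with_seed(sub, stats::rnorm(length(means)))
    vals <- means + noise * config$jitter_sd[profile_fields()]
    for (f in profile_fields()) {
      vals[f] <- min(max(vals[f], bounds[[f]][1]), bounds[[f]][2])
    }
    rows[[i]] <- tibble(
      age_lo = pyr$age_lo[i], age_hi = pyr$age_hi[i], sex = pyr$sex[i],
      count = counts[i], !!!as.list(vals))
  }
  city_population(bind_rows(rows), name = config$name)
}

#' Read a stratified population from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns `age_lo`,
#' `age_hi`, `sex`, `count`, `sbp`, `tc`, `hdl`, `bmi`, `smoking`, `diabetes`,
#' `treated_htn`. Invariant violations (overlapping strata, out-of-range
#' values, non-numeric cells) are rejected with informative errors, never
#' silently clamped.
#'
#' @param path Path to the CSV file.
#' @param name Population label; defaults to the file name.
#' @return A [city_population()].
#' @export
read_population <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Population file not found: %s", path))
  }
  spec <- readr::cols(
    age_lo = readr::col_integer(), age_hi = readr::col_integer(),
    sex = readr::col_character(), count = readr::col_double(),
    sbp = readr::col_double(), tc = readr::col_double(),
    hdl = readr::col_double(), bmi = readr::col_double(),
    smoking = readr::col_double(), diabetes = readr::col_double(),
    treated_htn = readr::col_double())
  strata <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE))
  probs <- readr::problems(strata)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in %s at row(s) %s: non-numeric or malformed cells.",
                  path, paste(unique(probs$row), collapse = ", ")))
  }
  if (nrow(strata) == 0) {
    abort("Population must contain at least one stratum (file has header only).")
  }
  city_population(strata, name = name %||% basename(path))
}

#' Write a population to CSV
#'
#' Writes the strata table with full numeric precision so that
#' `read_population()` round-trips field-by-field.
#'
#' @param pop A `city_population`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "city_population"))
  readr::write_csv(as_tibble(pop), path, progress = FALSE)
  invisible(path)
}

#' Persons eligible for an intervention
#'
#' Applies an eligibility fraction to the whole-population total with half-up
#' rounding; e.g. a 5% exceptions rule gives eligibility 0.95.
#'
#' @param pop A `city_population`.
#' @param eligibility_fraction Fraction in \[0, 1\].
#' @return Integer person count.
#' @export
#' @examples
#' pop <- generate_population(population_config(530000))
#' eligible_count(pop, 0.95)
eligible_count <- function(pop, eligibility_fraction) {
  stopifnot(inherits(pop, "city_population"))
  if (!is.numeric(eligibility_fraction) || length(eligibility_fraction) != 1 ||
      is.na(eligibility_fraction) || eligibility_fraction < 0 ||
      eligibility_fraction > 1) {
    abort("eligibility_fraction must be a single value in [0, 1].")
  }
  as.integer(round_half_up(population_total(pop) * eligibility_fraction))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
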