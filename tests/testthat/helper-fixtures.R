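# Shared builders for small in-code fixtures.

# One homogeneous stratum with a fully specified mean profile.
homogeneous_pop <- function(count = 1000, age_lo = 50, age_hi = 60,
                            sex = "male", sbp = 135, tc = 5.5, hdl = 1.3,
                            bmi = 27, smoking = 0.2, diabetes = 0.06,
                            treated_htn = 0.15, name = "test") {
  city_population(tibble::tibble(
    age_lo = age_lo, age_hi = age_hi, sex = sex, count = count,
    sbp = sbp, tc = tc, hdl = hdl, bmi = bmi, smoking = smoking,
    diabetes = diabetes, treated_htn = treated_htn), name = name)
}

# Small multi-stratum population with deterministic, valid profiles.
multi_pop <- function(counts = c(400, 300, 200, 100)) {
  bands <- list(c(30L, 40L), c(40L, 50L), c(50L, 60L), c(60L, 70L))
  rows <- lapply(seq_along(counts), function(i) {
    tibble::tibble(
      age_lo = bands[[i]][1], age_hi = bands[[i]][2],
      sex = if (i %% 2 == 0) "female" else "male", count = counts[i],
      sbp = 120 + 5 * i, tc = 4.8 + 0.2 * i, hdl = 1.2 + 0.05 * i,
      bmi = 25 + 0.5 * i, smoking = 0.25 - 0.02 * i,
      diabetes = 0.02 + 0.01 * i, treated_htn = 0.05 + 0.03 * i)
  })
  city_population(dplyr::bind_rows(rows), name = "multi")
}

# Random valid risk profile rows for property tests (plain tibble with age/sex).
random_profiles <- function(n) {
  tibble::tibble(
    age = stats::runif(n, 30, 89),
    sex = sample(c("male", "female"), n, replace = TRUE),
    sbp = stats::runif(n, 95, 190),
    tc = stats::runif(n, 3.5, 8),
    hdl = stats::runif(n, 0.8, 2.5),
    bmi = stats::runif(n, 20, 35),
    smoking = stats::runif(n),
    diabetes = stats::runif(n),
    treated_htn = stats::runif(n))
}

# Random small population (2-5 strata, valid by construction).
random_pop <- function() {
  k <- sample(2:5, 1)
  cuts <- sort(sample(seq(30L, 85L, by = 5L), k + 1))
  rows <- lapply(seq_len(k), function(i) {
    tibble::tibble(
      age_lo = cuts[i], age_hi = cuts[i + 1],
      sex = sample(c("male", "female"), 1),
      count = sample(50:2000, 1),
      sbp = stats::runif(1, 100, 180), tc = stats::runif(1, 4, 7.5),
      hdl = stats::runif(1, 0.9, 2.2), bmi = stats::runif(1, 21, 33),
      smoking = stats::runif(1, 0, 0.6), diabetes = stats::runif(1, 0, 0.3),
      treated_htn = stats::runif(1, 0, 0.6))
  })
  city_population(dplyr::bind_rows(rows), name = "random")
}

# Random intervention with beneficial (default-channel) effects.
random_intervention <- function(name = "iv") {
  intervention(
    name = name, domain = sample(intervention_domains(), 1),
    reach_fraction = stats::runif(1, 0.05, 1),
    distal_impact = stats::runif(1, 0.2, 1),
    municipal_influence = sample(1:10, 1),
    effects = tibble::tibble(
      channel = sample(c("exercise", "stress", "diet"), 1),
      intensity = stats::runif(1, 0.1, 1.5),
      grade = sample(c("moderate", "strong", "very_strong"), 1)),
    cost_effectiveness = stats::runif(1))
}
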