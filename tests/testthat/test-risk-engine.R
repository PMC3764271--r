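# Zero-coefficient pack: risk collapses to 1 - baseline survival.
null_pack <- function(s0 = 0.95) {
  zero <- c(lage = 0, ltc = 0, lhdl = 0, lsbp_untreated = 0,
            lsbp_treated = 0, smoking = 0, diabetes = 0, lbmi = 0)
  pack <- framingham_coefficients()
  pack$male$coef <- zero; pack$male$s0_10 <- s0; pack$male$mean_lp <- 0
  pack$female$coef <- zero; pack$female$s0_10 <- s0; pack$female$mean_lp <- 0
  pack
}

test_that("zero linear predictor leaves only the baseline survival", {
  r <- ten_year_risk(random_profiles(5), coefficients = null_pack(0.95))
  expect_equal(r$risk10, rep(0.05, 5), tolerance = 1e-12)
})

test_that("the default pack reproduces independently computed risks", {
  # Frozen from a hand evaluation of the published coefficient arithmetic
  # (mean-level application, mmol/L inputs converted at 38.67 mg/dL per mmol/L).
  fixtures <- tibble::tribble(
    ~age, ~sex, ~sbp, ~tc, ~hdl, ~smoking, ~diabetes, ~treated_htn, ~expected,
    61, "male",   130, 5.2,        1.2,        1.00, 0.00, 0.00, 0.284331621073422,
    61, "female", 124, 180/38.67,  47/38.67,   1.00, 0.00, 0.00, 0.104841802037200,
    72, "male",   145, 6.1,        1.0,        0.25, 0.10, 0.40, 0.512880318541036,
    45, "female", 118, 4.8,        1.6,        0.15, 0.05, 0.10, 0.027243109372928,
    55, "male",   160, 5.8,        1.3,        0.00, 1.00, 1.00, 0.388523138839142,
    67, "female", 135, 5.5,        1.4,        0.30, 0.08, 0.25, 0.140792765275859)
  r <- ten_year_risk(fixtures)
  expect_equal(r$risk10, fixtures$expected, tolerance = 1e-10)
})

test_that("risk is monotone in each factor with the expected sign", {
  base <- tibble::tibble(age = 61, sex = "male", sbp = 130, tc = 5.2,
                         hdl = 1.2, smoking = 0.3, diabetes = 0.1,
                         treated_htn = 0.2)
  r0 <- ten_year_risk(base)$risk10
  expect_gt(ten_year_risk(dplyr::mutate(base, sbp = 150))$risk10, r0)
  expect_gt(ten_year_risk(dplyr::mutate(base, tc = 6.5))$risk10, r0)
  expect_gt(ten_year_risk(dplyr::mutate(base, age = 70))$risk10, r0)
  expect_gt(ten_year_risk(dplyr::mutate(base, smoking = 0.6))$risk10, r0)
  expect_gt(ten_year_risk(dplyr::mutate(base, diabetes = 0.3))$risk10, r0)
  expect_lt(ten_year_risk(dplyr::mutate(base, hdl = 1.8))$risk10, r0)
})

test_that("age and profile domains are enforced", {
  good <- random_profiles(1)
  expect_error(ten_year_risk(dplyr::mutate(good, age = 25)), "\\[30, 89\\]")
  expect_error(ten_year_risk(dplyr::mutate(good, sbp = 400)), "sbp")
  bad_pack <- framingham_coefficients()
  bad_pack$male$coef <- bad_pack$male$coef[-1]
  expect_error(new_pack <- cvdoffset:::new_risk_coefficients(unclass(bad_pack)),
               "missing terms")
})

test_that("annual hazard inverts the ten-year risk in closed form", {
  expect_identical(annual_hazard(0), 0)
  expect_equal(annual_hazard(1 - exp(-1)), 0.1, tolerance = 1e-14)
  expect_equal(annual_hazard(0.2), 0.0223143551314210, tolerance = 1e-14)
  expect_error(annual_hazard(1), "infinite hazard")
  expect_error(annual_hazard(-0.1), "\\[0, 1\\)")
})

test_that("projection is zero for empty strata and linear in counts", {
  empty <- homogeneous_pop(count = 0)
  proj <- project_events(empty, horizon = 3)
  expect_true(all(proj$events == 0))
  expect_equal(attr(proj, "total"), 0)

  pop <- multi_pop()
  doubled <- city_population(dplyr::mutate(tibble::as_tibble(pop),
                                           count = count * 2L))
  p1 <- project_events(pop)
  p2 <- project_events(doubled)
  expect_equal(p2$events, 2 * p1$events, tolerance = 1e-12)
})

test_that("a homogeneous stratum equals n times the single-person expectation", {
  n <- 5000L
  pop_n <- homogeneous_pop(count = n)
  pop_1 <- homogeneous_pop(count = 1L)
  pn <- project_events(pop_n, horizon = 4)
  p1 <- project_events(pop_1, horizon = 4)
  expect_equal(attr(pn, "total"), n * attr(p1, "total"), tolerance = 1e-9)
})

test_that("projection totals are invariant under split permutation", {
  pop <- multi_pop()
  split <- event_split()
  shuffled <- split[c(4, 2, 6, 1, 3, 5)]
  t1 <- attr(project_events(pop, split = split), "total")
  t2 <- attr(project_events(pop, split = shuffled), "total")
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_error(project_events(pop, split = split * 2), "sum to 1")
})

test_that("strata outside the risk-age domain contribute zero and are reported", {
  young <- homogeneous_pop(count = 800, age_lo = 0, age_hi = 30,
                           sex = "female")
  adult <- homogeneous_pop(count = 1200, age_lo = 40, age_hi = 50,
                           sex = "female")
  both <- city_population(dplyr::bind_rows(tibble::as_tibble(young),
                                           tibble::as_tibble(adult)))
  p_both <- project_events(both)
  p_adult <- project_events(adult)
  expect_equal(attr(p_both, "total"), attr(p_adult, "total"),
               tolerance = 1e-12)
  expect_equal(attr(p_both, "excluded_persons"), 800)
})

test_that("apply_deltas implements the mixture mean and refuses to clamp", {
  pop <- multi_pop()
  same <- apply_deltas(pop, risk_deltas(), affected = pop$count)
  expect_equal(as.data.frame(same), as.data.frame(pop))

  full <- apply_deltas(pop, risk_deltas(d_sbp = -4), affected = pop$count)
  expect_equal(full$sbp, pop$sbp - 4, tolerance = 1e-12)

  half <- apply_deltas(pop, risk_deltas(d_sbp = -4), affected = pop$count / 2)
  expect_equal(half$sbp, pop$sbp - 2, tolerance = 1e-12)

  expect_error(apply_deltas(pop, risk_deltas(d_sbp = -4),
                            affected = pop$count + 1), "exceeds stratum count")
  low <- homogeneous_pop(sbp = 71)
  expect_error(apply_deltas(low, risk_deltas(d_sbp = -4),
                            affected = low$count),
               "clamping is not applied")
})
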