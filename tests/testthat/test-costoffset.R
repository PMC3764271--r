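test_that("a scenario without interventions reproduces the raw projection", {
  pop <- multi_pop()
  s <- scenario(pop, horizon = 5)
  expect_equal(tibble::as_tibble(run_scenario(s)),
               tibble::as_tibble(project_events(pop, horizon = 5)))

  iv <- helsingborg_intervention()
  iv$effects$intensity <- 0
  s0 <- scenario(pop, iv, horizon = 5)
  expect_equal(attr(run_scenario(s0), "total"),
               attr(run_scenario(s), "total"), tolerance = 1e-12)
})

test_that("avoided events are near-linear in reach in the small-delta regime", {
  pop <- generate_population(population_config(100000, seed = 20))
  base <- scenario(pop)
  full <- helsingborg_intervention()
  half <- full
  half$reach_fraction <- full$reach_fraction / 2
  a_full <- glance(compare_scenarios(base, scenario(pop, full)))$events_avoided
  a_half <- glance(compare_scenarios(base, scenario(pop, half)))$events_avoided
  expect_equal(a_half, a_full / 2, tolerance = 0.01)
})

test_that("self-comparison yields zeros and savings follow the dot product", {
  pop <- multi_pop()
  base <- scenario(pop)
  rep0 <- compare_scenarios(base, base)
  expect_true(all(abs(rep0$avoided$events_avoided) < 1e-12))
  expect_equal(rep0$savings_eur, 0)
  expect_equal(rep0$deaths_avoided, 0)

  trt <- scenario(pop, helsingborg_intervention())
  costs <- unit_costs()
  rep <- compare_scenarios(base, trt, costs = costs)
  by_cat <- rep$by_category
  expect_equal(rep$savings_eur,
               sum(by_cat$events_avoided * costs[by_cat$category]),
               tolerance = 1e-9)
  expect_equal(rep$deaths_avoided,
               sum(by_cat$events_avoided * case_fatality()[by_cat$category]),
               tolerance = 1e-9)

  rep2 <- compare_scenarios(base, trt, costs = costs * 2)
  expect_equal(rep2$savings_eur, 2 * rep$savings_eur, tolerance = 1e-9)
  expect_equal(rep2$events_avoided, rep$events_avoided, tolerance = 1e-12)
})

test_that("mismatched scenarios are rejected", {
  a <- scenario(multi_pop())
  b <- scenario(multi_pop(counts = c(1, 2, 3, 4)))
  expect_error(compare_scenarios(a, b), "same population")
  c5 <- scenario(multi_pop(), horizon = 5)
  c3 <- scenario(multi_pop(), horizon = 3)
  expect_error(compare_scenarios(c5, c3), "same horizon")
})

test_that("harmful interventions produce negative avoided values, unclipped", {
  pop <- multi_pop()
  channels <- behaviour_channels()
  # negative intensity is disallowed at construction; a harmful direction is
  # expressed through the channel table instead
  expect_error(intervention(
    "stressor", "economy", 1, 1, 10,
    effects = tibble::tibble(channel = "stress", intensity = -1,
                             grade = "very_strong"),
    cost_effectiveness = 0), "intensities")
  channels$d_sbp[channels$channel == "stress"] <- +1.5
  trt <- scenario(pop, intervention(
    "stressor", "economy", 1, 1, 10,
    effects = tibble::tibble(channel = "stress", intensity = 1,
                             grade = "very_strong"),
    cost_effectiveness = 0), channels = channels)
  base <- scenario(pop, channels = channels)
  rep <- compare_scenarios(base, trt)
  expect_lt(rep$events_avoided, 0)
  expect_lt(rep$savings_eur, 0)
})

test_that("discounting shrinks savings but not events", {
  pop <- multi_pop()
  base <- scenario(pop)
  trt <- scenario(pop, helsingborg_intervention())
  undisc <- compare_scenarios(base, trt)
  disc <- compare_scenarios(base, trt, discount_rate = 0.035)
  expect_lt(disc$savings_eur, undisc$savings_eur)
  expect_equal(disc$events_avoided, undisc$events_avoided, tolerance = 1e-12)
})

test_that("attribution shares are symmetric and sum to the total avoided", {
  pop <- generate_population(population_config(50000, seed = 4))
  iv1 <- helsingborg_intervention()
  iv2 <- helsingborg_intervention()
  iv2$name <- "twin"
  base <- scenario(pop)

  single <- attribute_interventions(base, scenario(pop, iv1))
  expect_equal(single$share, 1)

  both <- scenario(pop, list(iv1, iv2))
  attr2 <- attribute_interventions(base, both)
  expect_equal(attr2$share[1], attr2$share[2], tolerance = 1e-9)
  total <- glance(compare_scenarios(base, both))$events_avoided
  expect_equal(sum(attr2$events_attributed), total, tolerance = 1e-9)
})

test_that("tidiers and plots expose the report surface", {
  pop <- multi_pop()
  base <- scenario(pop)
  trt <- scenario(pop, helsingborg_intervention())
  rep <- compare_scenarios(base, trt)
  td <- tidy(rep)
  expect_named(td, c("category", "year", "events_avoided", "savings_eur"))
  expect_equal(nrow(td), 6 * 5)
  gl <- glance(rep)
  expect_equal(gl$baseline_events - gl$treated_events, gl$events_avoided,
               tolerance = 1e-9)
  proj <- run_scenario(base)
  expect_s3_class(autoplot(proj), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_population_pyramid(pop), "ggplot")
  expect_named(glance(proj),
               c("scenario", "horizon_years", "total_events",
                 "events_per_year", "excluded_persons"))
})
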