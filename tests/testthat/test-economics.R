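test_that("discount factor follows annual compounding", {
  expect_equal(discount_factor(0, 0.03), 1.0)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0), 1.0)
  expect_error(discount_factor(-1, 0.03), "non-negative")
})

test_that("currency conversion applies the purchasing-power parity", {
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(100000), 8510)
  expect_equal(convert_currency(1), 0.0851)
})

test_that("QALYs equal life-years with unit values and no discounting", {
  men <- toy_men(2, death_age = c(80, 62.5))
  ev <- data.frame(man_id = c(1L, 1L), age = c(55, 59),
                   event = "screen_visit", detail = "psa")
  run <- toy_run(men, ev)
  q <- accumulate_qalys(run, NULL, unit_utilities(), rate = 0)
  expect_equal(q$qalys, q$life_years)
  expect_equal(q$life_years, c(45, 27.5))
})

test_that("a one-year state contributes norm times multiplier", {
  men <- toy_men(1, death_age = 36)
  ev <- data.frame(man_id = 1L, age = 35, event = "screen_visit",
                   detail = "psa")
  st <- default_utility_states()
  st <- lapply(st, function(s) { s$mult <- 1; s })
  st$screening <- list(mult = 0.9, duration = 1)
  ut <- utility_table(population_norm = flat_norm(0.8), states = st)
  q <- accumulate_qalys(toy_run(men, ev), NULL, ut, rate = 0)
  expect_equal(q$qalys, 0.72)
})

test_that("disjoint sub-year states sum by hand over a two-year horizon", {
  men <- toy_men(1, death_age = 37)
  ev <- data.frame(man_id = c(1L, 1L), age = c(35, 35.5),
                   event = c("screen_visit", "biopsy"),
                   detail = c("psa", "screen"))
  st <- lapply(default_utility_states(), function(s) { s$mult <- 1; s })
  st$screening <- list(mult = 0.9, duration = 0.5)
  st$biopsy <- list(mult = 0.7, duration = 0.5)
  ut <- utility_table(population_norm = flat_norm(1), states = st)
  q <- accumulate_qalys(toy_run(men, ev), NULL, ut, rate = 0)
  expect_equal(q$qalys, 0.45 + 0.35 + 1.0)
})

test_that("overlapping states resolve to the minimum multiplier", {
  men <- toy_men(1, death_age = 36)
  ev <- data.frame(man_id = c(1L, 1L), age = c(35, 35),
                   event = c("screen_visit", "biopsy"),
                   detail = c("psa", "screen"))
  st <- lapply(default_utility_states(), function(s) { s$mult <- 1; s })
  st$screening <- list(mult = 0.9, duration = 1)
  st$biopsy <- list(mult = 0.7, duration = 1)
  ut <- utility_table(population_norm = flat_norm(1), states = st)
  q <- accumulate_qalys(toy_run(men, ev), NULL, ut, rate = 0)
  expect_equal(q$qalys, 0.7)
})

test_that("single screening events carry the printed unit costs", {
  men <- toy_men(1, death_age = 80)
  ct <- cost_table()
  run_psa <- toy_run(men, data.frame(man_id = 1L, age = 35,
                                     event = "screen_visit", detail = "psa"))
  c_psa <- accumulate_costs(run_psa, NULL, ct, rate = 0)
  expect_equal(c_psa$screening, 58)
  run_s3m <- toy_run(men, data.frame(man_id = 1L, age = 35,
                                     event = "screen_visit", detail = "s3m"))
  c_s3m <- accumulate_costs(run_s3m, NULL, ct, rate = 0)
  expect_equal(c_s3m$screening, 255)
  expect_equal(ct$s3m_assay, 196)
  run_sx <- toy_run(men, data.frame(man_id = 1L, age = 35,
                                    event = "symptomatic_dx",
                                    detail = "2_biopsies"))
  c_sx <- accumulate_costs(run_sx, NULL, ct, rate = 0)
  expect_equal(c_sx$diagnosis, 2 * 560)
})

test_that("event costs discount by age and unknown keys raise errors", {
  men <- toy_men(1, death_age = 80)
  ct <- cost_table()
  run <- toy_run(men, data.frame(man_id = 1L, age = 36,
                                 event = "screen_visit", detail = "psa"))
  cc <- accumulate_costs(run, NULL, ct, rate = 0.03)
  expect_equal(cc$screening, 58)
  expect_equal(cc$screening_disc, 58 / 1.03)
  bad <- toy_run(men, data.frame(man_id = 1L, age = 36,
                                 event = "mystery", detail = ""))
  expect_error(accumulate_costs(bad, NULL, ct, rate = 0), "mystery")
  badtr <- toy_run(men, data.frame(man_id = 1L, age = 36,
                                   event = "treatment", detail = "cryo"))
  expect_error(accumulate_costs(badtr, NULL, ct, rate = 0), "cryo")
})

test_that("cost breakdowns are additive and discounting is monotone for every simulated man", {
  sc <- default_scenario(1)
  sim <- simulate_scenario(sc, 3000)
  for (run in sim$runs[c("none", "psa", "s3m_1")]) {
    cc <- accumulate_costs(run, sim$cohort, sc$costs, rate = 0.03)
    expect_equal(cc$total_direct,
                 cc$screening + cc$diagnosis + cc$treatment +
                   cc$advanced_disease, tolerance = 1e-9)
    expect_equal(cc$total_societal, cc$total_direct + cc$productivity_loss,
                 tolerance = 1e-9)
    expect_true(all(cc$total_societal_disc <= cc$total_societal + 1e-9))
    post <- run$events$age > 35
    # strictly lower discounted totals for men with post-reference events
    men_post <- unique(run$events$man_id[post &
      run$events$event %in% c("screen_visit", "biopsy", "symptomatic_dx")])
    if (length(men_post))
      expect_true(all(cc$total_societal_disc[men_post] <
                        cc$total_societal[men_post]))
    # zero rate: discounted equals undiscounted exactly
    c0 <- accumulate_costs(run, sim$cohort, sc$costs, rate = 0)
    expect_equal(c0$total_societal_disc, c0$total_societal)
    q0 <- accumulate_qalys(run, sim$cohort, sc$utilities, rate = 0)
    expect_equal(q0$qalys_disc, q0$qalys)
    expect_true(all(q0$qalys <= q0$life_years + 1e-9))
  }
})

test_that("productivity losses stop at the retirement age", {
  ct <- cost_table()
  men <- toy_men(1, death_age = 90)
  before <- toy_run(men, data.frame(man_id = 1L, age = 60,
                                    event = "screen_visit", detail = "psa"))
  after <- toy_run(men, data.frame(man_id = 1L, age = 70,
                                   event = "screen_visit", detail = "psa"))
  expect_gt(accumulate_costs(before, NULL, ct, 0)$productivity_loss, 0)
  expect_equal(accumulate_costs(after, NULL, ct, 0)$productivity_loss, 0)
  ct2 <- cost_table(retirement_age = Inf)
  expect_gt(accumulate_costs(after, NULL, ct2, 0)$productivity_loss, 0)
})
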