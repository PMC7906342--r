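# Controlled single-man cohorts: overwrite the PSA random effects of a
# simulated cohort row so the trajectory is deterministic.
fixed_psa_cohort <- function(beta0, n = 1, onset_age = NA, gleason = NA,
                             other_death = 90) {
  p <- nh_params(psa_noise_sd = 0)
  lt <- gen_lifetable()
  coh <- simulate_cohort(p, lt, n, seed = 1)
  coh$beta0 <- beta0
  coh$beta1 <- 0
  coh$beta2 <- 0
  coh$onset_age <- onset_age
  coh$gleason <- factor(gleason, levels = c("GS6", "GS7", "GS8plus"))
  coh$t_advanced_age <- ifelse(is.na(onset_age), NA, onset_age + 30)
  coh$t_metastatic_age <- ifelse(is.na(onset_age), NA, onset_age + 60)
  coh$clinical_dx_age <- NA_real_
  coh$dx_extent <- factor(NA, levels = c("localised", "advanced", "metastatic"))
  coh$pc_death_age <- NA_real_
  coh$other_death_age <- other_death
  coh$death_age <- other_death
  attr(coh, "params") <- p
  coh
}

tau3 <- function(alpha) {
  structure(data.frame(alpha = alpha,
                       state = factor(c("benign", "GS6", "GS7plus"),
                                      c("benign", "GS6", "GS7plus")),
                       tau = 3),
            class = c("tau_table", "data.frame"))
}

test_that("a man below every threshold gets four screens, no reflex tests, no biopsies", {
  coh <- fixed_psa_cohort(beta0 = log(0.5))
  spec <- strategy_spec("s3m_1", "s3m_reflex", alpha = 1,
                        biopsy_compliance = 1)
  run <- run_strategy(coh, spec, tau = tau3(1))
  expect_equal(run$men$n_screens, 4L)
  expect_equal(run$men$n_s3m, 0L)
  expect_equal(run$men$n_biopsies, 0L)
  ages <- run$events$age[run$events$event == "screen_visit"]
  expect_equal(sort(ages), c(55, 59, 63, 67))
})

test_that("PSA at or above the upper threshold refers directly to biopsy with no reflex test", {
  coh <- fixed_psa_cohort(beta0 = log(12))
  spec <- strategy_spec("s3m_1", "s3m_reflex", alpha = 1,
                        biopsy_compliance = 1)
  run <- run_strategy(coh, spec, tau = tau3(1))
  expect_equal(run$men$n_s3m, 0L)
  expect_gte(run$men$n_biopsies, 1L)
  first_bx <- min(run$events$age[run$events$event == "biopsy"])
  expect_equal(first_bx, 55)
})

test_that("no-screening strategy produces no screening events", {
  sc <- default_scenario(1)
  coh <- simulate_cohort(sc$natural_history, sc$life_table, 2000, seed = 3)
  run <- run_strategy(coh, strategy_spec("none", "none"))
  expect_true(all(run$men$n_screens == 0))
  expect_true(all(run$men$n_s3m == 0))
  expect_false(any(run$events$event == "screen_visit"))
  expect_true(all(run$men$overdiagnosed == FALSE))
})

test_that("with unit relative positive fractions the reflex pathway equals the PSA pathway under shared random numbers", {
  sc <- default_scenario(1)
  coh <- simulate_cohort(sc$natural_history, sc$life_table, 3000, seed = 21)
  psa_spec <- strategy_spec("psa", "psa", biopsy_compliance = 1)
  s3m_spec <- strategy_spec("s3m", "s3m_reflex", alpha = 1,
                            biopsy_compliance = 1)
  run_psa <- run_strategy(coh, psa_spec)
  run_s3m <- run_strategy(coh, s3m_spec, tau = tau3(1))
  men_a <- run_psa$men
  men_b <- run_s3m$men
  men_b$n_s3m <- men_a$n_s3m  # reflex-test administration differs by design
  expect_equal(men_a, men_b)
  ev_a <- run_psa$events[run_psa$events$event != "screen_visit", ]
  ev_b <- run_s3m$events[run_s3m$events$event != "screen_visit", ]
  rownames(ev_a) <- rownames(ev_b) <- NULL
  expect_equal(ev_a, ev_b)
  # screen visits coincide in (man, age); only the visit kind differs
  sv_a <- run_psa$events[run_psa$events$event == "screen_visit",
                         c("man_id", "age")]
  sv_b <- run_s3m$events[run_s3m$events$event == "screen_visit",
                         c("man_id", "age")]
  rownames(sv_a) <- rownames(sv_b) <- NULL
  expect_equal(sv_a, sv_b)
})

test_that("biopsy counts are monotone over reflex thresholds on a common cohort", {
  sc <- default_scenario(1)
  n <- 20000
  sim <- simulate_scenario(sc, n)
  bx <- vapply(sim$runs, function(r) sum(r$men$n_biopsies), numeric(1))
  expect_lte(bx[["s3m_2"]], bx[["s3m_1.5"]])
  expect_lte(bx[["s3m_1.5"]], bx[["s3m_1"]])
  expect_lte(bx[["s3m_1"]], bx[["psa"]])
})

test_that("diagnosed cancers decompose into screen-detected plus clinical, and overdiagnosed is a subset", {
  sc <- default_scenario(1)
  sim <- simulate_scenario(sc, 5000)
  for (run in sim$runs) {
    m <- run$men
    sd_n <- sum(!is.na(m$dx_mode) & m$dx_mode == "screen_detected")
    cl_n <- sum(!is.na(m$dx_mode) & m$dx_mode == "clinical")
    expect_equal(sum(m$diagnosed), sd_n + cl_n)
    expect_lte(sum(m$overdiagnosed), sd_n)
    expect_true(all(m$n_neg_biopsies <= m$n_biopsies))
    # screen-detected diagnoses have a screen-initiated biopsy at the
    # diagnosis age
    sd_men <- which(!is.na(m$dx_mode) & m$dx_mode == "screen_detected")
    if (length(sd_men)) {
      bx <- run$events[run$events$event == "biopsy", ]
      ok <- vapply(sd_men, function(i)
        any(bx$man_id == i & abs(bx$age - m$dx_age[i]) < 1e-9), logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("outcome classification implements the counterfactual overdiagnosis definition", {
  men <- toy_men(3)
  men$diagnosed <- c(TRUE, TRUE, FALSE)
  men$dx_mode <- c("screen_detected", "screen_detected", NA)
  men$dx_age <- c(60, 60, NA)
  men$dx_gleason <- c("GS6", "GS6", NA)
  men$dx_extent <- c("localised", "localised", NA)
  cohort <- data.frame(id = 1:3,
                       clinical_dx_age = c(65, 62, NA),
                       other_death_age = c(63, 80, 85))
  out <- classify_outcomes(toy_run(men), cohort)
  # counterfactual clinical diagnosis after other-cause death
  expect_true(out$overdiagnosed[1])
  # clinical diagnosis would have occurred in life
  expect_false(out$overdiagnosed[2])
  expect_false(out$screen_detected[3])
})

test_that("screen detection can only improve the detection state and survival", {
  sc <- default_scenario(1)
  coh <- simulate_cohort(sc$natural_history, sc$life_table, 20000, seed = 13)
  run <- run_strategy(coh, strategy_spec("psa", "psa", biopsy_compliance = 1))
  m <- run$men
  sdm <- which(!is.na(m$dx_mode) & m$dx_mode == "screen_detected" &
                 !is.na(coh$clinical_dx_age))
  # same man, same survival quantile: death under screening never earlier
  expect_true(all(m$death_age[sdm] >= coh$death_age[sdm] - 1e-9))
  ext <- match(m$dx_extent[sdm], c("localised", "advanced", "metastatic"))
  ext_clin <- as.integer(coh$dx_extent[sdm])
  expect_true(all(ext <= ext_clin))
})
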