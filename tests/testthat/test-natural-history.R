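test_that("zero onset hazard yields no cancer fields and only other-cause death", {
  p <- const_params(onset = 0)
  lt <- const_lifetable(0.02)
  coh <- simulate_cohort(p, lt, 500, seed = 7)
  expect_true(all(is.na(coh$onset_age)))
  expect_true(all(is.na(coh$clinical_dx_age)))
  expect_true(all(is.na(coh$pc_death_age)))
  expect_true(all(coh$death_age == coh$other_death_age))
})

test_that("constant other-cause hazard gives the exponential mean within Monte-Carlo error", {
  mu <- 0.04  # short lives: negligible truncation at the horizon
  p <- const_params(onset = 0)
  lt <- const_lifetable(mu)
  n <- 1e5
  coh <- simulate_cohort(p, lt, n, seed = 11)
  t <- coh$other_death_age - 35
  # capped at the 75-year horizon: E[min(X, T)] = (1 - exp(-mu T)) / mu
  T <- 75
  m_full <- (1 - exp(-mu * T)) / mu
  se <- sd(t) / sqrt(n)
  expect_lt(abs(mean(t) - m_full), 3 * se)
})

test_that("cohorts are reproducible and satisfy the substream subset contract", {
  p <- nh_params()
  lt <- gen_lifetable()
  a <- simulate_cohort(p, lt, 200, seed = 3)
  b <- simulate_cohort(p, lt, 200, seed = 3)
  expect_identical(a, b)
  big <- simulate_cohort(p, lt, 1000, seed = 3)
  expect_equal(big[1:200, ], a, ignore_attr = TRUE)
})

test_that("event ordering invariants hold across random parameter draws", {
  lt <- gen_lifetable()
  set.seed(99)
  for (k in 1:5) {
    p <- nh_params(onset_rates = runif(5, 0.001, 0.03),
                   adv_rates = runif(3, 0.01, 0.2),
                   met_rates = runif(3, 0.01, 0.2),
                   dx_rates = matrix(runif(9, 0.01, 0.5), 3, 3,
                                     dimnames = list(c("GS6", "GS7", "GS8plus"), NULL)),
                   surv_rates = matrix(runif(9, 0.01, 0.5), 3, 3,
                                       dimnames = list(c("GS6", "GS7", "GS8plus"), NULL)))
    coh <- simulate_cohort(p, lt, 2000, seed = k)
    has_onset <- !is.na(coh$onset_age)
    expect_true(all(coh$onset_age[has_onset] >= 35))
    expect_true(all(coh$t_advanced_age[has_onset] >= coh$onset_age[has_onset]))
    expect_true(all(coh$t_metastatic_age[has_onset] >=
                      coh$t_advanced_age[has_onset]))
    hd <- !is.na(coh$clinical_dx_age)
    expect_true(all(hd == FALSE | has_onset))
    expect_true(all(coh$clinical_dx_age[hd] >= coh$onset_age[hd]))
    expect_true(all(coh$pc_death_age[hd] > coh$clinical_dx_age[hd]))
    expect_true(all(coh$death_age == pmin(
      ifelse(is.na(coh$pc_death_age), Inf, coh$pc_death_age),
      coh$other_death_age)))
    # no cancer without onset
    expect_true(all(is.na(coh$gleason[!has_onset])))
  }
})

test_that("single histories draw from the current RNG stream and share the cohort layout", {
  p <- nh_params()
  lt <- gen_lifetable()
  set.seed(123)
  h1 <- simulate_history(p, lt)
  set.seed(123)
  h2 <- simulate_history(p, lt)
  expect_equal(h1, h2)
  expect_equal(nrow(h1), 1)
  coh <- simulate_cohort(p, lt, 5, seed = 1)
  expect_setequal(names(h1), names(coh))
  expect_gte(h1$other_death_age, 35)
})

test_that("PSA values follow the log-linear growth model", {
  p <- nh_params(psa_noise_sd = 0)
  h <- data.frame(beta0 = log(2), beta1 = 0, beta2 = 0, onset_age = NA)
  expect_equal(psa_value(h, 60, p, noise_q = 0.5), 2.0)
  h2 <- data.frame(beta0 = 0, beta1 = 0.05, beta2 = 0, onset_age = NA)
  expect_equal(psa_value(h2, 55, p, noise_q = 0.5), exp(1.0), tolerance = 1e-12)
  expect_error(psa_value(h, 30, p), "age 35")
  # post-onset slope raises PSA for cancer cases
  h3 <- data.frame(beta0 = 0, beta1 = 0.05, beta2 = 0.2, onset_age = 55)
  expect_gt(psa_value(h3, 67, p, noise_q = 0.5), psa_value(h2, 67, p, noise_q = 0.5))
})

test_that("mean log-PSA at 67 is higher for men with onset at 55 than cancer-free men", {
  p <- nh_params()
  lt <- gen_lifetable()
  coh <- simulate_cohort(p, lt, 1e4, seed = 5)
  with_onset <- coh
  with_onset$onset_age <- 55
  no_onset <- coh
  no_onset$onset_age <- NA
  expect_gt(mean(psa_mean_log(with_onset, 67)), mean(psa_mean_log(no_onset, 67)))
})

test_that("oracle reproduces the closed-form competing-exponential onset probability", {
  lam <- 0.01; mu <- 0.02
  # immediate certain diagnosis, no cure: huge diagnosis and death rates
  p <- const_params(onset = lam, dx = 1e4, surv = 1e4, adv = 0, met = 0)
  lt <- const_lifetable(mu)
  probs <- expected_counts_oracle(lam, p, lt, dt = 0.02)
  T <- 75
  p_onset_cf <- lam / (lam + mu) * (1 - exp(-(lam + mu) * T))
  expect_equal(unname(probs["onset"]), p_onset_cf, tolerance = 2e-3)
  # cap relaxed: the closed form approaches lambda/(lambda+mu) = 1/3
  expect_equal(lam / (lam + mu), 1 / 3, tolerance = 1e-12)
  # certain immediate diagnosis and death make all three probabilities equal
  expect_equal(unname(probs["clinical_dx"]), unname(probs["onset"]),
               tolerance = 5e-3)
  expect_equal(unname(probs["pc_death"]), unname(probs["onset"]),
               tolerance = 5e-3)
})

test_that("oracle rejects age-varying hazards and zero onset gives zero probabilities", {
  lt <- const_lifetable(0.02)
  p0 <- const_params(onset = 0)
  expect_equal(unname(expected_counts_oracle(0, p0, lt)), c(0, 0, 0))
  p_var <- nh_params()
  expect_error(expected_counts_oracle(0.01, p_var, lt), "constant")
})

test_that("simulator agrees with the integration oracle for constant hazards", {
  lam <- 0.012; mu <- 0.025
  p <- const_params(onset = lam, dx = 0.08, adv = 0.06, met = 0.05,
                    surv = 0.12)
  lt <- const_lifetable(mu)
  oracle <- expected_counts_oracle(lam, p, lt, dt = 0.01)
  n <- 1e5
  coh <- simulate_cohort(p, lt, n, seed = 17)
  sim <- c(
    onset = mean(!is.na(coh$onset_age) & coh$onset_age < coh$other_death_age),
    clinical_dx = mean(!is.na(coh$clinical_dx_age) &
                         coh$clinical_dx_age < coh$other_death_age),
    pc_death = mean(!is.na(coh$pc_death_age) &
                      coh$pc_death_age < coh$other_death_age))
  for (k in names(sim)) {
    se <- sqrt(sim[k] * (1 - sim[k]) / n)
    expect_lt(abs(sim[k] - oracle[k]), 3 * se + 2e-3)
  }
})
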