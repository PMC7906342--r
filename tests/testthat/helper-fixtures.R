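# Shared fixtures: constant-hazard life tables, minimal strategy runs
# built by hand, and flat utility/cost tables for exact arithmetic.

const_lifetable <- function(mu, max_age = 110) {
  age <- 0:max_age
  qx <- rep(1 - exp(-mu), length(age))
  qx[length(qx)] <- 1
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

# nh_params with a single constant onset hazard (oracle-compatible)
const_params <- function(onset = 0.01,
                         dx = 0.1, adv = 0.05, met = 0.05, surv = 0.1, ...) {
  nh_params(onset_breaks = 35, onset_rates = onset,
            adv_rates = rep(adv, 3), met_rates = rep(met, 3),
            dx_rates = matrix(dx, 3, 3, dimnames = list(
              c("GS6", "GS7", "GS8plus"), NULL)),
            surv_rates = matrix(surv, 3, 3, dimnames = list(
              c("GS6", "GS7", "GS8plus"), NULL)), ...)
}

toy_men <- function(n = 1, death_age = 85, diagnosed = FALSE,
                    dx_age = NA_real_, dx_mode = NA_character_,
                    treatment = "none", adv_start = NA_real_,
                    pc_death_age = NA_real_, pc_died = FALSE,
                    overdiagnosed = FALSE) {
  data.frame(id = seq_len(n), n_screens = 0L, n_s3m = 0L, n_biopsies = 0L,
             n_neg_biopsies = 0L, diagnosed = diagnosed, dx_age = dx_age,
             dx_mode = dx_mode, dx_gleason = NA_character_,
             dx_extent = NA_character_, treatment = treatment,
             adv_start = adv_start, pc_death_age = pc_death_age,
             death_age = death_age, pc_died = pc_died,
             overdiagnosed = overdiagnosed)
}

toy_run <- function(men, events = NULL,
                    spec = strategy_spec("toy", "none")) {
  if (is.null(events))
    events <- data.frame(man_id = integer(0), age = numeric(0),
                         event = character(0), detail = character(0))
  structure(list(spec = spec, men = men, events = events),
            class = "strategy_run")
}

flat_norm <- function(v = 1) data.frame(age_min = 0, value = v)

# utilities with every multiplier 1 (no decrements)
unit_utilities <- function(norm = 1) {
  st <- default_utility_states()
  st <- lapply(st, function(s) { s$mult <- 1; s })
  utility_table(population_norm = flat_norm(norm), states = st)
}

# a cheap scenario for pipeline tests: small differences from default
test_scenario <- function(seed = 1L, compliance = 0.9) {
  sc <- default_scenario(seed)
  sc$strategies <- lapply(sc$strategies, function(s) {
    s$biopsy_compliance <- compliance
    s
  })
  sc
}

# mean discounted societal cost and QALYs for one strategy run at a
# chosen rate (rate 0 makes the discounted fields undiscounted)
econ_for_run_test <- function(sc, sim, name, rate) {
  run <- sim$runs[[name]]
  q <- accumulate_qalys(run, sim$cohort, sc$utilities, rate,
                        reference_age = sc$econ$discount_reference_age)
  cc <- accumulate_costs(run, sim$cohort, sc$costs, rate,
                         reference_age = sc$econ$discount_reference_age)
  list(cost = mean(cc$total_societal_disc), qaly = mean(q$qalys_disc))
}

# brute-force efficiency-frontier oracle: a strategy is efficient iff
# it is undominated and maximises net monetary benefit for some
# willingness-to-pay; candidate lambdas are all pairwise slopes
frontier_oracle <- function(d) {
  n <- nrow(d)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && d$cost[j] <= d$cost[i] && d$qaly[j] >= d$qaly[i] &&
        (d$cost[j] < d$cost[i] || d$qaly[j] > d$qaly[i])
    }, logical(1)))
  }, logical(1))
  lambdas <- c(1e-9, 1e12)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d$qaly[i] != d$qaly[j]) {
      l <- (d$cost[i] - d$cost[j]) / (d$qaly[i] - d$qaly[j])
      if (l > 0) lambdas <- c(lambdas, l)
    }
  }
  eff <- vapply(seq_len(n), function(i) {
    !dominated[i] && any(vapply(lambdas, function(l) {
      l * d$qaly[i] - d$cost[i] >= max(l * d$qaly - d$cost) - 1e-9
    }, logical(1)))
  }, logical(1))
  ifelse(dominated, "dominated",
         ifelse(eff, "efficient", "extended_dominated"))
}
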