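# Natural-history model: latent prostate-cancer life histories from
# age 35 -- onset with a fixed Gleason grade, T-stage and metastatic
# progression, clinical diagnosis, prostate-cancer survival anchored at
# the (possibly counterfactual) clinical diagnosis, other-cause death,
# and a log-linear PSA growth model with person-level random effects.

GLEASON_LEVELS <- c("GS6", "GS7", "GS8plus")
EXTENT_LEVELS <- c("localised", "advanced", "metastatic")
STATE_LEVELS <- c("benign", "GS6", "GS7plus")

# layout of the per-man uniform matrix drawn by simulate_cohort();
# man-major order makes earlier men's histories independent of cohort
# size (the subset contract)
N_SCREEN_OCCASIONS <- 6L
U_COLS <- local({
  base <- c("other_death", "onset", "gleason", "t_adv", "t_met",
            "clinical_dx", "surv", "re1", "re2", "re3")
  c(base,
    paste0("noise", seq_len(N_SCREEN_OCCASIONS)),
    paste0("biopsy", seq_len(N_SCREEN_OCCASIONS)),
    "treat", "spare")
})

#' Natural-history parameters
#'
#' Bundles every rate and distribution of the latent disease model.
#' All hazards are per person-year; ages in years.
#'
#' @param onset_breaks,onset_rates piecewise-constant cancer-onset
#'   hazard; `onset_breaks` are segment start ages (first must be 35).
#' @param gleason_probs probabilities over Gleason grades
#'   `c(GS6, GS7, GS8plus)`, summing to 1.
#' @param adv_rates,met_rates per-Gleason hazards of progression from
#'   localised to advanced T-stage and from advanced to metastatic.
#' @param dx_rates 3x3 matrix (Gleason x extent) of clinical-diagnosis
#'   hazards.
#' @param surv_rates 3x3 matrix (Gleason x extent at detection) of
#'   exponential prostate-cancer death rates, measured from the
#'   clinical diagnosis age.
#' @param psa_mu means of the log-PSA random effects
#'   `c(b0, b1, b2)`: intercept at age 35, pre-onset slope per year,
#'   and additional post-onset slope per year.
#' @param psa_sigma 3x3 between-man covariance of the random effects
#'   (symmetric positive semi-definite).
#' @param psa_noise_sd standard deviation of fresh log-scale
#'   measurement noise per PSA determination.
#' @return a validated `nh_params` object.
#' @export
nh_params <- function(onset_breaks = c(35, 50, 60, 70, 80),
                      onset_rates = c(0.0010, 0.0060, 0.0120, 0.0180, 0.0200),
                      gleason_probs = c(GS6 = 0.55, GS7 = 0.30, GS8plus = 0.15),
                      adv_rates = c(GS6 = 0.04, GS7 = 0.08, GS8plus = 0.12),
                      met_rates = c(GS6 = 0.03, GS7 = 0.06, GS8plus = 0.10),
                      dx_rates = rbind(GS6 = c(0.03, 0.08, 0.25),
                                       GS7 = c(0.05, 0.12, 0.35),
                                       GS8plus = c(0.08, 0.15, 0.45)),
                      surv_rates = rbind(GS6 = c(0.004, 0.030, 0.150),
                                         GS7 = c(0.020, 0.060, 0.200),
                                         GS8plus = c(0.050, 0.100, 0.300)),
                      psa_mu = c(b0 = 0, b1 = 0.025, b2 = 0.15),
                      psa_sigma = diag(c(0.55, 0.012, 0.05)^2),
                      psa_noise_sd = 0.25) {
  colnames(dx_rates) <- colnames(surv_rates) <- EXTENT_LEVELS
  p <- structure(list(onset_breaks = onset_breaks, onset_rates = onset_rates,
                      gleason_probs = gleason_probs,
                      adv_rates = adv_rates, met_rates = met_rates,
                      dx_rates = dx_rates, surv_rates = surv_rates,
                      psa_mu = psa_mu, psa_sigma = psa_sigma,
                      psa_noise_sd = psa_noise_sd),
                 class = "nh_params")
  validate_nh_params(p)
}

#' @rdname nh_params
#' @param p object to validate.
#' @export
validate_nh_params <- function(p) {
  stopifnot(inherits(p, "nh_params"))
  stopifnot(p$onset_breaks[1] == 35, !is.unsorted(p$onset_breaks),
            length(p$onset_rates) == length(p$onset_breaks),
            all(p$onset_rates >= 0))
  stopifnot(length(p$gleason_probs) == 3, all(p$gleason_probs >= 0),
            abs(sum(p$gleason_probs) - 1) < 1e-8)
  stopifnot(all(p$adv_rates >= 0), all(p$met_rates >= 0),
            all(p$dx_rates >= 0), all(p$surv_rates >= 0),
            all(dim(p$dx_rates) == c(3, 3)), all(dim(p$surv_rates) == c(3, 3)))
  stopifnot(isTRUE(all.equal(p$psa_sigma, t(p$psa_sigma))))
  ev <- eigen(p$psa_sigma, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > -1e-10))
  stopifnot(p$psa_noise_sd >= 0)
  invisible(p)
}

# matrix square root robust to semi-definite covariances
psa_sigma_chol <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3) %*% t(e$vectors)
}

# core transform: uniform matrix (n x length(U_COLS)) -> life histories
histories_from_uniforms <- function(u, params, life_table) {
  n <- nrow(u)
  colnames(u) <- U_COLS
  e_death <- -log(u[, "other_death"])
  other_death_age <- sample_other_death(e_death, life_table, from_age = 35)

  e_onset <- -log(u[, "onset"])
  horizon <- max(life_table$age)
  onset_age <- sample_pwc(e_onset, params$onset_breaks, params$onset_rates,
                          horizon = horizon)

  gl <- findInterval(u[, "gleason"], cumsum(params$gleason_probs)) + 1L
  gl[gl > 3L] <- 3L
  gl[is.na(onset_age)] <- NA_integer_

  has <- !is.na(onset_age)
  t_adv <- t_met <- clinical_dx <- rep(NA_real_, n)
  dx_extent <- rep(NA_integer_, n)
  if (any(has)) {
    gi <- gl[has]
    t_adv[has] <- onset_age[has] +
      stats::qexp(u[has, "t_adv"], rate = pmax(params$adv_rates[gi], 1e-300))
    t_met[has] <- t_adv[has] +
      stats::qexp(u[has, "t_met"], rate = pmax(params$met_rates[gi], 1e-300))
    # clinical diagnosis: hazard switches at T-stage and metastatic
    # progression; invert the piecewise cumulative hazard
    e <- -log(u[has, "clinical_dx"])
    r1 <- params$dx_rates[cbind(gi, 1L)]
    r2 <- params$dx_rates[cbind(gi, 2L)]
    r3 <- params$dx_rates[cbind(gi, 3L)]
    d1 <- t_adv[has] - onset_age[has]
    d2 <- t_met[has] - t_adv[has]
    H1 <- r1 * d1
    H2 <- H1 + r2 * d2
    dx <- ifelse(e <= H1, onset_age[has] + e / r1,
          ifelse(e <= H2, t_adv[has] + (e - H1) / r2,
                 t_met[has] + (e - H2) / r3))
    ext <- ifelse(e <= H1, 1L, ifelse(e <= H2, 2L, 3L))
    beyond <- !is.finite(dx) | dx > horizon
    dx[beyond] <- NA_real_
    ext[beyond] <- NA_integer_
    clinical_dx[has] <- dx
    dx_extent[has] <- ext
  }

  # prostate-cancer death: exponential survival indexed by the state at
  # detection (here: the clinical-diagnosis state), anchored at the
  # clinical diagnosis age; shared quantile u_surv lets screening
  # re-index the same draw to a better state
  pc_death <- rep(NA_real_, n)
  hd <- !is.na(clinical_dx)
  if (any(hd)) {
    rate <- params$surv_rates[cbind(gl[hd], dx_extent[hd])]
    pc_death[hd] <- clinical_dx[hd] +
      stats::qexp(u[hd, "surv"], rate = pmax(rate, 1e-300))
  }

  z <- stats::qnorm(u[, c("re1", "re2", "re3"), drop = FALSE])
  betas <- sweep(z %*% psa_sigma_chol(params$psa_sigma), 2, params$psa_mu, `+`)

  hist <- data.frame(
    id = seq_len(n),
    beta0 = betas[, 1], beta1 = betas[, 2], beta2 = betas[, 3],
    onset_age = onset_age,
    gleason = factor(GLEASON_LEVELS[gl], levels = GLEASON_LEVELS),
    t_advanced_age = t_adv, t_metastatic_age = t_met,
    clinical_dx_age = clinical_dx,
    dx_extent = factor(EXTENT_LEVELS[dx_extent], levels = EXTENT_LEVELS),
    pc_death_age = pc_death,
    other_death_age = other_death_age)
  hist$death_age <- pmin(ifelse(is.na(pc_death), Inf, pc_death),
                         other_death_age)
  un <- as.data.frame(u[, c(paste0("noise", seq_len(N_SCREEN_OCCASIONS)),
                            paste0("biopsy", seq_len(N_SCREEN_OCCASIONS)),
                            "treat", "spare", "surv"), drop = FALSE])
  names(un) <- paste0("u_", names(un))
  out <- cbind(hist, un)
  attr(out, "params") <- params
  attr(out, "life_table") <- life_table
  class(out) <- c("life_history_cohort", "data.frame")
  out
}

#' Simulate a cohort of life histories
#'
#' Draws `n` independent latent life histories from age 35.  Events
#' beyond the life-table horizon are absent (`NA`).  Progression and
#' clinical-diagnosis ages are kept latent even past other-cause death:
#' the counterfactual clinical diagnosis age is what defines
#' overdiagnosis and anchors post-detection survival.
#'
#' The per-man random numbers are laid out man-by-man under the single
#' seed, so the first `m` histories are identical for every cohort size
#' `n >= m`.
#'
#' @param params a [nh_params()] bundle.
#' @param life_table a [gen_lifetable()] table.
#' @param n cohort size (at least 1).
#' @param seed integer seed.
#' @return a `life_history_cohort` data.frame, one row per man, with
#'   latent event ages, PSA random effects, and the per-man uniforms
#'   reserved for the screening pathway (shared across strategies for
#'   common-random-number comparisons).
#' @export
simulate_cohort <- function(params, life_table, n, seed) {
  stopifnot(n >= 1)
  validate_nh_params(params)
  validate_lifetable(life_table)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- matrix(stats::runif(n * length(U_COLS)), ncol = length(U_COLS),
              byrow = TRUE)
  histories_from_uniforms(u, params, life_table)
}

#' Simulate a single life history
#'
#' Convenience wrapper drawing one history from the current RNG stream
#' (set a seed beforehand for reproducibility).
#'
#' @inheritParams simulate_cohort
#' @return a one-row `life_history_cohort`.
#' @export
simulate_history <- function(params, life_table) {
  u <- matrix(stats::runif(length(U_COLS)), nrow = 1)
  histories_from_uniforms(u, params, life_table)
}

#' Evaluate a PSA measurement for a simulated man
#'
#' log PSA = b0 + b1 (age - 35) + b2 max(0, age - onset) + noise, with
#' fresh Gaussian measurement noise; always strictly positive.
#'
#' @param history a row (or rows) of a `life_history_cohort`.
#' @param age measurement age(s), at least 35.
#' @param params the [nh_params()] used for the cohort (for the noise
#'   standard deviation).
#' @param noise_q optional uniform quantile(s) for the noise (used by
#'   the screening module to share noise across strategies); default
#'   draws fresh noise from the current RNG.
#' @return PSA in ng/mL.
#' @export
psa_value <- function(history, age, params, noise_q = NULL) {
  if (any(age < 35)) stop("PSA is modelled from age 35 on")
  m <- psa_mean_log(history, age)
  z <- if (is.null(noise_q)) stats::rnorm(length(m)) else stats::qnorm(noise_q)
  exp(m + z * params$psa_noise_sd)
}

# mean log PSA (no measurement noise)
psa_mean_log <- function(history, age) {
  onset <- ifelse(is.na(history$onset_age), Inf, history$onset_age)
  history$beta0 + history$beta1 * (age - 35) +
    history$beta2 * pmax(0, age - onset)
}

#' Lifetime event probabilities by numerical integration
#'
#' Independent verification oracle for the simulator in the
#' constant-hazard special case: computes the lifetime probabilities of
#' cancer onset, clinical diagnosis and prostate-cancer death by
#' numerical integration of the competing-risks equations, with no
#' simulation.
#'
#' @param onset_rate constant onset hazard (per year) from age 35.
#' @param params a [nh_params()] whose progression, diagnosis and
#'   survival rates are used (its onset segments must be constant equal
#'   to `onset_rate`; supply a single-segment onset when building it).
#' @param life_table the competing other-cause mortality; pass a
#'   zero-hazard table and `horizon = Inf` behaviour is approximated by
#'   a large horizon.
#' @param dt integration step (years).
#' @return named vector `c(onset, clinical_dx, pc_death)` of lifetime
#'   probabilities.
#' @export
expected_counts_oracle <- function(onset_rate, params, life_table, dt = 0.02) {
  if (length(unique(params$onset_rates)) != 1 ||
      params$onset_rates[1] != onset_rate)
    stop("oracle requires a constant onset hazard matching onset_rate")
  validate_nh_params(params)
  hz <- lifetable_hazard(life_table, 35)
  horizon <- max(life_table$age)
  grid <- seq(35, horizon, by = dt)
  mu <- step_lookup(grid, hz$breaks, ifelse(is.finite(hz$rates), hz$rates, 1e6))

  # forward Kolmogorov over the Markov chain
  #   Free -> (L,A,M by Gleason) -> (DxL,DxA,DxM by Gleason) -> PC death,
  # other-cause death at rate mu(t) from every alive state.  Onset,
  # diagnosis and prostate-cancer death probabilities accumulate as
  # flows; the latent simulator draws the same competing-risks law.
  free <- 1
  occ <- array(0, dim = c(3, 3))  # undiagnosed: gleason x extent
  dxs <- array(0, dim = c(3, 3))  # diagnosed: gleason x extent at dx
  p_onset <- p_dx <- p_pcd <- 0
  pg <- params$gleason_probs
  la <- params$adv_rates; lm <- params$met_rates
  d <- params$dx_rates; s <- params$surv_rates
  # within each step all rates are constant, so state occupancies decay
  # exactly and the leaving mass splits across destinations in
  # proportion to the rates (single-transition-per-step approximation;
  # unconditionally stable, exact in the limit dt -> 0 and robust for
  # near-instantaneous transitions)
  leave_split <- function(mass, total_rate, part_rate) {
    frac <- ifelse(total_rate > 0, part_rate / total_rate, 0)
    mass * (1 - exp(-total_rate * dt)) * frac
  }
  for (k in seq_len(length(grid) - 1)) {
    m <- mu[k]
    r_free <- onset_rate + m
    onset_flow <- leave_split(free, r_free, onset_rate)
    free <- free * exp(-r_free * dt)
    p_onset <- p_onset + onset_flow

    r1 <- la + d[, 1] + m
    r2 <- lm + d[, 2] + m
    r3 <- d[, 3] + m
    to_adv <- leave_split(occ[, 1], r1, la)
    to_dx1 <- leave_split(occ[, 1], r1, d[, 1])
    to_met <- leave_split(occ[, 2], r2, lm)
    to_dx2 <- leave_split(occ[, 2], r2, d[, 2])
    to_dx3 <- leave_split(occ[, 3], r3, d[, 3])
    occ[, 1] <- occ[, 1] * exp(-r1 * dt) + onset_flow * pg
    occ[, 2] <- occ[, 2] * exp(-r2 * dt) + to_adv
    occ[, 3] <- occ[, 3] * exp(-r3 * dt) + to_met
    dx_flow <- cbind(to_dx1, to_dx2, to_dx3)
    p_dx <- p_dx + sum(dx_flow)

    rd <- s + m
    pcd_flow <- dxs * (1 - exp(-rd * dt)) * ifelse(rd > 0, s / rd, 0)
    p_pcd <- p_pcd + sum(pcd_flow)
    dxs <- dxs * exp(-rd * dt) + dx_flow
  }
  c(onset = p_onset, clinical_dx = p_dx, pc_death = p_pcd)
}
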