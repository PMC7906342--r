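# Reflex-test characteristics: relative positive fractions r(alpha|D)
# and the derived per-state PSA thresholds tau(alpha|D) that realise
# the reflex test's positivity inside the simulator.

#' Construct a relative-positive-fraction table
#'
#' @param alpha reflex threshold(s) in ng/mL.
#' @param state disease state (benign/GS6/GS7plus).
#' @param r relative positive fraction (ratio of reflex positivity to
#'   the probability of PSA in [3, 10), conditional on state and on
#'   PSA in [alpha, 10)).
#' @param ci_low,ci_high optional 95\% confidence bounds.
#' @return an `rpf_table` data.frame.
#' @export
rpf_table <- function(alpha, state, r, ci_low = NA_real_, ci_high = NA_real_) {
  d <- data.frame(alpha = alpha, state = factor(state, STATE_LEVELS),
                  r = r, ci_low = ci_low, ci_high = ci_high)
  stopifnot(all(d$r > 0))
  ok <- is.na(d$ci_low) | (d$ci_low <= d$r & d$r <= d$ci_high)
  stopifnot(all(ok))
  structure(d, class = c("rpf_table", "data.frame"))
}

#' Reference reflex-test characteristics
#'
#' The published relative positive fractions of the Stockholm3 reflex
#' test versus PSA 3--10 ng/mL, by reflex threshold and disease state,
#' with 95\% confidence intervals (the Gleason >= 7 fraction at the
#' 1 ng/mL threshold is exactly 1 by design, with no interval).
#' @return an `rpf_table` with entries for alpha 1, 1.5 and 2 ng/mL.
#' @export
reference_rpf_table <- function() {
  rpf_table(
    alpha = rep(c(1, 1.5, 2), each = 3),
    state = rep(c("benign", "GS6", "GS7plus"), 3),
    r = c(0.56, 0.83, 1.00,
          0.52, 0.79, 0.98,
          0.48, 0.72, 0.95),
    ci_low = c(0.46, 0.74, NA,
               0.44, 0.72, 0.94,
               0.40, 0.66, 0.91),
    ci_high = c(0.65, 0.93, NA,
                0.60, 0.87, 1.03,
                0.55, 0.80, 0.99))
}

#' Estimate relative positive fractions from a paired trial dataset
#'
#' For each disease state D, within the window alpha <= PSA < 10,
#' r = (number reflex-positive) / (number with 3 <= PSA < 10).  The
#' confidence interval is a nonparametric bootstrap over men.
#'
#' @param data a `trial_dataset` (columns psa, state, s3m_positive).
#' @param alpha reflex threshold in ng/mL.
#' @param n_boot bootstrap replicates for the CI (0 skips the CI).
#' @param conf confidence level.
#' @return an `rpf_table` with one row per state; a state with an
#'   empty [3, 10) denominator gets `r = NA` and is flagged
#'   inestimable via the `inestimable` attribute.
#' @export
estimate_rpf <- function(data, alpha, n_boot = 200, conf = 0.95) {
  stopifnot(all(c("psa", "state", "s3m_positive") %in% names(data)))
  est_one <- function(d) {
    w <- d[d$psa >= alpha & d$psa < 10, ]
    den <- sum(w$psa >= 3)
    if (den == 0) return(NA_real_)
    sum(w$s3m_positive) / den
  }
  res <- lapply(STATE_LEVELS, function(s) {
    d <- data[data$state == s, ]
    if (nrow(d) == 0) return(c(NA_real_, NA_real_, NA_real_))
    r <- est_one(d)
    if (is.na(r) || n_boot == 0) return(c(r, NA_real_, NA_real_))
    bs <- vapply(seq_len(n_boot), function(b) {
      est_one(d[sample.int(nrow(d), replace = TRUE), ])
    }, numeric(1))
    qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    c(r, qs[1], qs[2])
  })
  m <- do.call(rbind, res)
  out <- data.frame(alpha = alpha, state = factor(STATE_LEVELS, STATE_LEVELS),
                    r = m[, 1], ci_low = m[, 2], ci_high = m[, 3])
  attr(out, "inestimable") <- STATE_LEVELS[is.na(m[, 1])]
  class(out) <- c("rpf_table", "data.frame")
  out
}

#' Calibrate per-state PSA thresholds from relative positive fractions
#'
#' Finds tau(alpha|D) such that, within the window alpha <= PSA < 10
#' for state D, the fraction of the reference sample at or above tau
#' equals r(alpha|D) times the fraction with 3 <= PSA < 10.  With an
#' empirical sample, tau is the smallest sample value achieving the
#' target count (values rounded to the nearest attainable count); when
#' r = 1 the defining equation is satisfied by the 3 ng/mL referral
#' threshold itself, and tau = 3 exactly.  A survival function can be
#' supplied instead of a sample, in which case tau is solved by
#' bisection to |target - achieved| < 1e-6.
#'
#' @param reference_psa either a named list of numeric PSA samples per
#'   state (values restricted to, or filtered to, [alpha, 10)), or a
#'   named list of functions `S(x)` giving P(x <= PSA < 10 | state,
#'   alpha <= PSA < 10).
#' @param alpha reflex threshold in ng/mL.
#' @param rpf an `rpf_table` with rows for this alpha.
#' @param psa_referral,psa_upper referral and upper thresholds
#'   (defaults 3 and 10 ng/mL).
#' @return a `tau_table` data.frame with columns alpha, state, tau.
#' @export
calibrate_tau <- function(reference_psa, alpha, rpf,
                          psa_referral = 3, psa_upper = 10) {
  rows <- rpf[rpf$alpha == alpha, ]
  stopifnot(nrow(rows) > 0)
  tau <- vapply(STATE_LEVELS, function(s) {
    r <- rows$r[rows$state == s]
    stopifnot(length(r) == 1, is.finite(r))
    ref <- reference_psa[[s]]
    if (is.function(ref)) {
      target <- r * ref(psa_referral)
      if (target > 1 + 1e-12)
        stop("inconsistent target for state ", s,
             ": implied positivity fraction ", signif(target, 4), " > 1")
      if (abs(target - ref(psa_referral)) < 1e-12) return(psa_referral)
      lo <- alpha; hi <- psa_upper
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (ref(mid) > target) lo <- mid else hi <- mid
        if (hi - lo < 1e-9) break
      }
      return((lo + hi) / 2)
    }
    x <- ref[ref >= alpha & ref < psa_upper]
    if (!length(x)) stop("empty reference sample for state ", s)
    n_win <- length(x)
    n_ref <- sum(x >= psa_referral)
    target <- r * n_ref / n_win
    if (target > 1 + 1e-12)
      stop("inconsistent target for state ", s,
           ": implied positivity fraction ", signif(target, 4), " > 1")
    k <- round(target * n_win)
    if (k == n_ref) return(psa_referral)  # r = 1: the referral cut itself
    if (k == 0) return(psa_upper)
    sort(x, decreasing = TRUE)[k]
  }, numeric(1))
  structure(data.frame(alpha = alpha,
                       state = factor(STATE_LEVELS, STATE_LEVELS),
                       tau = unname(tau)),
            class = c("tau_table", "data.frame"))
}

#' Per-state PSA reference sample at scheduled screening ages
#'
#' Records the (noise-free schedule plus measurement noise) PSA values
#' of a simulated cohort at the scheduled screening ages, labelled with
#' each man's latent state at that age, restricted to the reflex
#' window [alpha, 10).  This is the distribution the tau-calibration
#' equation conditions on.
#'
#' @param cohort a `life_history_cohort`.
#' @param params the [nh_params()] used to simulate it.
#' @param screen_ages scheduled screening ages.
#' @param alpha reflex threshold in ng/mL.
#' @param psa_upper upper referral threshold.
#' @return named list of numeric PSA samples per state.
#' @export
build_reference_sample <- function(cohort, params, screen_ages, alpha,
                                   psa_upper = 10) {
  out <- list(benign = numeric(0), GS6 = numeric(0), GS7plus = numeric(0))
  for (j in seq_along(screen_ages)) {
    a <- screen_ages[j]
    alive <- a < cohort$other_death_age &
      (is.na(cohort$clinical_dx_age) | a < cohort$clinical_dx_age)
    if (!any(alive)) next
    h <- cohort[alive, ]
    psa <- psa_value(h, a, params, noise_q = h[[paste0("u_noise", j)]])
    st <- latent_state(h, a)
    keep <- psa >= alpha & psa < psa_upper
    for (s in STATE_LEVELS) {
      out[[s]] <- c(out[[s]], psa[keep & st == s])
    }
  }
  out
}

# latent disease state label at a given age
latent_state <- function(history, age) {
  st <- rep("benign", nrow(history))
  cancer <- !is.na(history$onset_age) & history$onset_age <= age
  st[cancer & history$gleason == "GS6"] <- "GS6"
  st[cancer & history$gleason != "GS6"] <- "GS7plus"
  factor(st, STATE_LEVELS)
}
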