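# Sensitivity machinery: one-way analyses over single parameter axes,
# probabilistic parameter draws, and cost-effectiveness acceptability
# curves.

#' Specify the probabilistic-analysis parameter distributions
#'
#' Natural-history rates are multivariate normal around base values
#' (diagonal covariance as relative standard deviations -- the
#' calibrated posterior covariance is not public); reflex-test
#' relative positive fractions are independent normals with standard
#' deviation (ci_high - ci_low)/3.92, truncated at 0; the biopsy and
#' urology episode cost is log-normal parameterised so its 2.5/97.5
#' percentiles are 330 and 880 EUR; other costs and utility
#' decrements get triangular multipliers with mode 1 and extremes
#' 0.8/1.2.  Infeasible draws (negative rates, non-positive r) are
#' resampled and counted.
#'
#' @param scenario base `scenario_config`.
#' @param nh_rel_sd relative standard deviation applied to every
#'   natural-history hazard.
#' @param n_draws number of parameter combinations (at least 2;
#'   500 in the reference analysis).
#' @param seed integer seed.
#' @param vary_rpf,vary_costs,vary_utilities switch off individual
#'   uncertainty components (all on by default); with `nh_rel_sd = 0`
#'   and all three off the spec is degenerate and every draw equals
#'   the base scenario.
#' @return an `uncertainty_spec`.
#' @export
uncertainty_spec <- function(scenario, nh_rel_sd = 0.05, n_draws = 500,
                             seed = 1L, vary_rpf = TRUE, vary_costs = TRUE,
                             vary_utilities = TRUE) {
  stopifnot(n_draws >= 2, nh_rel_sd >= 0)
  structure(list(scenario = scenario, nh_rel_sd = nh_rel_sd,
                 n_draws = n_draws, seed = as.integer(seed),
                 vary_rpf = vary_rpf, vary_costs = vary_costs,
                 vary_utilities = vary_utilities,
                 biopsy_cost_meanlog = (log(330) + log(880)) / 2,
                 biopsy_cost_sdlog = log(880 / 330) / 3.92),
            class = "uncertainty_spec")
}

#' Draw parameter bundles for the probabilistic analysis
#'
#' @param spec an [uncertainty_spec()].
#' @return list of `n_draws` perturbed `scenario_config` bundles;
#'   attribute `resamples` counts rejected infeasible draws.
#' @export
sample_uncertainty <- function(spec) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  base <- spec$scenario
  resamples <- 0L

  draw_pos <- function(mean, rel_sd) {
    # normal truncated at 0 by resampling
    if (rel_sd == 0) return(mean)
    x <- stats::rnorm(length(mean), mean, abs(mean) * rel_sd)
    bad <- x < 0 & mean > 0
    while (any(bad)) {
      resamples <<- resamples + sum(bad)
      x[bad] <- stats::rnorm(sum(bad), mean[bad], abs(mean[bad]) * rel_sd)
      bad <- x < 0 & mean > 0
    }
    x
  }

  draws <- vector("list", spec$n_draws)
  for (k in seq_len(spec$n_draws)) {
    sc <- base
    nh <- sc$natural_history
    nh$onset_rates <- draw_pos(nh$onset_rates, spec$nh_rel_sd)
    nh$adv_rates <- draw_pos(nh$adv_rates, spec$nh_rel_sd)
    nh$met_rates <- draw_pos(nh$met_rates, spec$nh_rel_sd)
    nh$dx_rates[] <- draw_pos(c(nh$dx_rates), spec$nh_rel_sd)
    nh$surv_rates[] <- draw_pos(c(nh$surv_rates), spec$nh_rel_sd)
    sc$natural_history <- validate_nh_params(nh)

    if (spec$vary_rpf) {
      r_sd <- (base$rpf$ci_high - base$rpf$ci_low) / 3.92
      r_sd[is.na(r_sd)] <- 0
      r <- stats::rnorm(nrow(base$rpf), base$rpf$r, r_sd)
      bad <- r <= 0
      while (any(bad)) {
        resamples <- resamples + sum(bad)
        r[bad] <- stats::rnorm(sum(bad), base$rpf$r[bad], r_sd[bad])
        bad <- r <= 0
      }
      sc$rpf <- rpf_table(base$rpf$alpha, as.character(base$rpf$state), r,
                          ci_low = pmin(base$rpf$ci_low, r),
                          ci_high = pmax(base$rpf$ci_high, r))
    }

    if (spec$vary_costs) {
      ct <- sc$costs
      ct$biopsy_episode <- stats::rlnorm(1, spec$biopsy_cost_meanlog,
                                         spec$biopsy_cost_sdlog)
      tri <- function() qtriangular(stats::runif(1), 0.8, 1.0, 1.2)
      ct$psa_test_total <- base$costs$psa_test_total * tri()
      ct$s3m_test_total <- base$costs$s3m_test_total * tri()
      ct$advanced_disease <- base$costs$advanced_disease * tri()
      ct$terminal_care <- base$costs$terminal_care * tri()
      ct$treatment_costs <- base$costs$treatment_costs * tri()
      sc$costs <- ct
    }

    if (spec$vary_utilities) {
      # utility decrements scale multiplicatively: decrement (1 - mult)
      # scaled, population norms untouched
      um <- qtriangular(stats::runif(1), 0.8, 1.0, 1.2)
      sc$utilities$states <- lapply(base$utilities$states, function(s) {
        s$mult <- max(0, min(1, 1 - (1 - s$mult) * um))
        s
      })
    }
    draws[[k]] <- sc
  }
  attr(draws, "resamples") <- resamples
  draws
}

#' Cost-effectiveness acceptability curves
#'
#' For each strategy and willingness-to-pay value, the probability
#' (over parameter-uncertainty draws) that the strategy has strictly
#' higher net monetary benefit than the reference:
#' lambda * dQALY - dCost > 0.
#'
#' @param draw_results data.frame with columns `draw`, `strategy`,
#'   `cost`, `qaly` (per man).
#' @param reference name of the reference strategy.
#' @param wtp_grid willingness-to-pay values (EUR/QALY, non-negative).
#' @return data.frame `wtp`, `strategy`, `probability` in [0, 1].
#' @export
ceac <- function(draw_results, reference,
                 wtp_grid = seq(0, 150000, by = 5000)) {
  stopifnot(all(wtp_grid >= 0), reference %in% draw_results$strategy)
  stopifnot(length(unique(draw_results$draw)) >= 2)
  ref <- draw_results[draw_results$strategy == reference, ]
  out <- list()
  for (s in setdiff(unique(draw_results$strategy), reference)) {
    d <- draw_results[draw_results$strategy == s, ]
    m <- merge(d, ref, by = "draw", suffixes = c("", "_ref"))
    dq <- m$qaly - m$qaly_ref
    dc <- m$cost - m$cost_ref
    prob <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
    out[[s]] <- data.frame(wtp = wtp_grid, strategy = s, probability = prob)
  }
  do.call(rbind, out)
}

#' One-way sensitivity analysis
#'
#' Perturbs the scenario along a single axis, holding everything else
#' at base values, and reports the discounted societal ICER of
#' `strategy` versus `reference` at each axis point.  The simulation
#' reuses one cohort (common random numbers): axes touching only the
#' economic inputs re-price the same runs, and the reflex-performance
#' axis recalibrates the test thresholds and re-runs the screening
#' pathway on the same cohort.
#'
#' @param scenario a `scenario_config`.
#' @param axis one of `s3m_unit_cost` (EUR values), `discount`
#'   (rates), `rpf` (labels low/base/high = CI bounds),
#'   `utility_decrement` (scale factors), `biopsy_cost` (EUR values),
#'   `all_costs` (scale factors).
#' @param values axis points (see `axis`).
#' @param strategy,reference strategy names to compare.
#' @param n cohort size.
#' @param warn_outside warn (not fail) when values leave the
#'   documented range.
#' @return data.frame: axis, value, delta_cost, delta_qaly, icer,
#'   label.
#' @export
oneway_sensitivity <- function(scenario, axis, values, strategy, reference,
                               n = 10000, warn_outside = TRUE) {
  axis <- match.arg(axis, c("s3m_unit_cost", "discount", "rpf",
                            "utility_decrement", "biopsy_cost", "all_costs"))
  ranges <- list(discount = c(0, 0.05), biopsy_cost = c(330, 880),
                 utility_decrement = c(0.8, 1.2), all_costs = c(0.8, 1.2))
  if (warn_outside && axis %in% names(ranges)) {
    rg <- ranges[[axis]]
    if (any(values < rg[1] | values > rg[2]))
      warning("axis values outside the documented range [",
              rg[1], ", ", rg[2], "]; proceeding")
  }
  sim <- simulate_scenario(scenario, n)
  res <- lapply(values, function(v) {
    sc <- scenario
    resim <- NULL
    if (axis == "s3m_unit_cost") sc$costs$s3m_test_total <- v
    if (axis == "biopsy_cost") sc$costs$biopsy_episode <- v
    if (axis == "discount") sc$econ$discount_rate <- v
    if (axis == "all_costs") {
      for (f in c("psa_test_total", "s3m_test_total", "biopsy_episode",
                  "advanced_disease", "terminal_care"))
        sc$costs[[f]] <- sc$costs[[f]] * v
      sc$costs$treatment_costs <- sc$costs$treatment_costs * v
      sc$costs$salaries$annual_salary <- sc$costs$salaries$annual_salary * v
    }
    if (axis == "utility_decrement") {
      sc$utilities$states <- lapply(sc$utilities$states, function(s) {
        s$mult <- max(0, min(1, 1 - (1 - s$mult) * v))
        s
      })
    }
    if (axis == "rpf") {
      stopifnot(v %in% c("low", "base", "high"))
      r <- sc$rpf
      if (v == "low") r$r <- ifelse(is.na(r$ci_low), r$r, r$ci_low)
      if (v == "high") r$r <- ifelse(is.na(r$ci_high), r$r, r$ci_high)
      sc$rpf <- r
      resim <- c(strategy, reference)
    }
    pair <- evaluate_pair(sc, sim, strategy, reference, resim = resim)
    data.frame(axis = axis, value = if (is.numeric(v)) v else NA,
               value_label = as.character(v),
               delta_cost = pair$delta_cost, delta_qaly = pair$delta_qaly,
               icer = pair$value, label = pair$label)
  })
  do.call(rbind, res)
}
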