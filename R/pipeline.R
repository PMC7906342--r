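# End-to-end orchestration: simulate a scenario, execute every
# strategy on a common cohort, price and weight the outcomes, and
# write the headline tables and machine-readable outputs.

#' Simulate a scenario: cohort, test-threshold calibration, runs
#'
#' Simulates one cohort and executes every configured strategy on it
#' (common random numbers).  Reflex strategies get their per-state PSA
#' thresholds calibrated from the cohort's own screen-age PSA
#' distribution and the scenario's relative-positive-fraction table.
#'
#' @param scenario a `scenario_config`.
#' @param n cohort size.
#' @param seed cohort seed (default: the scenario's cohort seed).
#' @return list with `cohort`, `taus` (per reflex strategy) and `runs`
#'   (named list of `strategy_run`).
#' @export
simulate_scenario <- function(scenario, n, seed = scenario$seeds$cohort) {
  validate_scenario(scenario)
  params <- scenario$natural_history
  cohort <- simulate_cohort(params, scenario$life_table, n, seed)
  taus <- list()
  runs <- list()
  for (spec in scenario$strategies) {
    tau <- NULL
    if (spec$kind == "s3m_reflex") {
      key <- as.character(spec$alpha)
      if (is.null(taus[[key]])) {
        ref <- build_reference_sample(cohort, params, screen_schedule(spec),
                                      spec$alpha, spec$psa_upper)
        taus[[key]] <- calibrate_tau(ref, spec$alpha, scenario$rpf,
                                     psa_referral = spec$psa_referral,
                                     psa_upper = spec$psa_upper)
      }
      tau <- taus[[key]]
    }
    runs[[spec$name]] <- run_strategy(
      cohort, spec, tau = tau, params = params,
      treatment_probs = scenario$treatment_probs,
      symptomatic_dx_biopsies = scenario$costs$symptomatic_dx_biopsies)
  }
  list(cohort = cohort, taus = taus, runs = runs)
}

# economics for one run under a scenario's economic settings
econ_for_run <- function(scenario, run, cohort) {
  rate <- scenario$econ$discount_rate
  ref_age <- scenario$econ$discount_reference_age
  list(qalys = accumulate_qalys(run, cohort, scenario$utilities, rate,
                                reference_age = ref_age),
       costs = accumulate_costs(run, cohort, scenario$costs, rate,
                                reference_age = ref_age))
}

# discounted societal (cost, qaly) pair comparison used by the
# sensitivity machinery
evaluate_pair <- function(scenario, sim, strategy, reference, resim = NULL) {
  get_run <- function(name) {
    if (!is.null(resim) && name %in% resim) {
      spec <- Find(function(s) s$name == name, scenario$strategies)
      tau <- NULL
      if (spec$kind == "s3m_reflex") {
        ref <- build_reference_sample(sim$cohort, scenario$natural_history,
                                      screen_schedule(spec), spec$alpha,
                                      spec$psa_upper)
        tau <- calibrate_tau(ref, spec$alpha, scenario$rpf,
                             psa_referral = spec$psa_referral,
                             psa_upper = spec$psa_upper)
      }
      run_strategy(sim$cohort, spec, tau = tau,
                   params = scenario$natural_history,
                   treatment_probs = scenario$treatment_probs,
                   symptomatic_dx_biopsies = scenario$costs$symptomatic_dx_biopsies)
    } else sim$runs[[name]]
  }
  s1 <- get_run(strategy); s0 <- get_run(reference)
  e1 <- econ_for_run(scenario, s1, sim$cohort)
  e0 <- econ_for_run(scenario, s0, sim$cohort)
  dc <- mean(e1$costs$total_societal_disc) - mean(e0$costs$total_societal_disc)
  dq <- mean(e1$qalys$qalys_disc) - mean(e0$qalys$qalys_disc)
  icer(dc, dq)
}

#' Run the full cost-effectiveness analysis
#'
#' Simulates the cohort, runs all strategies, prices outcomes and
#' returns summaries, pairwise comparisons (each screening strategy
#' versus no screening, and each reflex strategy versus PSA) and the
#' discounted societal cost-efficiency frontier.
#'
#' @param scenario a `scenario_config`.
#' @param n cohort size.
#' @param seed optional override of the cohort seed.
#' @return a `cea_result`: list with `summaries` (named list of
#'   `strategy_summary`), `summary_table` (stacked data.frame),
#'   `comparisons` (named list of `strategy_comparison`), `frontier`.
#' @export
run_all_strategies <- function(scenario, n, seed = scenario$seeds$cohort) {
  sim <- simulate_scenario(scenario, n, seed)
  summaries <- list()
  for (name in names(sim$runs)) {
    e <- econ_for_run(scenario, sim$runs[[name]], sim$cohort)
    summaries[[name]] <- summarize_strategy(sim$runs[[name]], e$qalys,
                                            e$costs, n)
  }
  kinds <- vapply(scenario$strategies, `[[`, "", "kind")
  names(kinds) <- vapply(scenario$strategies, `[[`, "", "name")
  none_name <- names(kinds)[kinds == "none"]
  psa_name <- if (any(kinds == "psa")) names(kinds)[kinds == "psa"][1] else NULL
  comparisons <- list()
  for (name in names(summaries)) {
    if (name != none_name)
      comparisons[[paste0(name, "_vs_", none_name)]] <-
        compare_strategies(summaries[[name]], summaries[[none_name]])
    if (!is.null(psa_name) && kinds[name] == "s3m_reflex")
      comparisons[[paste0(name, "_vs_", psa_name)]] <-
        compare_strategies(summaries[[name]], summaries[[psa_name]])
  }
  fr <- frontier(unname(summaries))
  structure(list(summaries = summaries,
                 summary_table = do.call(rbind, summaries),
                 comparisons = comparisons, frontier = fr,
                 sim = sim, scenario = scenario, n = n),
            class = "cea_result")
}

# weak structural fingerprint of a scenario for the run manifest
scenario_fingerprint <- function(sc) {
  raw <- serialize(scenario_to_list(sc), NULL, version = 2)
  b <- as.integer(raw)
  sprintf("%s-%d", format(sum(as.double(b) * seq_along(b)) %% 2147483647,
                          scientific = FALSE), length(b))
}

round_summary_fields <- function(df) {
  for (f in SUMMARY_COUNT_FIELDS)
    if (f %in% names(df)) df[[f]] <- round(df[[f]])
  for (f in SUMMARY_COST_FIELDS)
    if (f %in% names(df)) df[[f]] <- round(df[[f]])
  df
}

#' Run the analysis and write result files
#'
#' Writes `summary.csv` (per-strategy outcomes per 10,000 men and
#' costs per man; counts and euros rounded to integers, matching the
#' conventional table precision), `comparisons.csv` (differences,
#' percent changes and ICERs, EUR/QALY rounded to integers),
#' `frontier.csv` and `manifest.json` to `out_dir`.  Outputs are
#' byte-identical across reruns with the same manifest.
#'
#' @param scenario a `scenario_config` or path to a YAML scenario.
#' @param n cohort size (at least 100).
#' @param out_dir output directory (created if needed).
#' @param seed optional cohort-seed override.
#' @return the `cea_result`, invisibly.
#' @export
run_cea <- function(scenario, n, out_dir, seed = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(n >= 100)
  if (is.null(seed)) seed <- scenario$seeds$cohort
  res <- run_all_strategies(scenario, n, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  st <- round_summary_fields(res$summary_table)
  utils::write.csv(st, file.path(out_dir, "summary.csv"), row.names = FALSE)

  comp <- list()
  for (key in names(res$comparisons)) {
    cmp <- res$comparisons[[key]]
    tab <- cmp$table
    tab$comparison <- key
    comp[[key]] <- tab
  }
  comp_df <- do.call(rbind, comp)
  icer_rows <- do.call(rbind, lapply(names(res$comparisons), function(key) {
    ic <- res$comparisons[[key]]$icers
    data.frame(comparison = key, perspective = names(ic),
               icer = vapply(ic, function(x)
                 if (is.na(x$value)) NA_real_ else round(x$value), numeric(1)),
               label = vapply(ic, `[[`, "", "label"))
  }))
  utils::write.csv(comp_df, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(icer_rows, file.path(out_dir, "icers.csv"),
                   row.names = FALSE)
  utils::write.csv(res$frontier, file.path(out_dir, "frontier.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "prostacea",
    version = as.character(utils::packageVersion("prostacea")),
    scenario_fingerprint = scenario_fingerprint(scenario),
    seeds = scenario$seeds, cohort_seed = seed, n = n,
    strategies = vapply(scenario$strategies, `[[`, "", "name"),
    generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Probabilistic sensitivity analysis with CEAC output files
#'
#' Draws parameter bundles, re-evaluates every strategy per draw on a
#' common cohort random-number stream (so parameter uncertainty, not
#' Monte-Carlo noise, dominates), and writes `draws.csv` (per-draw
#' discounted societal cost and QALYs per man, per strategy) and
#' `ceac.csv` (acceptability versus the reference strategy).
#'
#' @param scenario a `scenario_config`.
#' @param n_draws number of parameter draws (at least 2).
#' @param n cohort size per draw.
#' @param out_dir optional output directory; when `NULL` nothing is
#'   written.
#' @param reference reference strategy name (default the PSA
#'   strategy).
#' @param wtp_grid willingness-to-pay grid.
#' @param nh_rel_sd relative sd of the natural-history draws.
#' @param verbose log progress per draw.
#' @return list with `draws` (data.frame) and `ceac` (data.frame).
#' @export
run_probabilistic <- function(scenario, n_draws, n, out_dir = NULL,
                              reference = "psa",
                              wtp_grid = seq(0, 150000, by = 5000),
                              nh_rel_sd = 0.05, verbose = FALSE) {
  spec <- uncertainty_spec(scenario, nh_rel_sd = nh_rel_sd,
                           n_draws = n_draws, seed = scenario$seeds$psa_draws)
  draws <- sample_uncertainty(spec)
  rows <- list()
  for (k in seq_along(draws)) {
    sc <- draws[[k]]
    sim <- simulate_scenario(sc, n, seed = scenario$seeds$cohort)
    for (name in names(sim$runs)) {
      e <- econ_for_run(sc, sim$runs[[name]], sim$cohort)
      rows[[length(rows) + 1L]] <- data.frame(
        draw = k, strategy = name,
        cost = mean(e$costs$total_societal_disc),
        qaly = mean(e$qalys$qalys_disc))
    }
    if (verbose) message(sprintf("draw %d/%d done", k, length(draws)))
  }
  dr <- do.call(rbind, rows)
  cc <- ceac(dr, reference, wtp_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dr, file.path(out_dir, "draws.csv"), row.names = FALSE)
    utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  }
  list(draws = dr, ceac = cc, resamples = attr(draws, "resamples"))
}

#' Published reference lifetime outcomes for the five strategies
#'
#' The lifetime predictions per 10,000 men (events) and per man
#' (undiscounted costs, EUR) published for the registry-calibrated
#' Stockholm3 screening cost-effectiveness analysis.  Shipped for
#' arithmetic cross-checks of the comparison machinery -- the
#' package's synthetic scenario does not reproduce these absolute
#' values.
#'
#' @return named list of `strategy_summary` objects (none, psa,
#'   s3m_1, s3m_1.5, s3m_2).
#' @export
reference_outcomes <- function() {
  path <- system.file("extdata", "stockholm3_reference_outcomes.csv",
                      package = "prostacea")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(d$strategy)) {
    v <- d$value[d$strategy == s]
    names(v) <- d$field[d$strategy == s]
    out[[s]] <- strategy_summary(s, v)
  }
  out
}
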