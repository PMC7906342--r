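# Strategy-level summaries and comparative cost-effectiveness
# statistics: differences and relative changes, ICERs with dominance
# markers, the cost-efficiency frontier with extended dominance, and
# the Swedish NBHW cost-per-QALY bands.

SUMMARY_COUNT_FIELDS <- c("screening_tests", "s3m_tests", "biopsies",
                          "negative_biopsies", "diagnosed",
                          "screen_detected", "overdiagnosed", "pc_deaths",
                          "life_years", "qalys",
                          "life_years_disc", "qalys_disc")
SUMMARY_COST_FIELDS <- c("cost_screening", "cost_diagnosis", "cost_treatment",
                         "cost_advanced_disease", "cost_direct",
                         "cost_productivity", "cost_societal",
                         "cost_screening_disc", "cost_diagnosis_disc",
                         "cost_treatment_disc", "cost_advanced_disease_disc",
                         "cost_direct_disc", "cost_productivity_disc",
                         "cost_societal_disc")

#' Construct a strategy summary from named values
#'
#' Event counts are per 10,000 men, costs are EUR per man; useful for
#' wrapping externally published outcome tables as well as simulated
#' results.
#'
#' @param name strategy name.
#' @param values named numeric vector or list (any subset of the
#'   summary fields).
#' @param n cohort size the summary was computed from.
#' @return a `strategy_summary` (one-row data.frame, attribute `n`).
#' @export
strategy_summary <- function(name, values, n = 10000) {
  v <- as.list(values)
  out <- data.frame(strategy = name)
  for (f in c(SUMMARY_COUNT_FIELDS, SUMMARY_COST_FIELDS))
    out[[f]] <- if (!is.null(v[[f]])) as.numeric(v[[f]]) else NA_real_
  attr(out, "n") <- n
  class(out) <- c("strategy_summary", "data.frame")
  out
}

#' Summarise per-man results for one strategy
#'
#' Scales event counts to a 10,000-man cohort and averages costs per
#' man; both discounted and undiscounted variants are kept.  The
#' summary is invariant to cohort size for fixed per-man results.
#'
#' @param run a `strategy_run`.
#' @param qalys output of [accumulate_qalys()].
#' @param costs output of [accumulate_costs()].
#' @param n cohort size (defaults to the number of men in the run).
#' @return a `strategy_summary`.
#' @export
summarize_strategy <- function(run, qalys, costs, n = nrow(run$men)) {
  stopifnot(n >= 1)
  m <- run$men
  per10k <- function(x) sum(x) * 10000 / n
  vals <- c(
    screening_tests = per10k(m$n_screens),
    s3m_tests = per10k(m$n_s3m),
    biopsies = per10k(m$n_biopsies),
    negative_biopsies = per10k(m$n_neg_biopsies),
    diagnosed = per10k(m$diagnosed),
    screen_detected = per10k(!is.na(m$dx_mode) & m$dx_mode == "screen_detected"),
    overdiagnosed = per10k(m$overdiagnosed),
    pc_deaths = per10k(m$pc_died),
    life_years = per10k(qalys$life_years),
    qalys = per10k(qalys$qalys),
    life_years_disc = per10k(qalys$life_years_disc),
    qalys_disc = per10k(qalys$qalys_disc),
    cost_screening = mean(costs$screening),
    cost_diagnosis = mean(costs$diagnosis),
    cost_treatment = mean(costs$treatment),
    cost_advanced_disease = mean(costs$advanced_disease),
    cost_direct = mean(costs$total_direct),
    cost_productivity = mean(costs$productivity_loss),
    cost_societal = mean(costs$total_societal),
    cost_screening_disc = mean(costs$screening_disc),
    cost_diagnosis_disc = mean(costs$diagnosis_disc),
    cost_treatment_disc = mean(costs$treatment_disc),
    cost_advanced_disease_disc = mean(costs$advanced_disease_disc),
    cost_direct_disc = mean(costs$total_direct_disc),
    cost_productivity_disc = mean(costs$productivity_loss_disc),
    cost_societal_disc = mean(costs$total_societal_disc))
  strategy_summary(run$spec$name, vals, n = n)
}

#' Incremental cost-effectiveness ratio with dominance markers
#'
#' @param delta_cost incremental cost, EUR per man.
#' @param delta_qaly incremental QALYs per man.
#' @return an `icer` object: list with `value` (EUR/QALY or NA) and
#'   `label` in ratio/dominant/dominated/southwest/undefined.  In the
#'   south-west quadrant (less effective, cheaper) the ratio is
#'   reported with an explicit flag since a bare ratio is ambiguous
#'   there.
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (delta_qaly == 0) {
    out <- list(value = NA_real_, label = "undefined")
  } else if (delta_qaly > 0 && delta_cost > 0) {
    out <- list(value = delta_cost / delta_qaly, label = "ratio")
  } else if (delta_qaly > 0) {
    out <- list(value = NA_real_, label = "dominant")
  } else if (delta_cost >= 0) {
    out <- list(value = NA_real_, label = "dominated")
  } else {
    out <- list(value = delta_cost / delta_qaly, label = "southwest")
  }
  out$delta_cost <- delta_cost
  out$delta_qaly <- delta_qaly
  structure(out, class = "icer")
}

#' @export
format.icer <- function(x, ...) {
  switch(x$label,
         ratio = sprintf("%.0f EUR/QALY", x$value),
         southwest = sprintf("%.0f EUR/QALY (south-west quadrant)", x$value),
         x$label)
}

#' @export
print.icer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Compare two strategy summaries
#'
#' Field-wise differences and relative changes (percent of the
#' reference), plus incremental cost-effectiveness ratios per cost
#' perspective (direct = health sector, societal) and discounting
#' variant.  QALY differences per man are the per-10,000 difference
#' divided by 10,000.
#'
#' @param a,ref `strategy_summary` objects on the same scale.
#' @return a `strategy_comparison`: list with `table` (field, a, ref,
#'   difference, pct_change) and `icers` (named list of [icer()]
#'   results: `undisc_direct`, `undisc_societal`, `disc_direct`,
#'   `disc_societal`).
#' @export
compare_strategies <- function(a, ref) {
  fields <- c(SUMMARY_COUNT_FIELDS, SUMMARY_COST_FIELDS)
  av <- unlist(a[1, fields])
  rv <- unlist(ref[1, fields])
  diff <- av - rv
  pct <- ifelse(rv != 0, 100 * diff / rv, NA_real_)
  tab <- data.frame(field = fields, a = unname(av), ref = unname(rv),
                    difference = unname(diff), pct_change = unname(pct))
  ic <- list()
  pair <- function(cost_f, qaly_f) {
    if (any(is.na(c(av[cost_f], rv[cost_f], av[qaly_f], rv[qaly_f]))))
      return(NULL)
    icer(av[[cost_f]] - rv[[cost_f]],
         (av[[qaly_f]] - rv[[qaly_f]]) / 10000)
  }
  ic$undisc_direct <- pair("cost_direct", "qalys")
  ic$undisc_societal <- pair("cost_societal", "qalys")
  ic$disc_direct <- pair("cost_direct_disc", "qalys_disc")
  ic$disc_societal <- pair("cost_societal_disc", "qalys_disc")
  structure(list(a = a$strategy, ref = ref$strategy, table = tab,
                 icers = ic[!vapply(ic, is.null, TRUE)]),
            class = "strategy_comparison")
}

#' NBHW cost-per-QALY category
#'
#' Swedish National Board of Health and Welfare bands (EUR/QALY,
#' half-open, lower-inclusive): below 8,300 low; 8,300 to 41,600
#' moderate; 41,600 to 83,300 high; above very high.
#'
#' @param x an ICER in EUR/QALY (non-negative number) or an [icer()]
#'   object; dominance markers pass through unchanged.
#' @return category string.
#' @export
nbhw_category <- function(x) {
  if (inherits(x, "icer")) {
    if (x$label %in% c("dominant", "dominated", "undefined", "southwest"))
      return(x$label)
    x <- x$value
  }
  stopifnot(is.finite(x), x >= 0)
  if (x < 8300) "low"
  else if (x < 41600) "moderate"
  else if (x < 83300) "high"
  else "very_high"
}

#' Cost-efficiency frontier with extended dominance
#'
#' Sorts strategies by cost, removes strictly dominated strategies
#' (another strategy has no higher cost and no lower effectiveness,
#' with at least one strict), then removes extended-dominated ones
#' until the incremental ICER sequence along the frontier is
#' non-decreasing.  Ties in both cost and effectiveness keep the first
#' strategy in name order.
#'
#' @param summaries data.frame with columns `strategy`, `cost`,
#'   `qaly` (per man), or a list of `strategy_summary` objects (then
#'   discounted societal cost and discounted QALYs are used).
#' @return the input data.frame with a `label` column
#'   (efficient/dominated/extended_dominated) and, for efficient
#'   strategies, `icer_frontier`: the incremental ICER versus the
#'   previous frontier point (NA for the cheapest).
#' @export
frontier <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s)
      data.frame(strategy = s$strategy,
                 cost = s$cost_societal_disc,
                 qaly = s$qalys_disc / 10000)))
  }
  d <- summaries
  stopifnot(nrow(d) >= 1, all(c("strategy", "cost", "qaly") %in% names(d)))
  d <- d[order(d$cost, -d$qaly, d$strategy), ]
  lab <- rep("efficient", nrow(d))
  # strict dominance (ties in both keep the first by name order)
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i == j) next
      ci <- d$cost[i]; cj <- d$cost[j]; qi <- d$qaly[i]; qj <- d$qaly[j]
      if (cj <= ci && qj >= qi && (cj < ci || qj > qi)) {
        lab[i] <- "dominated"; break
      }
      if (cj == ci && qj == qi && d$strategy[j] < d$strategy[i]) {
        lab[i] <- "dominated"; break
      }
    }
  }
  # extended dominance on the remaining, cost-ordered set
  repeat {
    idx <- which(lab == "efficient")
    if (length(idx) < 3) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1)) {
      i0 <- idx[k - 1]; i1 <- idx[k]; i2 <- idx[k + 1]
      icer1 <- (d$cost[i1] - d$cost[i0]) / (d$qaly[i1] - d$qaly[i0])
      icer2 <- (d$cost[i2] - d$cost[i1]) / (d$qaly[i2] - d$qaly[i1])
      if (icer1 > icer2) {
        lab[i1] <- "extended_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  d$label <- lab
  d$icer_frontier <- NA_real_
  idx <- which(lab == "efficient")
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      i0 <- idx[k - 1]; i1 <- idx[k]
      d$icer_frontier[i1] <- (d$cost[i1] - d$cost[i0]) /
        (d$qaly[i1] - d$qaly[i0])
    }
  }
  d
}
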