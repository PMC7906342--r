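# Economic accounting: utilities -> QALYs, unit costs -> discounted
# and undiscounted per-man cost breakdowns, currency conversion and
# discounting conventions.

#' Discount factor
#'
#' Annual compounding, `(1 + rate)^(-t)`, with fractional `t` allowed.
#'
#' @param t years since the discount reference time (non-negative).
#' @param rate discount rate per year (fraction, e.g. 0.03).
#' @return dimensionless factor in (0, 1].
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("discounting requires non-negative times")
  (1 + rate)^(-t)
}

#' Convert Swedish kronor to euros
#'
#' Purchasing-power-parity conversion at 0.0851 EUR/SEK.
#' @param amount_sek amount in SEK.
#' @param rate EUR per SEK.
#' @return amount in EUR.
#' @export
convert_currency <- function(amount_sek, rate = 0.0851) {
  stopifnot(all(is.finite(amount_sek)))
  amount_sek * rate
}

#' Utility table: population norms and state multipliers
#'
#' Health-state values are the product of an age-specific population
#' norm and a state multiplier; transient states carry a duration.
#' The shipped defaults are synthetic stand-ins in the style of
#' published screening models (the underlying trial's exact values are
#' not public) and every entry can be overridden.
#'
#' @param population_norm data.frame with `age_min` and `value`
#'   (step function of age, values in [0, 1]).
#' @param states named list; each element is `list(mult, duration)`
#'   with multiplier in [0, 1] and duration in years (`NA` duration
#'   means the state lasts until its phase ends: advanced disease runs
#'   to death, terminal covers the closing months before
#'   prostate-cancer death).
#' @return a `utility_table`.
#' @export
utility_table <- function(population_norm = default_population_norm(),
                          states = default_utility_states()) {
  stopifnot(all(population_norm$value >= 0 & population_norm$value <= 1))
  for (s in states) {
    stopifnot(s$mult >= 0, s$mult <= 1)
    if (!is.na(s$duration)) stopifnot(s$duration > 0)
  }
  structure(list(population_norm = population_norm, states = states),
            class = "utility_table")
}

#' @rdname utility_table
#' @export
default_population_norm <- function() {
  data.frame(age_min = c(0, 45, 55, 65, 75, 85),
             value = c(0.92, 0.89, 0.85, 0.82, 0.79, 0.74))
}

#' @rdname utility_table
#' @export
default_utility_states <- function() {
  list(screening = list(mult = 0.99, duration = 1 / 52),
       biopsy = list(mult = 0.90, duration = 3 / 52),
       diagnosis = list(mult = 0.80, duration = 1 / 12),
       active_surveillance = list(mult = 0.97, duration = 7),
       prostatectomy = list(mult = 0.86, duration = 2 / 12),
       radiation = list(mult = 0.73, duration = 2 / 12),
       post_treatment = list(mult = 0.95, duration = 10),
       advanced = list(mult = 0.60, duration = NA_real_),
       terminal = list(mult = 0.40, duration = 0.5))
}

#' Cost table
#'
#' Unit costs in EUR.  The PSA-test total of 58 EUR is stored verbatim
#' (its printed components -- sampling 30, analysis 4, GP share 26 --
#' are metadata only and are not asserted to sum to it); the reflex
#' test totals 255 EUR of which the assay itself is 196 EUR.  A
#' reflexed screening visit is costed at the full reflex-visit total.
#' Values not publicly printed are synthetic defaults, flagged in
#' `synthetic_keys`.
#'
#' @param psa_test_total,s3m_test_total,s3m_assay,biopsy_episode,
#'   advanced_disease,terminal_care unit costs (EUR).
#' @param treatment_costs named vector over
#'   active_surveillance/prostatectomy/radiation/none.
#' @param symptomatic_dx_biopsies mean diagnostic biopsies per
#'   symptomatic diagnosis.
#' @param salaries data.frame `age_min`, `annual_salary` (EUR,
#'   including social fees).
#' @param work_hours_per_year divisor turning annual salary into an
#'   hourly wage.
#' @param time_lost_hours named vector of productive hours lost per
#'   event kind.
#' @param retirement_age productivity losses only accrue below this
#'   age; `Inf` disables the cap.
#' @param components metadata on printed cost components.
#' @return a `cost_table`.
#' @export
cost_table <- function(psa_test_total = 58,
                       s3m_test_total = 255,
                       s3m_assay = 196,
                       biopsy_episode = 560,
                       advanced_disease = 41683,
                       terminal_care = 20000,
                       treatment_costs = c(active_surveillance = 4000,
                                           prostatectomy = 8000,
                                           radiation = 10000,
                                           none = 0),
                       symptomatic_dx_biopsies = 2,
                       salaries = default_salary_table(),
                       work_hours_per_year = 1600,
                       time_lost_hours = c(screen_visit = 2, biopsy = 8,
                                           symptomatic_dx = 16, diagnosis = 8,
                                           active_surveillance = 40,
                                           prostatectomy = 240,
                                           radiation = 160, none = 0,
                                           advanced_phase = 300, pc_death = 0),
                       retirement_age = 65,
                       components = list(psa_sampling = 30, psa_analysis = 4,
                                         gp_visit_share = 26)) {
  ct <- structure(list(psa_test_total = psa_test_total,
                       s3m_test_total = s3m_test_total,
                       s3m_assay = s3m_assay,
                       biopsy_episode = biopsy_episode,
                       advanced_disease = advanced_disease,
                       terminal_care = terminal_care,
                       treatment_costs = treatment_costs,
                       symptomatic_dx_biopsies = symptomatic_dx_biopsies,
                       salaries = salaries,
                       work_hours_per_year = work_hours_per_year,
                       time_lost_hours = time_lost_hours,
                       retirement_age = retirement_age,
                       components = components,
                       synthetic_keys = c("terminal_care", "treatment_costs",
                                          "salaries", "time_lost_hours")),
                  class = "cost_table")
  stopifnot(all(unlist(ct[c("psa_test_total", "s3m_test_total", "s3m_assay",
                            "biopsy_episode", "advanced_disease",
                            "terminal_care")]) >= 0),
            all(treatment_costs >= 0))
  ct
}

#' @rdname cost_table
#' @export
default_salary_table <- function() {
  data.frame(age_min = c(0, 25, 35, 45, 55, 65),
             annual_salary = c(30000, 45000, 52000, 55000, 52000, 18000))
}

# ---- QALY machinery ------------------------------------------------------

# cumulative weight function over ages [35, horizon): W(t) integrates
# norm(age) * (1+rate)^-(midyear - reference_age) at yearly resolution
make_weight_fun <- function(utilities, rate, reference_age = 35,
                            horizon = 111) {
  ages <- 35:(horizon - 1)
  norm <- step_lookup(ages, utilities$population_norm$age_min,
                      utilities$population_norm$value)
  disc <- discount_factor(ages + 0.5 - reference_age, rate)
  w <- norm * disc
  cw <- c(0, cumsum(w))
  function(t) {
    t <- pmin(pmax(t, 35), horizon)
    fl <- pmin(floor(t), horizon - 1)
    i <- as.integer(fl) - 35L + 1L
    cw[i] + (t - fl) * w[pmin(i, length(w))]
  }
}

# min-multiplier resolution of possibly overlapping state intervals;
# iv: data.table with man, s, e, mult
resolve_min_multiplier <- function(iv) {
  man <- s <- e <- b <- i.s <- i.e <- NULL  # data.table NSE
  iv <- iv[iv$e > iv$s, ]
  if (!nrow(iv)) return(iv)
  iv <- data.table::as.data.table(iv)
  cnt <- iv[, .N, by = man]
  single <- iv[man %in% cnt$man[cnt$N == 1L]]
  multi <- iv[man %in% cnt$man[cnt$N > 1L]]
  if (nrow(multi)) {
    bp <- multi[, list(b = sort(unique(c(s, e)))), by = man]
    seg <- bp[, list(s = b[-length(b)], e = b[-1]), by = man]
    data.table::setkey(multi, man, s, e)
    ov <- data.table::foverlaps(seg, multi, by.x = c("man", "s", "e"),
                                type = "within", nomatch = NULL)
    res <- ov[, list(mult = min(mult)), by = list(man, i.s, i.e)]
    data.table::setnames(res, c("i.s", "i.e"), c("s", "e"))
    out <- rbind(single, res[, list(man, s, e, mult)])
  } else out <- single
  out
}

#' Accumulate quality-adjusted life-years for a strategy run
#'
#' Partitions each man's life course from age 35 to death into
#' intervals, weights them by the age-specific population norm times
#' the state multiplier (overlapping states resolved by taking the
#' minimum multiplier) and a discount factor, and integrates by yearly
#' quadrature.  Life-years are the same integral with all values 1 and
#' no discounting.
#'
#' @param run a `strategy_run` (its event log and per-man phases
#'   define the state intervals).
#' @param history the `life_history_cohort` the run was made on.
#' @param utilities a [utility_table()].
#' @param rate discount rate per year.
#' @param reference_age discount reference age (default 35, model
#'   entry).
#' @return data.frame per man: `id`, `life_years`, `qalys`,
#'   `life_years_disc`, `qalys_disc`.
#' @export
accumulate_qalys <- function(run, history, utilities, rate,
                             reference_age = 35) {
  men <- run$men
  ev <- run$events
  n <- nrow(men)
  death <- men$death_age
  W0 <- make_weight_fun(utilities, 0, reference_age)
  W1 <- make_weight_fun(utilities, rate, reference_age)
  st <- utilities$states

  iv_list <- list()
  add_iv <- function(man, s, dur_or_e, mult, until = FALSE) {
    e <- if (until) dur_or_e else s + dur_or_e
    iv_list[[length(iv_list) + 1L]] <<-
      data.frame(man = man, s = s, e = e, mult = mult)
  }
  if (nrow(ev)) {
    sv <- ev[ev$event == "screen_visit", ]
    if (nrow(sv)) add_iv(sv$man_id, sv$age, st$screening$duration,
                         st$screening$mult)
    bx <- ev[ev$event %in% c("biopsy", "symptomatic_dx"), ]
    if (nrow(bx)) add_iv(bx$man_id, bx$age, st$biopsy$duration,
                         st$biopsy$mult)
  }
  dxm <- which(men$diagnosed)
  if (length(dxm)) {
    add_iv(dxm, men$dx_age[dxm], st$diagnosis$duration, st$diagnosis$mult)
    for (tr in c("active_surveillance", "prostatectomy", "radiation")) {
      who <- dxm[men$treatment[dxm] == tr]
      if (!length(who)) next
      add_iv(who, men$dx_age[who], st[[tr]]$duration, st[[tr]]$mult)
      if (tr != "active_surveillance") {
        ps <- men$dx_age[who] + st[[tr]]$duration
        add_iv(who, ps, men$dx_age[who] + st$post_treatment$duration,
               st$post_treatment$mult, until = TRUE)
      }
    }
  }
  adv <- which(!is.na(men$adv_start))
  if (length(adv)) add_iv(adv, men$adv_start[adv], death[adv],
                          st$advanced$mult, until = TRUE)
  pcd <- which(men$pc_died)
  if (length(pcd)) add_iv(pcd, death[pcd] - st$terminal$duration,
                          death[pcd], st$terminal$mult, until = TRUE)

  life_years <- death - 35
  base0 <- W0(death)
  base1 <- W1(death)
  dec0 <- dec1 <- numeric(n)
  if (length(iv_list)) {
    iv <- do.call(rbind, iv_list)
    # clip to the lived interval
    iv$s <- pmax(iv$s, 35)
    iv$e <- pmin(iv$e, death[iv$man])
    iv <- resolve_min_multiplier(iv)
    if (nrow(iv)) {
      d0 <- (1 - iv$mult) * (W0(iv$e) - W0(iv$s))
      d1 <- (1 - iv$mult) * (W1(iv$e) - W1(iv$s))
      t0 <- tapply(d0, iv$man, sum)
      t1 <- tapply(d1, iv$man, sum)
      ids <- as.integer(names(t0))
      dec0[ids] <- t0
      dec1[ids] <- t1
    }
  }
  # discounted life-years: values 1, discount applied
  ages <- 35:110
  dw <- discount_factor(ages + 0.5 - reference_age, rate)
  cdw <- c(0, cumsum(dw))
  lyd <- function(t) {
    t <- pmin(pmax(t, 35), 111)
    fl <- pmin(floor(t), 110)
    i <- as.integer(fl) - 35L + 1L
    cdw[i] + (t - fl) * dw[pmin(i, length(dw))]
  }
  data.frame(id = men$id,
             life_years = life_years,
             qalys = base0 - dec0,
             life_years_disc = lyd(death),
             qalys_disc = base1 - dec1)
}

#' Accumulate per-man costs for a strategy run
#'
#' Each event contributes its unit cost, tagged by category
#' (screening, diagnosis, treatment, advanced disease), times the
#' discount factor at the event age.  A reflexed screening visit costs
#' the full reflex-visit total; a symptomatic diagnosis contributes
#' the configured number of diagnostic biopsies.  Productivity losses
#' follow the human-capital approach: hours lost per event times the
#' age-specific hourly wage, below the retirement age only.
#'
#' @param run a `strategy_run`.
#' @param history the `life_history_cohort` (unused fields tolerated;
#'   kept for interface symmetry).
#' @param costs a [cost_table()].
#' @param rate discount rate per year.
#' @param reference_age discount reference age.
#' @return data.frame per man: cost components and totals, discounted
#'   (`_disc`) and undiscounted, satisfying
#'   `total_direct = screening + diagnosis + treatment +
#'   advanced_disease` and `total_societal = total_direct +
#'   productivity_loss`.
#' @export
accumulate_costs <- function(run, history, costs, rate, reference_age = 35) {
  men <- run$men
  ev <- run$events
  n <- nrow(men)
  cat_names <- c("screening", "diagnosis", "treatment", "advanced_disease",
                 "productivity_loss")
  acc0 <- matrix(0, n, length(cat_names), dimnames = list(NULL, cat_names))
  acc1 <- acc0

  if (nrow(ev)) {
    amount <- numeric(nrow(ev))
    category <- character(nrow(ev))
    kind <- ev$event
    amount[kind == "screen_visit"] <-
      ifelse(ev$detail[kind == "screen_visit"] == "s3m",
             costs$s3m_test_total, costs$psa_test_total)
    category[kind == "screen_visit"] <- "screening"
    amount[kind == "biopsy"] <- costs$biopsy_episode
    category[kind == "biopsy"] <- "diagnosis"
    amount[kind == "symptomatic_dx"] <-
      costs$symptomatic_dx_biopsies * costs$biopsy_episode
    category[kind == "symptomatic_dx"] <- "diagnosis"
    amount[kind == "diagnosis"] <- 0
    category[kind == "diagnosis"] <- "diagnosis"
    if (any(kind == "treatment")) {
      mod <- ev$detail[kind == "treatment"]
      bad <- setdiff(mod, names(costs$treatment_costs))
      if (length(bad))
        stop("no treatment cost configured for modality: ",
             paste(bad, collapse = ", "))
      amount[kind == "treatment"] <- costs$treatment_costs[mod]
      category[kind == "treatment"] <- "treatment"
    }
    amount[kind == "advanced_phase"] <- costs$advanced_disease
    category[kind == "advanced_phase"] <- "advanced_disease"
    amount[kind == "pc_death"] <- costs$terminal_care
    category[kind == "pc_death"] <- "advanced_disease"
    unknown <- !kind %in% c("screen_visit", "biopsy", "symptomatic_dx",
                            "diagnosis", "treatment", "advanced_phase",
                            "pc_death")
    if (any(unknown))
      stop("no cost rule for event type: ",
           paste(unique(kind[unknown]), collapse = ", "))

    disc <- discount_factor(pmax(ev$age - reference_age, 0), rate)
    for (cc in unique(category)) {
      i <- category == cc
      a0 <- tapply(amount[i], ev$man_id[i], sum)
      a1 <- tapply(amount[i] * disc[i], ev$man_id[i], sum)
      ids <- as.integer(names(a0))
      acc0[ids, cc] <- acc0[ids, cc] + a0
      acc1[ids, cc] <- acc1[ids, cc] + a1
    }

    # productivity: hours lost per event x hourly wage at event age,
    # capped at the retirement age; treatment events use their
    # modality-specific hours
    hours <- numeric(nrow(ev))
    hkey <- ifelse(kind == "treatment", ev$detail, kind)
    known <- hkey %in% names(costs$time_lost_hours)
    hours[known] <- costs$time_lost_hours[hkey[known]]
    wage <- step_lookup(ev$age, costs$salaries$age_min,
                        costs$salaries$annual_salary) / costs$work_hours_per_year
    p <- hours * wage * (ev$age < costs$retirement_age)
    p0 <- tapply(p, ev$man_id, sum)
    p1 <- tapply(p * disc, ev$man_id, sum)
    ids <- as.integer(names(p0))
    acc0[ids, "productivity_loss"] <- p0
    acc1[ids, "productivity_loss"] <- p1
  }

  out <- data.frame(id = men$id)
  for (cc in cat_names) out[[cc]] <- acc0[, cc]
  out$total_direct <- rowSums(acc0[, 1:4, drop = FALSE])
  out$total_societal <- out$total_direct + out$productivity_loss
  for (cc in cat_names) out[[paste0(cc, "_disc")]] <- acc1[, cc]
  out$total_direct_disc <- rowSums(acc1[, 1:4, drop = FALSE])
  out$total_societal_disc <- out$total_direct_disc + out$productivity_loss_disc
  out
}
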