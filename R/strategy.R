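# Screening strategies and their execution over a simulated cohort.
# The reflex (S3M-style) pathway is realised as per-state PSA
# thresholds tau(alpha|state); positivity is a deterministic threshold
# on the modelled PSA, with no extra randomness.

TREATMENT_LEVELS <- c("active_surveillance", "prostatectomy", "radiation", "none")

#' Define a screening strategy
#'
#' @param name unique strategy name.
#' @param kind one of "none" (no screening), "psa" (PSA alone),
#'   "s3m_reflex" (PSA with a reflex test for PSA >= alpha).
#' @param alpha reflex threshold in ng/mL (s3m_reflex only).
#' @param psa_referral PSA referral-to-biopsy threshold (default 3).
#' @param psa_upper PSA level triggering direct referral without a
#'   reflex test (default 10).
#' @param start_age,stop_age,interval quadrennial schedule bounds:
#'   screens at `seq(start_age, stop_age, interval)`.
#' @param biopsy_compliance probability a referred man is biopsied.
#' @param post70_followup if `TRUE`, men test-positive and
#'   biopsy-negative at their final scheduled screen get one follow-up
#'   retest `interval/2` years later (clinical follow-up after the
#'   stopping age).
#' @param biopsy_sensitivity probability a biopsy detects an existing
#'   cancer (default 1: the biopsy reveals the latent state).
#' @return a `strategy_spec`.
#' @export
strategy_spec <- function(name, kind = c("none", "psa", "s3m_reflex"),
                          alpha = NA_real_, psa_referral = 3, psa_upper = 10,
                          start_age = 55, stop_age = 69, interval = 4,
                          biopsy_compliance = 0.9, post70_followup = TRUE,
                          biopsy_sensitivity = 1.0) {
  kind <- match.arg(kind)
  stopifnot(start_age < stop_age, interval >= 1,
            psa_referral > 0, psa_upper > psa_referral,
            biopsy_compliance >= 0, biopsy_compliance <= 1)
  if (kind == "s3m_reflex") {
    stopifnot(is.finite(alpha), alpha > 0, alpha < psa_referral)
  }
  structure(list(name = name, kind = kind, alpha = alpha,
                 psa_referral = psa_referral, psa_upper = psa_upper,
                 start_age = start_age, stop_age = stop_age,
                 interval = interval, biopsy_compliance = biopsy_compliance,
                 post70_followup = post70_followup,
                 biopsy_sensitivity = biopsy_sensitivity),
            class = "strategy_spec")
}

screen_schedule <- function(spec) {
  if (spec$kind == "none") return(numeric(0))
  seq(spec$start_age, spec$stop_age, by = spec$interval)
}

# extent index (1 localised, 2 advanced, 3 metastatic) at an age
extent_at <- function(history, age) {
  e <- 1L + (history$t_advanced_age <= age) + (history$t_metastatic_age <= age)
  e[is.na(history$onset_age) | history$onset_age > age] <- NA_integer_
  e
}

#' Execute a screening strategy over a cohort
#'
#' Runs the screening pathway at the scheduled ages: PSA pathway
#' refers to biopsy at PSA >= `psa_referral`; the reflex pathway
#' refers immediately at PSA >= `psa_upper` and otherwise evaluates
#' the reflex test for `alpha <= PSA < psa_upper`, positive when
#' PSA >= tau(alpha|state).  Referred men are biopsied with
#' probability `biopsy_compliance`; a biopsy reveals the latent state.
#' A positive biopsy yields a screen-detected diagnosis; clinical
#' diagnosis occurs at the latent clinical diagnosis age when not
#' pre-empted.  Prostate-cancer survival is re-indexed to the state at
#' detection but remains anchored at the (possibly counterfactual)
#' clinical diagnosis age, so earlier detection helps only through the
#' better state at detection.
#'
#' All randomness comes from per-man uniforms drawn with the cohort,
#' so strategies compared on one cohort share random numbers.
#'
#' @param cohort a `life_history_cohort`.
#' @param spec a [strategy_spec()].
#' @param tau a `tau_table` for `spec$alpha` (reflex strategies only).
#' @param params the [nh_params()] of the cohort (defaults to the
#'   cohort attribute).
#' @param treatment_probs 3x3 matrix (Gleason x modality
#'   active_surveillance/prostatectomy/radiation) of assignment
#'   probabilities for non-metastatic diagnoses.
#' @param symptomatic_dx_biopsies average diagnostic biopsies per
#'   symptomatic diagnosis (default 2).
#' @return a `strategy_run`: list with `spec`, `men` (one row per man:
#'   counts, diagnosis, treatment, phases, death ages under this
#'   strategy, overdiagnosis flag) and `events` (long log: man_id,
#'   age, event, detail).
#' @export
run_strategy <- function(cohort, spec, tau = NULL,
                         params = attr(cohort, "params"),
                         treatment_probs = default_treatment_probs(),
                         symptomatic_dx_biopsies = 2) {
  n <- nrow(cohort)
  if (spec$kind == "s3m_reflex" && is.null(tau))
    stop("reflex strategy requires a tau table")
  schedule <- screen_schedule(spec)
  if (spec$kind != "none" && length(schedule) == 0)
    warning("schedule produces zero screens")
  fu_age <- if (length(schedule)) schedule[length(schedule)] + spec$interval / 2
  ages <- c(schedule, if (spec$kind != "none" && spec$post70_followup) fu_age)
  n_occ <- length(ages)
  if (n_occ > N_SCREEN_OCCASIONS)
    stop("schedule exceeds the ", N_SCREEN_OCCASIONS,
         " reserved screening occasions per man")

  detected <- rep(FALSE, n)
  dx_age <- rep(NA_real_, n)
  det_extent <- rep(NA_integer_, n)
  flag_fu <- rep(FALSE, n)
  n_screens <- n_s3m <- n_biopsies <- n_negbx <- integer(n)
  ev_man <- ev_age <- ev_detail <- list(); ev_event <- list()
  push <- function(man, age, event, detail) {
    k <- length(ev_man) + 1L
    ev_man[[k]] <<- man; ev_age[[k]] <<- age
    ev_event[[k]] <<- rep(event, length(man)); ev_detail[[k]] <<- detail
  }
  cdx <- cohort$clinical_dx_age

  for (j in seq_len(n_occ)) {
    a <- ages[j]
    elig <- !detected & a < cohort$other_death_age & (is.na(cdx) | a < cdx)
    if (j > length(schedule)) elig <- elig & flag_fu
    idx <- which(elig)
    if (!length(idx)) next
    h <- cohort[idx, ]
    psa <- psa_value(h, a, params, noise_q = h[[paste0("u_noise", j)]])
    st <- latent_state(h, a)
    if (spec$kind == "psa") {
      referred <- psa >= spec$psa_referral
      reflexed <- rep(FALSE, length(idx))
    } else {
      direct <- psa >= spec$psa_upper
      reflexed <- psa >= spec$alpha & psa < spec$psa_upper
      tv <- tau$tau[match(st, tau$state)]
      referred <- direct | (reflexed & psa >= tv)
    }
    n_screens[idx] <- n_screens[idx] + 1L
    n_s3m[idx] <- n_s3m[idx] + reflexed
    push(idx, rep(a, length(idx)), "screen_visit",
         ifelse(reflexed, "s3m", "psa"))

    ub <- h[[paste0("u_biopsy", j)]]
    biopsied <- referred & ub < spec$biopsy_compliance
    cancer <- st != "benign"
    found <- cancer
    if (spec$biopsy_sensitivity < 1)
      found <- cancer & (h$u_spare < spec$biopsy_sensitivity)
    newly <- biopsied & found
    negbx <- biopsied & !found
    n_biopsies[idx] <- n_biopsies[idx] + biopsied
    n_negbx[idx] <- n_negbx[idx] + negbx
    if (any(biopsied)) {
      reason <- if (j > length(schedule)) "followup" else "screen"
      push(idx[biopsied], rep(a, sum(biopsied)), "biopsy",
           rep(reason, sum(biopsied)))
    }
    if (any(newly)) {
      who <- idx[newly]
      detected[who] <- TRUE
      dx_age[who] <- a
      det_extent[who] <- extent_at(cohort[who, ], a)
    }
    if (j == length(schedule)) flag_fu[idx] <- negbx
  }

  # clinical diagnoses not pre-empted by screen detection
  clin <- !detected & !is.na(cdx) & cdx < cohort$other_death_age
  dx_age[clin] <- cdx[clin]
  det_extent[clin] <- as.integer(cohort$dx_extent)[clin]
  n_biopsies[clin] <- n_biopsies[clin] + as.integer(symptomatic_dx_biopsies)
  n_negbx[clin] <- n_negbx[clin] + as.integer(symptomatic_dx_biopsies) - 1L
  if (any(clin))
    push(which(clin), cdx[clin], "symptomatic_dx",
         rep(sprintf("%d_biopsies", as.integer(symptomatic_dx_biopsies)),
             sum(clin)))

  diagnosed <- detected | clin
  mode <- ifelse(detected, "screen_detected", ifelse(clin, "clinical", NA))
  gl <- as.integer(cohort$gleason)

  # survival indexed by state at detection, anchored at the clinical
  # diagnosis age (shared survival quantile re-indexed to the
  # detection state)
  pc_death <- rep(NA_real_, n)
  anchored <- diagnosed & !is.na(cdx)
  if (any(anchored)) {
    rate <- params$surv_rates[cbind(gl[anchored], det_extent[anchored])]
    pc_death[anchored] <- cdx[anchored] +
      stats::qexp(cohort$u_surv[anchored], rate = pmax(rate, 1e-300))
  }
  death_age <- pmin(ifelse(is.na(pc_death), Inf, pc_death),
                    cohort$other_death_age)
  pc_died <- !is.na(pc_death) & pc_death <= cohort$other_death_age

  # treatment for non-metastatic diagnoses; metastatic disease goes to
  # advanced-disease management directly
  treatment <- rep("none", n)
  tm <- diagnosed & det_extent < 3L
  tm[is.na(tm)] <- FALSE
  if (any(tm)) {
    pr <- treatment_probs[gl[tm], , drop = FALSE]
    cum <- t(apply(pr, 1, cumsum))
    pick <- rowSums(cohort$u_treat[tm] > cum) + 1L
    pick[pick > 3L] <- 3L
    treatment[tm] <- TREATMENT_LEVELS[pick]
  }
  if (any(diagnosed)) {
    who <- which(diagnosed)
    push(who, dx_age[who], "diagnosis", mode[who])
    push(who, dx_age[who], "treatment", treatment[who])
  }

  # advanced-disease phase: metastatic disease in a diagnosed man,
  # from detection (if metastatic then) or latent metastatic
  # progression, until death
  adv_start <- rep(NA_real_, n)
  met_at_dx <- diagnosed & det_extent == 3L
  met_at_dx[is.na(met_at_dx)] <- FALSE
  adv_start[met_at_dx] <- dx_age[met_at_dx]
  later <- diagnosed & !met_at_dx & !is.na(cohort$t_metastatic_age) &
    cohort$t_metastatic_age < death_age
  adv_start[later] <- pmax(cohort$t_metastatic_age[later], dx_age[later])
  if (any(!is.na(adv_start)))
    push(which(!is.na(adv_start)), adv_start[!is.na(adv_start)],
         "advanced_phase", rep("start", sum(!is.na(adv_start))))
  if (any(pc_died))
    push(which(pc_died), death_age[pc_died], "pc_death",
         rep("terminal", sum(pc_died)))

  overdx <- detected & (is.na(cdx) | cdx > cohort$other_death_age)

  men <- data.frame(
    id = cohort$id, n_screens = n_screens, n_s3m = n_s3m,
    n_biopsies = n_biopsies, n_neg_biopsies = n_negbx,
    diagnosed = diagnosed, dx_age = dx_age, dx_mode = mode,
    dx_gleason = ifelse(diagnosed, GLEASON_LEVELS[gl], NA),
    dx_extent = ifelse(diagnosed, EXTENT_LEVELS[det_extent], NA),
    treatment = treatment, adv_start = adv_start,
    pc_death_age = pc_death, death_age = death_age, pc_died = pc_died,
    overdiagnosed = overdx)
  events <- data.frame(
    man_id = unlist(ev_man), age = unlist(ev_age),
    event = unlist(ev_event), detail = unlist(ev_detail))
  if (!nrow(events))
    events <- data.frame(man_id = integer(0), age = numeric(0),
                         event = character(0), detail = character(0))
  structure(list(spec = spec, men = men,
                 events = events[order(events$man_id, events$age), ]),
            class = "strategy_run")
}

#' Default treatment assignment probabilities
#'
#' Synthetic modality mix over active surveillance, radical
#' prostatectomy and radiation therapy by Gleason grade, for
#' non-metastatic diagnoses.
#' @return 3x3 probability matrix (rows GS6/GS7/GS8plus).
#' @export
default_treatment_probs <- function() {
  m <- rbind(GS6 = c(0.60, 0.25, 0.15),
             GS7 = c(0.10, 0.50, 0.40),
             GS8plus = c(0.05, 0.35, 0.60))
  colnames(m) <- TREATMENT_LEVELS[1:3]
  m
}

#' Classify screening outcomes for a run
#'
#' Applies the lifetime definitions: a screen-detected cancer is an
#' asymptomatic cancer found through a screening-initiated biopsy; an
#' overdiagnosed cancer is a screen-detected cancer in a man whose
#' counterfactual clinical diagnosis never occurs before other-cause
#' death.
#'
#' @param run a `strategy_run`.
#' @param cohort the `life_history_cohort` it was run on.
#' @return data.frame with `id`, `screen_detected`, `overdiagnosed`,
#'   `detection_state` (Gleason x extent label or NA).
#' @export
classify_outcomes <- function(run, cohort) {
  m <- run$men
  stopifnot(nrow(m) == nrow(cohort))
  sd <- !is.na(m$dx_mode) & m$dx_mode == "screen_detected"
  od <- sd & (is.na(cohort$clinical_dx_age) |
                cohort$clinical_dx_age > cohort$other_death_age)
  data.frame(id = m$id, screen_detected = sd, overdiagnosed = od,
             detection_state = ifelse(m$diagnosed,
                                      paste(m$dx_gleason, m$dx_extent, sep = "/"),
                                      NA_character_))
}
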