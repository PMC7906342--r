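# Internal numerical helpers shared across modules.

# data.table is used through :: calls only
.datatable.aware <- TRUE

#' Sample event times from a piecewise-constant hazard
#'
#' Inverts the cumulative hazard of a piecewise-constant rate function
#' for a vector of exponential(1) deviates.  Used for other-cause
#' mortality (life-table hazards) and age-dependent onset.
#'
#' @param e numeric vector of exponential(1) deviates (-log(u)).
#' @param breaks segment start times, first element is the time origin.
#' @param rates hazard per segment (length equal to `breaks`); the last
#'   segment extends to `horizon`.
#' @param horizon upper bound; times beyond it return `NA`.
#' @return event times (same length as `e`), `NA` where the cumulative
#'   hazard up to `horizon` is smaller than `e`.
#' @keywords internal
#' @noRd
sample_pwc <- function(e, breaks, rates, horizon = 110) {
  stopifnot(length(breaks) == length(rates), !is.unsorted(breaks))
  widths <- diff(c(breaks, horizon))
  widths[widths < 0] <- 0
  seg_h <- rates * widths
  cumh <- c(0, cumsum(seg_h))
  total <- cumh[length(cumh)]
  idx <- findInterval(e, cumh, rightmost.closed = FALSE)
  idx[idx > length(rates)] <- length(rates)
  t <- breaks[idx] + (e - cumh[idx]) / rates[idx]
  t[e >= total] <- NA_real_
  # zero-rate segments cannot host events; findInterval already skips
  # them because their cumulative-hazard increment is zero
  t
}

#' Triangular-distribution quantile function (symmetric, mode `mode`)
#' @keywords internal
#' @noRd
qtriangular <- function(p, lower, mode, upper) {
  stopifnot(all(lower <= mode & mode <= upper))
  fc <- (mode - lower) / (upper - lower)
  ifelse(p < fc,
         lower + sqrt(p * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
}

#' Derive a bounded sub-seed from a root seed
#'
#' Deterministic per-stage seed stream, kept below 2^31 so it is always
#' a valid R integer seed.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(cohort = 101L, trial = 211L, tau = 307L, psa_draws = 401L,
               economics = 503L, misc = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 9973) %% 2147483647)
}

# step-function lookup: value of `values[i]` for x in [breaks[i], breaks[i+1])
step_lookup <- function(x, breaks, values) {
  idx <- findInterval(x, breaks)
  idx[idx < 1] <- 1L
  values[idx]
}
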