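# Life tables: annual other-cause death probabilities and their
# conversion to piecewise-constant hazards for continuous-time
# competing-risks simulation.

#' Construct a life table from a Gompertz mortality model
#'
#' Annual death probability at age \eqn{x} is
#' \eqn{q_x = 1 - \exp(-a e^{bx})}, capped at 1; the terminal age is
#' forced to probability 1 so cumulative survival reaches zero.
#'
#' @param a Gompertz baseline hazard (per year), `a > 0` (a value of 0
#'   is accepted and gives the zero-hazard limit).
#' @param b Gompertz log-hazard slope (per year of age), `b > 0`.
#' @param terminal_age last age of the table (everyone dies by then),
#'   at most 110.
#' @return a `life_table`: data.frame with integer `age` (0 to
#'   `terminal_age`) and `qx`, the annual other-cause death probability.
#' @examples
#' lt <- gen_lifetable(1e-5, 0.1)
#' lt$qx[lt$age == 70]  # about 0.0109
#' @export
gen_lifetable <- function(a = 2e-5, b = 0.095, terminal_age = 110) {
  stopifnot(is.finite(a), is.finite(b), a >= 0, b >= 0,
            terminal_age <= 110, terminal_age >= 1)
  age <- 0:terminal_age
  qx <- pmin(1, 1 - exp(-a * exp(b * age)))
  qx[length(qx)] <- 1
  structure(data.frame(age = age, qx = qx), class = c("life_table", "data.frame"))
}

#' Validate a life table
#' @param lt object to validate.
#' @return `lt`, invisibly; errors on violation.
#' @export
validate_lifetable <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "qx") %in% names(lt)))
  stopifnot(all(lt$age == seq(min(lt$age), max(lt$age))))
  stopifnot(all(lt$qx >= 0 & lt$qx <= 1))
  if (lt$qx[nrow(lt)] != 1)
    stop("terminal age of a life table must carry death probability 1")
  invisible(lt)
}

# piecewise-constant other-cause hazard from `from_age` on:
# h_x = -log(1 - q_x) per one-year age band; Inf at the terminal age.
lifetable_hazard <- function(lt, from_age = 35) {
  lt <- lt[lt$age >= from_age, ]
  h <- -log1p(-lt$qx)
  list(breaks = as.numeric(lt$age), rates = h,
       horizon = max(lt$age) + 1)
}

# Sample other-cause death ages conditional on being alive at
# `from_age`, from exponential(1) deviates `e`.  Deaths within the
# terminal year collapse onto the terminal age (hazard is infinite
# there), so no NA is possible.
sample_other_death <- function(e, lt, from_age = 35) {
  hz <- lifetable_hazard(lt, from_age)
  finite <- is.finite(hz$rates)
  cumh <- c(0, cumsum(ifelse(finite, hz$rates, 0)))
  # age bands with finite hazard; anything surviving them dies at the
  # terminal age
  nb <- sum(finite)
  idx <- findInterval(e, cumh[seq_len(nb + 1)])
  idx[idx > nb] <- NA_integer_
  t <- hz$breaks[idx] + (e - cumh[idx]) / hz$rates[idx]
  t[is.na(t)] <- max(hz$breaks)
  pmin(t, hz$horizon)
}
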