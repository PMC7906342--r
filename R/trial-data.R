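# Paired-design trial datasets: one record per man with a PSA value,
# a disease state and a reflex-test (S3M) positivity flag.  The
# generator produces data whose relative positive fractions match
# supplied targets in expectation, emulating the screen-positive
# paired design the reflex-test characteristics were estimated from.

#' Generate a paired-design trial dataset with target relative
#' positive fractions
#'
#' Records are drawn per state from a log-normal PSA distribution.
#' Reflex-test positivity follows the mechanism that defines the
#' relative positive fraction \eqn{r(\alpha|D)}: within the window
#' \eqn{\alpha \le PSA < 10}, every record with \eqn{PSA \ge 3} is
#' positive with probability `min(r, 1)`, and for targets above 1 the
#' excess positivity is placed on records with \eqn{PSA < 3}.  The
#' estimand \eqn{r = \Pr(S3M+)/\Pr(3 \le PSA < 10)} (both conditional
#' on state and window) then equals the target in expectation.
#'
#' @param n number of records (at least 1).
#' @param target_rpf data.frame with columns `state`
#'   (benign/GS6/GS7plus) and `r` (targets in (0, 1.2]).
#' @param alpha reflex threshold in ng/mL, one of 1, 1.5, 2.
#' @param psa_model per-state log-normal parameters: named list of
#'   `c(meanlog, sdlog)` for benign, GS6, GS7plus.
#' @param state_probs mixture over states for the records.
#' @param seed integer seed.
#' @return a `trial_dataset`: data.frame with columns `psa` (ng/mL),
#'   `state`, `s3m_positive`.
#' @export
gen_trial_dataset <- function(n, target_rpf, alpha,
                              psa_model = default_trial_psa_model(),
                              state_probs = c(benign = 0.70, GS6 = 0.18,
                                              GS7plus = 0.12),
                              seed = 1L) {
  stopifnot(n >= 1, alpha %in% c(1, 1.5, 2))
  stopifnot(all(target_rpf$r > 0), all(target_rpf$r <= 1.2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  state <- sample(STATE_LEVELS, n, replace = TRUE,
                  prob = state_probs[STATE_LEVELS])
  psa <- numeric(n)
  for (s in STATE_LEVELS) {
    i <- state == s
    pm <- psa_model[[s]]
    psa[i] <- stats::rlnorm(sum(i), meanlog = pm[1], sdlog = pm[2])
  }
  pos <- rep(FALSE, n)
  window <- psa >= alpha & psa < 10
  for (s in STATE_LEVELS) {
    r <- target_rpf$r[target_rpf$state == s]
    stopifnot(length(r) == 1)
    iw <- which(window & state == s)
    hi <- psa[iw] >= 3
    p3 <- mean(hi)
    if (r <= 1) {
      pos[iw[hi]] <- stats::runif(sum(hi)) < r
    } else {
      # every record at or above the referral threshold is positive and
      # the excess positivity sits below it
      b <- (r - 1) * p3 / (1 - p3)
      if (!is.finite(b) || b > 1)
        stop("target r = ", r, " for state ", s,
             " implies positivity probability > 1 under this PSA model")
      pos[iw[hi]] <- TRUE
      pos[iw[!hi]] <- stats::runif(sum(!hi)) < b
    }
  }
  structure(data.frame(psa = psa, state = factor(state, STATE_LEVELS),
                       s3m_positive = pos),
            alpha = alpha, class = c("trial_dataset", "data.frame"))
}

#' Default per-state PSA distribution for trial generation
#'
#' Right-skewed log-normals with state-specific location: benign
#' lowest, Gleason 7 or above highest.  Only the conditional window
#' fractions matter to the relative-positive-fraction estimand.
#' @return named list of `c(meanlog, sdlog)` per state.
#' @export
default_trial_psa_model <- function() {
  list(benign = c(meanlog = 0.3, sdlog = 0.8),
       GS6 = c(meanlog = 1.1, sdlog = 0.7),
       GS7plus = c(meanlog = 1.5, sdlog = 0.7))
}

#' Read or write a trial dataset as CSV
#' @param x a `trial_dataset`.
#' @param path CSV file path.
#' @return `read_trial_dataset` returns a `trial_dataset`.
#' @export
write_trial_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("psa", "state", "s3m_positive") %in% names(d)))
  stopifnot(all(is.finite(d$psa)), all(d$psa > 0))
  stopifnot(all(d$state %in% STATE_LEVELS))
  structure(data.frame(psa = d$psa, state = factor(d$state, STATE_LEVELS),
                       s3m_positive = as.logical(d$s3m_positive)),
            class = c("trial_dataset", "data.frame"))
}
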