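#!/usr/bin/env Rscript
# Reflex-test characteristics: generate paired-design trial data with
# the published relative-positive-fraction targets, re-estimate the
# fractions with bootstrap intervals, and calibrate the per-state PSA
# thresholds tau(alpha|state) on a simulated screening cohort.
#
# Finding (typical run): the estimator recovers the targets to two
# decimals at 200,000 records, and tau rises as r falls -- the
# mechanism by which the reflex test skips low-PSA benign biopsies.

suppressPackageStartupMessages(library(prostacea))

sc <- read_scenario("results/scenario.yaml")
ref_rpf <- sc$rpf

est_rows <- list()
tau_rows <- list()
cohort <- simulate_cohort(sc$natural_history, sc$life_table, 50000,
                          seed = sc$seeds$tau)
for (alpha in c(1, 1.5, 2)) {
  targets <- ref_rpf[ref_rpf$alpha == alpha, c("state", "r")]
  trial <- gen_trial_dataset(200000, targets, alpha,
                             seed = sc$seeds$trial + round(10 * alpha))
  est <- estimate_rpf(trial, alpha, n_boot = 200)
  est$target <- targets$r[match(est$state, targets$state)]
  est_rows[[as.character(alpha)]] <- est

  refsample <- build_reference_sample(cohort, sc$natural_history,
                                      c(55, 59, 63, 67), alpha)
  tau <- calibrate_tau(refsample, alpha, ref_rpf)
  tau_rows[[as.character(alpha)]] <- tau
}

est_all <- do.call(rbind, est_rows)
tau_all <- do.call(rbind, tau_rows)
write.csv(est_all, "results/rpf_estimates.csv", row.names = FALSE)
write.csv(tau_all, "results/tau_tables.csv", row.names = FALSE)

cat("Relative positive fractions (estimated vs target):\n")
print(est_all, digits = 3, row.names = FALSE)
cat("\nCalibrated PSA test-characteristic thresholds (ng/mL):\n")
print(tau_all, digits = 3, row.names = FALSE)
stopifnot(max(abs(est_all$r - est_all$target), na.rm = TRUE) < 0.02)
cat("\nAll estimates within 0.02 of their targets.\n")
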