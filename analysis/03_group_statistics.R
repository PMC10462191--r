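#!/usr/bin/env Rscript

## Step 3 — group statistics on the measured MMN amplitudes: the linear
## mixed-effects model (SOA x Condition x Group fixed effects, random
## intercept + age slope per subject, REML), planned DEV-vs-STD contrasts
## per group and SOA (one-tailed toward negativity), JZS Bayes factors
## (Cauchy scale 0.707), and bootstrap Spearman age correlations.

suppressPackageStartupMessages(library(oddballmmn))

seed <- 20260926
measurements <- read.csv("results/measurements.csv")

fit <- fit_mmn_lme(amplitude_long_table(measurements), covariate = "group")
write.csv(fit$coefficients, "results/lme_fixed_effects.csv", row.names = FALSE)
cat("LME fixed effects (treatment coding; TD/STD/450 ms reference):\n")
print(fit$coefficients[, c("term", "beta", "se", "t", "p")], digits = 3)
cat(sprintf("\nWith- vs without-age likelihood ratio: chi2(%d) = %.2f, p = %.3g\n",
            fit$age_comparison$df, fit$age_comparison$chisq,
            fit$age_comparison$p))

cat("\nPlanned DEV-vs-STD contrasts (one-tailed toward negativity):\n")
combos <- expand.grid(group = c("TD", "CLN3"), soa = c(450, 900, 1800),
                      stringsAsFactors = FALSE)
contrasts <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
  ct <- planned_mmn_contrast(measurements, combos$group[i], combos$soa[i])
  bf <- jzs_bayes_ttest(
    measurements$amp_dev[measurements$group == combos$group[i] &
                           measurements$soa == combos$soa[i]],
    measurements$amp_std[measurements$group == combos$group[i] &
                           measurements$soa == combos$soa[i]],
    seed = derive_seed(seed, "bf", i))
  data.frame(group = combos$group[i], soa = combos$soa[i], n = ct$n,
             t = ct$t, p = ct$p, mean_diff = ct$mean_diff, bf10 = bf$bf10)
}))
print(contrasts, digits = 3)
write.csv(contrasts, "results/planned_contrasts.csv", row.names = FALSE)

cat("\nAge correlations (Spearman, 1000-resample percentile bootstrap):\n")
cors <- do.call(rbind, lapply(c("TD", "CLN3"), function(g) {
  sel <- measurements$group == g
  r <- robust_spearman_bootstrap(measurements$age[sel], measurements$mmn[sel],
                                 seed = derive_seed(seed, "corr", g))
  data.frame(group = g, rs = r$rs, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
             significant = r$significant, n = r$n)
}))
print(cors, digits = 3)
write.csv(cors, "results/age_correlations.csv", row.names = FALSE)
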