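#!/usr/bin/env Rscript
# Stage 7 — sample-size adequacy: resampling stability and empirical power.
#
# Fresh generator draws at n = 10, 20, 30, 40 per group estimate how the
# leave-one-out PLS-DA accuracy stabilises with n, and the fraction of
# replicates whose permutation test rejects at alpha = 0.05 gives the
# empirical power per n.

suppressPackageStartupMessages(library(evspec))

profile <- reproduce_profile()
n_grid <- c(10, 20, 30, 40)

curve <- stability_curve(profile, n_grid = n_grid, reps = 50, seed = 7)
power <- vapply(n_grid, function(n)
  as.numeric(empirical_power(profile, n = n, alpha = 0.05, reps = 50,
                             n_perm = 199, seed = 7 + n)), numeric(1))
curve$power <- power
power_report(curve, "results/power_curve.csv",
             meta = list(alpha = 0.05, reps = 50, n_perm = 199, seed = 7))

print(as.data.frame(curve))
cat(sprintf("accuracy stabilises (within 0.02 of the n = 40 mean) from n = %d\n",
            attr(curve, "stable_n")))
cat(sprintf("empirical power at n = 30: %.0f%%\n",
            100 * power[n_grid == 30]))
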