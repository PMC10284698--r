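#!/usr/bin/env Rscript
# Interfacial adaptation kinetics: generate contact-time force curves under
# the third-order cooperative law, pool them, select the reaction order by
# AICc, and summarize repeat-force variability on fluctuating vs rigid
# surfaces.

suppressPackageStartupMessages(library(sterolentropy))
dir.create("results", showWarnings = FALSE)

## 100 replicate curves, 12 contact times spanning 0-60 s, 5% noise
params <- kinetics_params(noise_cv = 0.05, seed = 42)
curves <- gen_adhesion_force_curves(params,
                                    times = seq(0, 60, length.out = 12),
                                    n_curves = 100)
pooled <- pool_curves(curves)
sel <- select_order(pooled, orders = 1:4)

cat("== reaction-order selection (pooled mean curve, AICc) ==\n")
print(sel$table[, c("order", "aicc", "r_squared", "kappa")], row.names = FALSE)
cat(sprintf("selected order: %d (generated at order %d)\n\n",
            sel$order, params$order))

best <- fit_kinetics(pooled, sel$order)
cat(sprintf("lumped rate kappa = %.4f +/- %.4f s^-1, F_inf = %.3f nN, R^2 = %.5f\n\n",
            best$kappa, best$kappa_se, best$force_scale, best$r_squared))

write_pipeline_csv(sel$table, "results/kinetics_order_selection.csv",
                   meta = list(generator = "gen_adhesion_force_curves",
                               seed = params$seed, n_curves = 100,
                               noise_cv = params$noise_cv))

## repeat-force variability: 16 sequential points per location
set.seed(42)
scl <- data.frame(force_nN = 2 * rlnorm(16 * 6, sdlog = 0.3),
                  location_id = rep(sprintf("scl_loc%d", 1:6), each = 16),
                  condition = "cholesterol_scl")
sam <- data.frame(force_nN = 2 + rnorm(16 * 6, sd = 0.06),
                  location_id = rep(sprintf("sam_loc%d", 1:6), each = 16),
                  condition = "thiocholesterol_sam")
rf <- normalize_repeat_forces(rbind(scl, sam))
cat("== repeat-force dispersion (CV of mean-normalized sequences) ==\n")
print(rf$cv_by_condition, row.names = FALSE)
write_pipeline_csv(rf$cv_by_location, "results/repeat_force_cv.csv",
                   meta = list(seed = 42))
cat("\nThe fluctuating SCL surface shows the larger repeat-force CV,\n",
    "consistent with an orientationally mobile interface.\n", sep = "")
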