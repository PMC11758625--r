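#!/usr/bin/env Rscript
# Step 3: absorption-pathway variant comparison on synthetic arms.
#
# The raw serum profiles behind the published fit are not deposited, so the
# estimation pipeline is exercised on synthetic data with the study's shape:
# 2 g and 4 g arms, 7-point schedule, 10 subjects per arm, 30% proportional
# noise, truth in the strongly saturated regime of the calibrated model.
# All three variants (full, non-saturable-only, saturable-only) are fitted
# simultaneously to both arm means and compared by least-squares AIC and
# final SSR.
#
# Outputs: results/synthetic_arms.csv, results/variant_comparison.csv,
#          results/fit_full.json

suppressPackageStartupMessages(library(ketodose))
dir.create("results", showWarnings = FALSE)

truth <- pk_params(CL = 1.82, C0 = 0.063, ka = 0.02, Km_prime = 2,
                   Vd = 85.7, Vmax = 0.48)
g <- generate_serum_profiles(truth, doses = c(2, 4), n_subjects = 10,
                             noise_cv = 0.30, seed = 20240101)
write_arms_csv(g$arms, "results/synthetic_arms.csv")

cmp <- compare_pk_variants(g$arms, fit_options(n_starts = 8, seed = 20240101))
print(cmp)
utils::write.csv(cmp$table, "results/variant_comparison.csv",
                 row.names = FALSE)

fit <- cmp$fits$full
print(fit)
est <- unlist(fit$params[c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax")])
jsonlite::write_json(
  list(variant = fit$variant,
       estimates = as.list(est),
       sd = as.list(fit$param_sd),
       ssr = fit$ssr, aic = fit$aic,
       n_obs = fit$n_obs, n_params = fit$n_params,
       converged = fit$converged, sd_reliable = fit$sd_reliable),
  "results/fit_full.json", auto_unbox = TRUE, digits = NA)

message("Selected variant: ", cmp$selected,
        " (lowest AIC, near-ties broken by lower final SSR)")
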