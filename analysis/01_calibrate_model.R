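#!/usr/bin/env Rscript
# Step 1: build the working one-compartment model for oral 3-HB.
#
# The disposition parameters are fixed at their published point estimates
# (CL = 1.82 L/min, C0 = 0.063 mM, Vd = 85.7 L) and the three absorption
# parameters (Vmax, Km', ka) are calibrated by least squares so that the
# simulated 2 g and 4 g profiles reproduce the printed peak summaries
# (0.266 mM at 30 min; 0.289 mM at 45 min) as closely as the model allows.
#
# Outputs: results/calibrated_params.json, results/calibration_residuals.csv,
#          results/profile_{2,3,3.5,4}g.csv

suppressPackageStartupMessages(library(ketodose))
dir.create("results", showWarnings = FALSE)

fixed <- list(CL = 1.82, C0 = 0.063, Vd = 85.7)
constraints <- data.frame(dose_g = c(2, 4),
                          cmax_mM = c(0.266, 0.289),
                          tmax_min = c(30, 45))

cal <- withCallingHandlers(
  calibrate_absorption(fixed, constraints, seed = 20240101),
  warning = function(w) {
    message("note: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
print(cal)

calib <- attr(cal, "calibration")
res <- data.frame(quantity = names(calib$residuals),
                  relative_error = as.numeric(calib$residuals))
print(res)
message(sprintf("residual norm %.3f (feasible within 5%%: %s)",
                sqrt(calib$ssr), calib$feasible))
message("The peak times are matched closely; the model cannot raise the 2 g ",
        "peak to the printed mean with the disposition parameters fixed - ",
        "a monotone-emptying gut caps Cmax at 30 min below that value.")

write_pk_params(cal, "results/calibrated_params.json")
utils::write.csv(res, "results/calibration_residuals.csv", row.names = FALSE)

for (d in c(2, 3, 3.5, 4)) {
  prof <- pk_simulate(cal, d, t_end = 240, grid_step = 0.1)
  ct <- summarize_cmax(prof)
  message(sprintf("dose %.1f g: Cmax %.4f mM at %.1f min", d, ct$cmax, ct$tmax))
  write_profile_csv(prof[seq(1, nrow(prof), by = 10), ],
                    sprintf("results/profile_%sg.csv", d))
}
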