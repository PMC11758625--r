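test_that("noise-free two-arm data recovers all six parameters", {
  truth <- test_truth()
  g <- generate_serum_profiles(truth, noise_cv = 0, seed = 1)
  fit <- fit_pk_model(g$arms, fit_options(n_starts = 20, seed = 11))
  rel <- abs(unlist(fit$params[kin_names]) / unlist(truth[kin_names]) - 1)
  expect_lt(max(rel), 0.01)
  expect_lt(fit$ssr, 1e-10)
  expect_true(fit$converged)
})

test_that("reduced-variant truth is recovered by its own variant and nested by the full model", {
  truth_ns <- pk_params(CL = 1.8, C0 = 0.06, ka = 0.03, Km_prime = 25,
                        Vd = 90, Vmax = 0)
  g <- generate_serum_profiles(truth_ns, noise_cv = 0, seed = 2,
                               variant = "nonsaturable_only")
  fit <- fit_pk_model(g$arms, fit_options(variant = "nonsaturable_only",
                                          n_starts = 10, seed = 3))
  expect_lt(fit$ssr, 1e-10)
  # The first-order model is identified only up to the classic flip-flop
  # ambiguity (absorption and elimination rates exchange): the fitted
  # {ka, CL/Vd} pair must match the generating pair as a set, and the
  # baseline must match exactly.
  rates_fit <- sort(c(fit$params$ka, fit$params$CL / fit$params$Vd))
  rates_truth <- sort(c(truth_ns$ka, truth_ns$CL / truth_ns$Vd))
  expect_equal(rates_fit, rates_truth, tolerance = 0.01)
  expect_equal(fit$params$C0, truth_ns$C0, tolerance = 0.01)

  cmp <- compare_pk_variants(g$arms, fit_options(n_starts = 6, seed = 4))
  ssr <- stats::setNames(cmp$table$ssr, cmp$table$variant)
  expect_lte(ssr[["full"]], ssr[["nonsaturable_only"]])
  expect_lte(ssr[["full"]], ssr[["saturable_only"]])
  # Boundary recovery: the full fit reproduces the linear-truth curve.
  pred <- ketodose:::conc_at_times(fit$params, 4, c(5, 15, 30, 45, 60, 120))
  pred_full <- ketodose:::conc_at_times(cmp$fits$full$params, 4,
                                        c(5, 15, 30, 45, 60, 120))
  expect_lt(max(abs(pred - pred_full)), 1e-4)
})

test_that("degenerate designs are refused", {
  p <- test_truth()
  # Only a dose-0 arm: absorption parameters are unconstrained.
  arms0 <- data.frame(arm_id = "a", dose_g = 0,
                      time_min = c(0, 15, 30, 60),
                      conc_mM = rep(p$C0, 4))
  expect_error(fit_pk_model(arms0), "identifiability")
  # Non-positive concentrations.
  arms_bad <- data.frame(arm_id = "a", dose_g = 2,
                         time_min = c(0, 15, 30, 60),
                         conc_mM = c(0.06, -0.1, 0.2, 0.1))
  expect_error(fit_pk_model(arms_bad), "finite and > 0")
  # Times must increase from 0.
  arms_t <- data.frame(arm_id = "a", dose_g = 2,
                       time_min = c(5, 15, 30, 60),
                       conc_mM = c(0.06, 0.1, 0.2, 0.1))
  expect_error(fit_pk_model(arms_t), "time 0")
})

test_that("least-squares AIC follows n ln(SSR/n) + 2p", {
  # ln(e) = 1: AIC = n + 2p.
  expect_equal(model_aic(exp(1) * 10, 10, 6), 10 + 12)
  # Halving the SSR strictly decreases AIC.
  expect_lt(model_aic(0.0005, 14, 6), model_aic(0.001, 14, 6))
  # Worked comparison: full (p = 6) vs reduced (p = 5) on 14 observations.
  d_aic <- model_aic(0.001, 14, 6) - model_aic(0.0012, 14, 5)
  expect_equal(d_aic, 14 * log(0.001 / 0.0012) + 2)
  expect_equal(d_aic, -0.5525, tolerance = 1e-3)
  expect_warning(a0 <- model_aic(0, 14, 6), "-Inf")
  expect_identical(a0, -Inf)
  expect_error(model_aic(0.1, 5, 6))
})

test_that("variant comparison prefers the generating model and respects SSR nesting", {
  # Truth with both pathways strongly active.
  truth <- pk_params(CL = 1.8, C0 = 0.06, ka = 0.03, Km_prime = 15, Vd = 90,
                     Vmax = 0.6)
  g <- generate_serum_profiles(truth, noise_cv = 0, seed = 5)
  cmp <- compare_pk_variants(g$arms, fit_options(n_starts = 6, seed = 6))
  ssr <- stats::setNames(cmp$table$ssr, cmp$table$variant)
  expect_equal(which.min(ssr), c(full = which(names(ssr) == "full")))
  expect_lte(ssr[["full"]], ssr[["nonsaturable_only"]])
  expect_lte(ssr[["full"]], ssr[["saturable_only"]])
  expect_true(cmp$selected %in% cmp$table$variant)
})

test_that("fits are deterministic given identical options", {
  truth <- test_truth()
  g <- generate_serum_profiles(truth, noise_cv = 0.3, seed = 7)
  f1 <- fit_pk_model(g$arms, fit_options(n_starts = 4, seed = 8))
  f2 <- fit_pk_model(g$arms, fit_options(n_starts = 4, seed = 8))
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$ssr, f2$ssr)
  expect_identical(f1$param_sd, f2$param_sd)
})

test_that("uniform and inverse-observation weighting agree on noise-free data", {
  truth <- test_truth()
  g <- generate_serum_profiles(truth, noise_cv = 0, seed = 9)
  fu <- fit_pk_model(g$arms, fit_options(n_starts = 10, seed = 10))
  fw <- fit_pk_model(g$arms, fit_options(n_starts = 10, seed = 10,
                                         weighting = "inverse_observation"))
  rel <- abs(unlist(fu$params[kin_names]) / unlist(fw$params[kin_names]) - 1)
  expect_lt(max(rel), 0.05)
})

test_that("parameter SDs are returned on the original scale and flag uncertainty", {
  truth <- test_truth()
  g <- generate_serum_profiles(truth, noise_cv = 0.3, seed = 12)
  fit <- fit_pk_model(g$arms, fit_options(n_starts = 6, seed = 13))
  sd_free <- fit$param_sd[kin_names]
  expect_true(all(is.finite(sd_free)))
  expect_true(all(sd_free >= 0))
  # Variant-fixed parameters carry no SD.
  fit_s <- fit_pk_model(g$arms, fit_options(variant = "saturable_only",
                                            n_starts = 6, seed = 13))
  expect_true(is.na(fit_s$param_sd[["ka"]]))
})

test_that("calibration from peak summaries recovers known absorption parameters", {
  truth <- test_truth()
  cons <- do.call(rbind, lapply(c(2, 4), function(d) {
    ct <- summarize_cmax(pk_simulate(truth, d, t_end = 240, grid_step = 0.5))
    data.frame(dose_g = d, cmax_mM = ct$cmax, tmax_min = ct$tmax)
  }))
  cal <- calibrate_absorption(list(CL = truth$CL, C0 = truth$C0,
                                   Vd = truth$Vd), cons, seed = 14)
  rel <- abs(unlist(cal[c("Vmax", "Km_prime", "ka")]) /
             unlist(truth[c("Vmax", "Km_prime", "ka")]) - 1)
  expect_lt(max(rel), 0.01)
  expect_true(attr(cal, "calibration")$feasible)
})

test_that("calibration refuses under-determined inputs", {
  expect_error(
    calibrate_absorption(printed_disposition(), printed_peak_summaries()[1, ]),
    "under-determined")
})

test_that("printed-summary calibration flags infeasibility but matches peak times", {
  expect_warning(
    cal <- calibrate_absorption(printed_disposition(), printed_peak_summaries(), seed = 15),
    "infeasible")
  res <- attr(cal, "calibration")$residuals
  # The peak times are reproduced closely; the peak heights cannot be under
  # this model with the disposition parameters fixed (monotone-decreasing
  # absorption bounds Cmax at 30 min below the printed 2 g value).
  expect_lt(max(abs(res[c("tmax_2g", "tmax_4g")])), 0.02)
  expect_false(attr(cal, "calibration")$feasible)
})
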