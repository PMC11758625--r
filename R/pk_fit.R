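#' Default fitting options
#'
#' Controls the simultaneous nonlinear least-squares fit: model variant,
#' number of Latin-hypercube multi-starts, box bounds (positivity is enforced
#' by optimising log-parameters), residual weighting, and the seed that makes
#' the start set reproducible.
#'
#' @param variant Model variant, see [pk_variant()].
#' @param n_starts Number of multi-start points (>= 1).
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults span
#'   CL 0.1-10 L/min, C0 0.01-0.2 mM, ka 1e-4-1 /min, Km' 0.1-500 mmol,
#'   Vd 5-500 L, Vmax 0.01-10 mmol/min.
#' @param weighting `"uniform"` (unweighted residuals, the default: mean
#'   profiles carry no stated weights) or `"inverse_observation"`
#'   (residuals divided by the observed concentration).
#' @param seed Integer seed for the multi-start draw.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(variant = "full", n_starts = 20, bounds = NULL,
                        weighting = c("uniform", "inverse_observation"),
                        seed = 20240101, max_iter = 200) {
  variant <- pk_variant(variant)
  weighting <- match.arg(weighting)
  default_bounds <- list(CL = c(0.1, 10), C0 = c(0.01, 0.2),
                         ka = c(1e-4, 1), Km_prime = c(0.1, 500),
                         Vd = c(5, 500), Vmax = c(0.01, 10))
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  stopifnot(n_starts >= 1)
  for (b in default_bounds) stopifnot(length(b) == 2, b[1] > 0, b[2] > b[1])
  structure(list(variant = variant, n_starts = as.integer(n_starts),
                 bounds = default_bounds, weighting = weighting,
                 seed = as.integer(seed), max_iter = as.integer(max_iter)),
            class = "fit_options")
}

# Validate a long-format arms table (arm_id, dose_g, time_min, conc_mM).
validate_arms <- function(arms) {
  req <- c("arm_id", "dose_g", "time_min", "conc_mM")
  if (!is.data.frame(arms) || !all(req %in% names(arms))) {
    stop("arms must be a data frame with columns ", paste(req, collapse = ", "))
  }
  split_arms <- split(arms, arms$arm_id)
  for (a in split_arms) {
    if (is.unsorted(a$time_min, strictly = TRUE)) {
      stop("times within an arm must be strictly increasing")
    }
    if (a$time_min[1] != 0) stop("each arm must start at time 0")
    if (any(!is.finite(a$conc_mM)) || any(a$conc_mM <= 0)) {
      stop("concentrations must be finite and > 0")
    }
    if (length(unique(a$dose_g)) != 1) stop("dose must be constant within an arm")
  }
  if (!any(vapply(split_arms, function(a) a$dose_g[1] > 0, logical(1)))) {
    stop("identifiability error: at least one arm must have dose > 0 ",
         "(absorption parameters are unconstrained otherwise)")
  }
  if (!any(vapply(split_arms, nrow, integer(1)) >= 4)) {
    stop("at least one arm needs >= 4 time points")
  }
  split_arms
}

# Latin-hypercube start matrix in log-parameter space (uses the current RNG
# stream; callers manage the seed).
lhs_starts <- function(n_starts, free, bounds) {
  lo <- log(vapply(bounds[free], `[`, numeric(1), 1))
  hi <- log(vapply(bounds[free], `[`, numeric(1), 2))
  H <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(H, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- free
  list(starts = starts, lower = lo, upper = hi)
}

# Multi-start Levenberg-Marquardt on log-parameters: LHS exploration plus
# deterministic jittered polishing rounds around the incumbent best.
multistart_lm <- function(resid_fn, n_starts, free, bounds, seed,
                          max_iter = 200, extra_starts = NULL,
                          polish = c(0.5, 0.25)) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # Screening phase: rank a larger Latin-hypercube candidate set by raw SSR
  # and run the local optimiser only from the most promising points.
  st <- lhs_starts(10 * n_starts, free, bounds)
  raw <- apply(st$starts, 1, function(lp) {
    r <- tryCatch(resid_fn(lp), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
  })
  starts <- st$starts[order(raw)[seq_len(n_starts)], , drop = FALSE]
  if (!is.null(extra_starts)) {
    ex <- do.call(rbind, lapply(extra_starts, function(s) {
      pmin(pmax(s[free], st$lower), st$upper)
    }))
    starts <- rbind(starts, ex)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter,
                                     ftol = 1e-13, ptol = 1e-13, gtol = 0)
  run1 <- function(lp) {
    tryCatch(minpack.lm::nls.lm(lp, fn = resid_fn,
                                lower = st$lower, upper = st$upper,
                                control = ctrl),
             error = function(e) NULL)
  }
  best <- NULL
  any_clean <- FALSE
  consider <- function(fit) {
    if (is.null(fit)) return(invisible())
    ss <- sum(fit$fvec^2)
    any_clean <<- any_clean || fit$info %in% 1:3
    if (is.null(best) || ss < best$ss) best <<- list(ss = ss, fit = fit)
    invisible()
  }
  for (k in seq_len(nrow(starts))) consider(run1(starts[k, ]))
  if (!is.null(best)) {
    n_jit <- max(4L, ceiling(n_starts / 4))
    for (sd_j in polish) {
      centre <- best$fit$par
      for (j in seq_len(n_jit)) {
        lp <- pmin(pmax(centre + stats::rnorm(length(centre), 0, sd_j),
                        st$lower), st$upper)
        consider(run1(lp))
      }
    }
  }
  if (is.null(best)) stop("non-convergence: all multi-starts failed")
  list(par = best$fit$par, ssr = best$ss, converged = any_clean,
       lower = st$lower, upper = st$upper)
}

#' Fit the compartment model to one or more dose arms
#'
#' Estimates the model parameters (all six for the full variant; the reduced
#' variants drop the removed pathway's parameters) by simultaneous nonlinear
#' least squares over every arm's concentration-time observations, sharing a
#' single parameter set (including the baseline `C0`) across arms.
#' Optimisation is Levenberg-Marquardt on log-parameters with multi-start
#' over a seeded Latin-hypercube; the best converged start is returned.
#' Standard deviations of the estimates come from the linearised covariance
#' `sigma^2 (J'J)^{-1}` on the log scale (`sigma^2 = SSR/(n - p)`),
#' back-transformed by the delta method.
#'
#' @param arms Data frame with columns `arm_id`, `dose_g`, `time_min`,
#'   `conc_mM` (one row per observation; the 2 g and 4 g mean profiles in
#'   the motivating design).
#' @param options A [fit_options()] list.
#' @param extra_starts Optional list of additional named log-parameter start
#'   vectors (clamped into the bounds), e.g. embedded solutions of a nested
#'   variant. Used by [compare_pk_variants()].
#' @return A list of class `pk_fit`: `params` ([pk_params]), `param_sd`
#'   (named, `NA` for parameters fixed by the variant), `ssr`, `aic`,
#'   `n_obs`, `n_params`, `converged`, `sd_reliable`, `variant`, and
#'   `fitted` (per-arm fitted curves on a 1-min grid).
#' @export
fit_pk_model <- function(arms, options = fit_options(), extra_starts = NULL) {
  split_arms <- validate_arms(arms)
  variant <- options$variant
  free <- variant_free_params(variant)
  n_obs <- sum(vapply(split_arms, nrow, integer(1)))
  n_params <- length(free)
  if (n_obs <= n_params) stop("need more observations than free parameters")

  base <- list(CL = 1, C0 = 0.05, ka = 0, Km_prime = 1, Vd = 50, Vmax = 0,
               molar_mass = HB_MOLAR_MASS)
  obs <- unlist(lapply(split_arms, `[[`, "conc_mM"), use.names = FALSE)
  w <- if (options$weighting == "inverse_observation") 1 / obs else rep(1, n_obs)

  resid_fn <- function(lp) {
    p <- base
    p[free] <- exp(lp)
    pred <- unlist(lapply(split_arms, function(a) {
      conc_at_times(p, a$dose_g[1], a$time_min, variant = variant)
    }), use.names = FALSE)
    (obs - pred) * w
  }

  best <- multistart_lm(resid_fn, options$n_starts, free, options$bounds,
                        seed = options$seed, max_iter = options$max_iter,
                        extra_starts = extra_starts)
  lp_hat <- best$par
  p_hat <- base
  p_hat[free] <- exp(lp_hat)
  params <- do.call(pk_params, p_hat)

  # SDs via linearised covariance on the log scale, delta-method transform.
  sd_reliable <- TRUE
  param_sd <- stats::setNames(rep(NA_real_, 6),
                              c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax"))
  J <- tryCatch(pracma::jacobian(resid_fn, lp_hat), error = function(e) NULL)
  if (!is.null(J) && best$ssr > 0 && n_obs > n_params) {
    sigma2 <- best$ssr / (n_obs - n_params)
    cov_log <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (is.null(cov_log) || any(diag(cov_log) < 0)) {
      sd_reliable <- FALSE
      warning("rank-deficient Jacobian: parameter SDs are unreliable")
    } else {
      param_sd[free] <- unlist(p_hat[free]) * sqrt(diag(cov_log))
    }
  } else {
    sd_reliable <- FALSE
  }

  fitted <- do.call(rbind, lapply(names(split_arms), function(id) {
    a <- split_arms[[id]]
    prof <- pk_simulate(params, a$dose_g[1], t_end = max(a$time_min),
                        variant = variant, grid_step = 1)
    data.frame(arm_id = id, dose_g = a$dose_g[1],
               time_min = prof$time_min, conc_mM = prof$conc_mM)
  }))

  structure(list(params = params, param_sd = param_sd, ssr = best$ssr,
                 aic = model_aic(best$ssr, n_obs, n_params),
                 n_obs = n_obs, n_params = n_params,
                 converged = best$converged, sd_reliable = sd_reliable,
                 variant = variant, fitted = fitted, options = options),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Compartment-model fit (%s): SSR = %.4g mM^2, AIC = %.3f, n = %d, p = %d\n",
              x$variant, x$ssr, x$aic, x$n_obs, x$n_params))
  est <- unlist(x$params[c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax")])
  tab <- data.frame(estimate = est, sd = x$param_sd[names(est)])
  print(round(tab, 5))
  if (!x$sd_reliable) cat("note: SDs flagged unreliable\n")
  invisible(x)
}

#' Least-squares Akaike information criterion
#'
#' `AIC = n * ln(SSR / n) + 2 p`, the form appropriate when only residual
#' sums of squares are available. Only differences between AIC values
#' computed by this same formula are meaningful.
#'
#' @param ssr Residual sum of squares, mM^2.
#' @param n_obs Number of observations.
#' @param n_params Number of free parameters.
#' @return AIC value; `-Inf` with a warning when `ssr` is 0.
#' @examples
#' model_aic(0.001, 14, 6) - model_aic(0.0012, 14, 5)
#' @export
model_aic <- function(ssr, n_obs, n_params) {
  stopifnot(ssr >= 0, n_obs > n_params, n_params >= 0)
  if (ssr == 0) {
    warning("SSR is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  n_obs * log(ssr / n_obs) + 2 * n_params
}

#' Fit and compare the absorption-pathway variants
#'
#' Fits the full model and both single-pathway reductions with shared
#' settings and tabulates SSR, AIC and parameter counts. Selection prefers
#' the lowest AIC; variants within `aic_tie` of the minimum are treated as
#' comparable and the near-tie is broken by the lower final SSR (the rule
#' used when a reduced model's AIC is comparable but its SSR is higher).
#'
#' @param arms As in [fit_pk_model()].
#' @param options A [fit_options()] list; its `variant` field is ignored.
#' @param aic_tie Near-tie width on the AIC scale (default 2).
#' @return A list of class `pk_variant_comparison` with `table` (one row per
#'   variant, AIC-ordered), `fits` (named list of `pk_fit` or `NULL` where a
#'   variant failed), and `selected` (variant tag).
#' @export
compare_pk_variants <- function(arms, options = fit_options(), aic_tie = 2) {
  variants <- c("full", "nonsaturable_only", "saturable_only")
  fit_variant <- function(v, extra_starts = NULL) {
    opt <- options
    opt$variant <- v
    tryCatch(fit_pk_model(arms, opt, extra_starts = extra_starts),
             error = function(e) {
               warning("variant ", v, " failed: ", conditionMessage(e))
               NULL
             })
  }
  fits <- list(nonsaturable_only = fit_variant("nonsaturable_only"),
               saturable_only = fit_variant("saturable_only"))
  # Seed the full fit with the reduced solutions embedded near the zero of
  # the removed pathway, so the nested model's optimum is always reachable.
  # The full fit's lower bounds on the pathway parameters are relaxed so the
  # embedded points reproduce the reduced SSR essentially exactly.
  full_opt <- options
  full_opt$bounds$ka[1] <- min(full_opt$bounds$ka[1], 1e-8)
  full_opt$bounds$Vmax[1] <- min(full_opt$bounds$Vmax[1], 1e-6)
  embed <- lapply(fits[!vapply(fits, is.null, logical(1))], function(f) {
    p <- unlist(f$params[c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax")])
    p["ka"] <- max(p["ka"], full_opt$bounds$ka[1])
    p["Vmax"] <- max(p["Vmax"], full_opt$bounds$Vmax[1])
    if (f$variant == "nonsaturable_only") p["Km_prime"] <- full_opt$bounds$Km_prime[2]
    log(p)
  })
  full_opt$variant <- "full"
  fits$full <- tryCatch(
    fit_pk_model(arms, full_opt, extra_starts = unname(embed)),
    error = function(e) {
      warning("variant full failed: ", conditionMessage(e))
      NULL
    })
  # A reduced model is exactly a boundary point of the full model (ka = 0 or
  # Vmax = 0), so the full model can never fit worse. If the optimiser left
  # an epsilon on the table, adopt the reduced solution as the full-model
  # boundary solution.
  if (!is.null(fits$full)) {
    for (f_red in fits[c("nonsaturable_only", "saturable_only")]) {
      if (!is.null(f_red) && f_red$ssr < fits$full$ssr) {
        snap <- fits$full
        snap$params <- f_red$params
        snap$param_sd <- f_red$param_sd
        snap$ssr <- f_red$ssr
        snap$aic <- model_aic(f_red$ssr, f_red$n_obs, snap$n_params)
        snap$sd_reliable <- f_red$sd_reliable
        snap$fitted <- f_red$fitted
        fits$full <- snap
      }
    }
  }
  fits <- fits[variants]
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all variants failed to fit")
  tab <- do.call(rbind, lapply(variants[ok], function(v) {
    f <- fits[[v]]
    data.frame(variant = v, ssr = f$ssr, aic = f$aic,
               n_params = f$n_params, converged = f$converged)
  }))
  tab <- tab[order(tab$aic), ]
  near <- tab[tab$aic <= min(tab$aic) + aic_tie, ]
  selected <- near$variant[which.min(near$ssr)]
  structure(list(table = tab, fits = fits, selected = selected),
            class = "pk_variant_comparison")
}

#' @export
print.pk_variant_comparison <- function(x, ...) {
  cat("Absorption-pathway variant comparison (AIC-ordered):\n")
  print(x$table, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Calibrate absorption parameters from printed Cmax/Tmax summaries
#'
#' Recovers the absorption parameters (`Vmax`, `Km_prime`, `ka`) when only
#' dose-level peak summaries are available, holding `CL`, `C0`, `Vd` fixed.
#' Minimises the relative peak residuals
#' `sum[((Cmax_sim - Cmax_obs)/Cmax_obs)^2 + w ((Tmax_sim - Tmax_obs)/Tmax_obs)^2]`
#' over log-parameters by seeded multi-start Levenberg-Marquardt. With fewer
#' than two (dose, Cmax, Tmax) constraints the three absorption parameters
#' are under-determined and the function refuses.
#'
#' @param fixed Named list with `CL` (L/min), `C0` (mM), `Vd` (L).
#' @param constraints Data frame with columns `dose_g`, `cmax_mM`,
#'   `tmax_min`; at least two rows.
#' @param weight_tmax Relative weight `w` of the Tmax residuals (default 1).
#' @param n_starts Multi-start count.
#' @param seed Seed for the start draw.
#' @param infeasible_tol Residual-norm threshold above which a
#'   calibration-infeasible warning is emitted (the best-found parameters
#'   are still returned).
#' @return A [pk_params] object with attribute `calibration`: a list with
#'   `ssr`, `residuals` (named, relative), and `feasible`.
#' @export
calibrate_absorption <- function(fixed, constraints, weight_tmax = 1,
                                 n_starts = 10, seed = 20240101,
                                 infeasible_tol = 0.05) {
  stopifnot(all(c("CL", "C0", "Vd") %in% names(fixed)))
  req <- c("dose_g", "cmax_mM", "tmax_min")
  if (!is.data.frame(constraints) || !all(req %in% names(constraints))) {
    stop("constraints must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(constraints) < 2) {
    stop("under-determined calibration: need >= 2 (dose, Cmax, Tmax) ",
         "constraints for 3 absorption parameters")
  }
  free <- c("Vmax", "Km_prime", "ka")
  bounds <- list(Vmax = c(0.01, 10), Km_prime = c(0.1, 500), ka = c(1e-4, 1))
  t_end <- max(180, 4 * max(constraints$tmax_min))

  resid_fn <- function(lp) {
    p <- list(CL = fixed$CL, C0 = fixed$C0, ka = exp(lp[3]),
              Km_prime = exp(lp[2]), Vd = fixed$Vd, Vmax = exp(lp[1]),
              molar_mass = HB_MOLAR_MASS)
    unlist(lapply(seq_len(nrow(constraints)), function(i) {
      ct <- cmax_for_dose(p, constraints$dose_g[i], t_end = t_end,
                          grid_step = 1)
      c((ct$cmax - constraints$cmax_mM[i]) / constraints$cmax_mM[i],
        sqrt(weight_tmax) * (ct$tmax - constraints$tmax_min[i]) /
          constraints$tmax_min[i])
    }))
  }

  best <- multistart_lm(resid_fn, n_starts, free, bounds, seed = seed,
                        max_iter = 300)
  est <- exp(best$par)
  params <- pk_params(CL = fixed$CL, C0 = fixed$C0, ka = est[3],
                      Km_prime = est[2], Vd = fixed$Vd, Vmax = est[1])
  res <- resid_fn(best$par)
  names(res) <- as.vector(t(outer(constraints$dose_g, c("cmax", "tmax"),
                                  function(d, s) paste0(s, "_", d, "g"))))
  feasible <- sqrt(best$ssr) <= infeasible_tol
  if (!feasible) {
    warning(sprintf(paste0("calibration infeasible within tolerance ",
                           "(residual norm %.3f > %.3f); returning ",
                           "best-found parameters"),
                    sqrt(best$ssr), infeasible_tol))
  }
  attr(params, "calibration") <- list(ssr = best$ssr, residuals = res,
                                      feasible = feasible)
  params
}
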