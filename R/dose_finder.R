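#' Smallest grid dose whose simulated Cmax reaches a target concentration
#'
#' Scans an increasing dose ladder, simulating each candidate and computing
#' its refined peak concentration, and returns the first dose whose Cmax
#' meets the target (ties count as reaching it). Because Cmax is strictly
#' increasing in dose for this model, the first qualifying dose is the
#' minimum.
#'
#' @param params A [pk_params] object (typically calibrated).
#' @param target_cmax Target peak serum concentration, mM.
#' @param doses Ordered candidate doses, g (default 0.5-8 g in 0.5 g steps,
#'   the granularity at which the motivating analysis reported its answer).
#' @param t_end,grid_step Simulation window and grid for the Cmax
#'   evaluation (default 240 min at 0.1 min; absorption is complete well
#'   before, observed peaks occur by 45 min).
#' @param variant Model variant.
#' @return The minimum qualifying dose in g; `0` (with a message) when the
#'   baseline `C0` already meets the target; `NA` when no grid dose
#'   qualifies. The attribute `cmax` carries the Cmax at the returned dose.
#' @examples
#' p <- pk_params(1.82, 0.063, 0.02, 30, 85.7, 0.5)
#' find_min_dose_grid(p, target_cmax = 0.28, grid_step = 1)
#' @export
find_min_dose_grid <- function(params, target_cmax,
                               doses = seq(0.5, 8, by = 0.5),
                               t_end = 240, grid_step = 0.1,
                               variant = "full") {
  validate_pk_params(params)
  stopifnot(target_cmax > 0, all(doses >= 0), !is.unsorted(doses, strictly = TRUE))
  if (params$C0 >= target_cmax) {
    message("baseline C0 already meets the target; minimum dose is 0 g")
    return(structure(0, cmax = params$C0))
  }
  for (d in doses) {
    ct <- cmax_for_dose(params, d, t_end = t_end, grid_step = grid_step,
                        variant = variant)
    if (ct$cmax >= target_cmax) {
      return(structure(d, cmax = ct$cmax, tmax = ct$tmax))
    }
  }
  message("no dose on the grid reaches the target Cmax")
  NA_real_
}

#' Continuous minimum-dose refinement by bisection
#'
#' Refines the grid answer to a continuous dose by bisection on the
#' monotone dose-to-Cmax map: the returned dose `d` satisfies
#' `Cmax(d) >= target` and `Cmax(d - tol) < target`.
#'
#' @inheritParams find_min_dose_grid
#' @param lower,upper Bracketing doses, g; `Cmax(lower)` must be below the
#'   target and `Cmax(upper)` at or above it.
#' @param tol Bisection tolerance on the dose, g.
#' @return The refined minimum dose, g, with attribute `cmax`.
#' @export
find_min_dose_bisect <- function(params, target_cmax, lower = 0, upper = 8,
                                 tol = 0.01, t_end = 240, grid_step = 0.1,
                                 variant = "full") {
  validate_pk_params(params)
  stopifnot(target_cmax > 0, upper > lower, tol > 0)
  cm <- function(d) {
    if (d == 0) params$C0
    else cmax_for_dose(params, d, t_end = t_end, grid_step = grid_step,
                       variant = variant)$cmax
  }
  c_lo <- cm(lower)
  c_hi <- cm(upper)
  if (c_lo >= target_cmax) {
    stop("bracketing error: Cmax at the lower dose already meets the target")
  }
  if (c_hi < target_cmax) {
    stop("bracketing error: Cmax at the upper dose is below the target")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (cm(mid) >= target_cmax) upper <- mid else lower <- mid
  }
  structure(upper, cmax = cm(upper))
}
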