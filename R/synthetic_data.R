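#' Generate synthetic serum 3-HB concentration-time data
#'
#' Emulates a single-dose sampling study: each subject's measurement at each
#' time is the model prediction times `(1 + e)` with `e ~ Normal(0,
#' noise_cv)` (proportional error, matching how the printed SDs scale with
#' the mean), floored at `noise_floor` so concentrations stay positive.
#' Between-subject kinetic variability is deliberately not modelled - the
#' noise is observation-level only, mirroring an analysis of mean profiles.
#' Arm means (the fitting input) and per-subject values are both returned.
#'
#' @param truth A [pk_params] object: the generating parameter set.
#' @param doses Doses to simulate, g (default `c(2, 4)`).
#' @param times Sampling schedule, min (default 0, 5, 15, 30, 45, 60, 120).
#' @param n_subjects Subjects per dose arm (default 10).
#' @param noise_cv Proportional noise coefficient (default 0.30, the
#'   observed SD/mean ratio at peak).
#' @param noise_floor Lower truncation for simulated concentrations, mM.
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param variant Model variant used for the predictions.
#' @return List with `arms` (columns `arm_id`, `dose_g`, `time_min`,
#'   `conc_mM` (arm mean), `sd_mM`, `n`) and `subjects` (long per-subject
#'   table).
#' @export
generate_serum_profiles <- function(truth, doses = c(2, 4),
                                    times = c(0, 5, 15, 30, 45, 60, 120),
                                    n_subjects = 10, noise_cv = 0.30,
                                    noise_floor = 0.001, seed = 20240101,
                                    variant = "full") {
  validate_pk_params(truth)
  stopifnot(noise_cv >= 0, n_subjects >= 1, all(doses >= 0),
            !is.unsorted(times, strictly = TRUE))
  if (times[1] != 0) {
    warning("sampling schedule does not start at 0: the C0 anchor is lost")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  subjects <- list()
  arms <- list()
  for (d in doses) {
    pred <- conc_at_times(truth, d, times, variant = variant)
    eps <- matrix(stats::rnorm(n_subjects * length(times), 0, noise_cv),
                  nrow = n_subjects)
    vals <- sweep(1 + eps, 2, pred, `*`)
    vals <- pmax(vals, noise_floor)
    id <- sprintf("dose_%gg", d)
    subjects[[id]] <- data.frame(
      arm_id = id, dose_g = d,
      subject = rep(seq_len(n_subjects), each = length(times)),
      time_min = rep(times, times = n_subjects),
      conc_mM = as.vector(t(vals)))
    arms[[id]] <- data.frame(
      arm_id = id, dose_g = d, time_min = times,
      conc_mM = colMeans(vals),
      sd_mM = apply(vals, 2, stats::sd),
      n = n_subjects)
  }
  list(arms = do.call(rbind, c(arms, make.row.names = FALSE)),
       subjects = do.call(rbind, c(subjects, make.row.names = FALSE)))
}

#' Generate a synthetic 2x2 crossover trial
#'
#' Emulates a two-sequence, two-period crossover with change scores
#' following a linear mixed model: `change = mean_change + sequence_effect *
#' 1[seq II] + period_effect * 1[period 2] + true_effect * 1[active] +
#' b_subject + e`, with `b ~ Normal(0, subject_sd)` and `e ~ Normal(0,
#' residual_sd)`. Treatment is determined by the (sequence, period) cell:
#' sequence I is active-then-placebo, sequence II placebo-then-active.
#' Pre-intervention scores are drawn from `Normal(baseline_mean,
#' baseline_sd)` and post = pre + change, so the change-score pipeline can
#' be exercised end to end.
#'
#' @param n_subjects Total subjects, split evenly across sequences
#'   (default 40, i.e. 20 per sequence). Must be even and >= 4.
#' @param true_effect Active-minus-placebo effect on the change score
#'   (default -4.7, the total-mood-disturbance scale of the motivating
#'   trial).
#' @param period_effect,sequence_effect Additive period-2 and sequence-II
#'   shifts (default 0).
#' @param mean_change Intercept: mean change under placebo, period 1,
#'   sequence I (default 5.3).
#' @param subject_sd Random-intercept SD (default 10).
#' @param residual_sd Residual SD (default 8.5). The defaults give
#'   change-score SDs near sqrt(10^2 + 8.5^2) ~ 13, the scale of the
#'   motivating trial's mood endpoint.
#' @param endpoint Endpoint label stored on the records.
#' @param baseline_mean,baseline_sd Distribution of pre-intervention scores.
#' @param sequences Optional explicit sequence assignment (character vector
#'   of "I"/"II" of length `n_subjects`); both sequences must occur or the
#'   generator refuses (the design would be inestimable).
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `sequence`, `period`,
#'   `treatment`, `endpoint`, `outcome_pre`, `outcome_post`, `change` (two
#'   rows per subject).
#' @export
generate_crossover_trial <- function(n_subjects = 40, true_effect = -4.7,
                                     period_effect = 0, sequence_effect = 0,
                                     mean_change = 5.3, subject_sd = 10,
                                     residual_sd = 8.5,
                                     endpoint = "poms2_tmd",
                                     baseline_mean = 10, baseline_sd = 12,
                                     sequences = NULL, seed = 20240101) {
  stopifnot(n_subjects >= 4, subject_sd >= 0, residual_sd >= 0)
  if (is.null(sequences)) {
    if (n_subjects %% 2 != 0) stop("n_subjects must be even for a balanced split")
    sequences <- rep(c("I", "II"), each = n_subjects / 2)
  }
  stopifnot(length(sequences) == n_subjects, all(sequences %in% c("I", "II")))
  if (length(unique(sequences)) < 2) {
    stop("inestimable design: all subjects in one sequence")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  b <- stats::rnorm(n_subjects, 0, subject_sd)
  rec <- expand.grid(subject_id = seq_len(n_subjects), period = 1:2,
                     KEEP.OUT.ATTRS = FALSE)
  rec <- rec[order(rec$subject_id, rec$period), ]
  rec$sequence <- sequences[rec$subject_id]
  rec$treatment <- implied_treatment(rec$sequence, rec$period)
  rec$endpoint <- endpoint
  eps <- stats::rnorm(nrow(rec), 0, residual_sd)
  rec$change <- mean_change +
    sequence_effect * (rec$sequence == "II") +
    period_effect * (rec$period == 2) +
    true_effect * (rec$treatment == "active") +
    b[rec$subject_id] + eps
  rec$outcome_pre <- stats::rnorm(nrow(rec), baseline_mean, baseline_sd)
  rec$outcome_post <- rec$outcome_pre + rec$change
  rownames(rec) <- NULL
  rec[, c("subject_id", "sequence", "period", "treatment", "endpoint",
          "outcome_pre", "outcome_post", "change")]
}
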