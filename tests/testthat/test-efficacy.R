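test_that("TMD is the five negative subscales minus vigor-activity", {
  zero <- data.frame(anger_hostility = 0, confusion_bewilderment = 0,
                     depression_dejection = 0, fatigue_inertia = 0,
                     tension_anxiety = 0, vigor_activity = 0)
  expect_equal(tmd_score(zero), 0)

  s <- data.frame(anger_hostility = 2, confusion_bewilderment = 2,
                  depression_dejection = 2, fatigue_inertia = 2,
                  tension_anxiety = 2, vigor_activity = 3)
  expect_equal(tmd_score(s), 7)

  # Linearity in vigor: raising vigor by delta lowers TMD by exactly delta.
  s2 <- s
  s2$vigor_activity <- s2$vigor_activity + 1.5
  expect_equal(tmd_score(s2), tmd_score(s) - 1.5)

  expect_error(tmd_score(s[, -1]), "missing subscale")
  s_na <- s
  s_na$fatigue_inertia <- NA
  expect_error(tmd_score(s_na), "missing data")
})

test_that("change scores are post minus pre with listwise exclusion", {
  rec <- data.frame(outcome_pre = c(40.1, 5, NA, 7),
                    outcome_post = c(73.8, 5, 2, NA))
  expect_message(out <- compute_change_scores(rec), "2 record")
  expect_equal(out$change, c(33.7, 0))
  expect_equal(attr(out, "n_excluded"), 2)
})

test_that("the mixed-model crossover estimate equals the closed-form contrast on balanced data", {
  for (s in 1:8) {
    tr <- generate_crossover_trial(n_subjects = 16, true_effect = -3,
                                   period_effect = 2, sequence_effect = 1.5,
                                   subject_sd = 8, residual_sd = 6,
                                   seed = 5000 + s)
    fit <- fit_crossover(tr)
    expect_equal(fit$effect, crossover_contrast(tr), tolerance = 1e-10)
  }
})

test_that("a fixed within-subject difference is estimated exactly", {
  set.seed(88)
  n <- 10
  placebo_change <- stats::rnorm(n, 5, 4)
  rows <- lapply(seq_len(n), function(i) {
    sq <- if (i <= n / 2) "I" else "II"
    data.frame(subject_id = i, sequence = sq, period = 1:2,
               treatment = if (sq == "I") c("active", "placebo")
                           else c("placebo", "active"),
               change = if (sq == "I") c(placebo_change[i] + 28.8, placebo_change[i])
                        else c(placebo_change[i], placebo_change[i] + 28.8))
  })
  tr <- do.call(rbind, rows)
  fit <- fit_crossover(tr)
  expect_equal(fit$effect, 28.8, tolerance = 1e-9)
})

test_that("constant outcomes give a zero effect with p = 1", {
  tr <- generate_crossover_trial(n_subjects = 8, true_effect = 0,
                                 period_effect = 0, sequence_effect = 0,
                                 subject_sd = 0, residual_sd = 0, seed = 1)
  fit <- fit_crossover(tr)
  expect_equal(fit$effect, 0)
  expect_equal(fit$p_value, 1)
})

test_that("relabelling periods flips the period effect but not the treatment estimate", {
  tr <- generate_crossover_trial(n_subjects = 20, true_effect = -4,
                                 period_effect = 3, subject_sd = 8,
                                 residual_sd = 6, seed = 321)
  fit <- fit_crossover(tr)
  # Swap period labels; the implied design flips each subject's sequence.
  tr2 <- tr
  tr2$period <- 3 - tr2$period
  tr2$sequence <- ifelse(tr2$sequence == "I", "II", "I")
  fit2 <- fit_crossover(tr2)
  expect_equal(fit2$effect, fit$effect, tolerance = 1e-10)
  expect_equal(unname(fit2$fixed_effects["period2"]),
               -unname(fit$fixed_effects["period2"]), tolerance = 1e-10)
})

test_that("invalid crossover designs are rejected", {
  tr <- generate_crossover_trial(n_subjects = 8, seed = 2)
  one_seq <- tr
  one_seq$sequence <- "I"
  one_seq$treatment <- ketodose:::implied_treatment(one_seq$sequence, one_seq$period)
  expect_error(fit_crossover(one_seq), "one sequence")

  bad_tr <- tr
  bad_tr$treatment[1] <- "placebo"
  expect_error(fit_crossover(bad_tr), "inconsistent")

  dup <- rbind(tr, tr[1, ])
  expect_error(fit_crossover(dup), "one record per period")

  expect_error(generate_crossover_trial(n_subjects = 8,
                                        sequences = rep("I", 8)),
               "inestimable")
})

test_that("incomplete subjects are excluded listwise", {
  tr <- generate_crossover_trial(n_subjects = 10, seed = 3)
  tr_miss <- tr[-1, ]  # subject 1 loses period 1
  expect_message(fit <- fit_crossover(tr_miss), "incomplete")
  expect_equal(fit$n_used, 9)
  expect_equal(fit$df, 7)
})

test_that("pooled t-test handles identical and degenerate groups by contract", {
  x <- c(1, 2, 3, 4)
  expect_equal(baseline_t_test(x, x)$p, 1)
  expect_equal(baseline_t_test(x, x)$t, 0)
  expect_equal(baseline_t_test(rep(2, 3), rep(2, 4))$p, 1)
  expect_equal(baseline_t_test(rep(2, 3), rep(3, 4))$p, 0)
})

test_that("summary-statistic t-test reproduces the printed baseline age comparison", {
  res <- baseline_t_test_summary(52.0, 6.4, 20, 52.2, 6.5, 20)
  expect_lt(abs(res$p - 0.922), 0.01)
  expect_equal(res$df, 38)
  # Summary mode agrees exactly with the data mode.
  set.seed(11)
  x <- rnorm(15, 3, 2)
  y <- rnorm(12, 3.5, 2.5)
  a <- baseline_t_test(x, y)
  b <- baseline_t_test_summary(mean(x), sd(x), 15, mean(y), sd(y), 12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  w <- baseline_t_test(x, y, var_equal = FALSE)
  w2 <- baseline_t_test_summary(mean(x), sd(x), 15, mean(y), sd(y), 12,
                                var_equal = FALSE)
  expect_equal(w$p, w2$p, tolerance = 1e-12)
})

test_that("pooled-t p-values track a permutation oracle under normality", {
  set.seed(22)
  for (i in 1:5) {
    x <- rnorm(10, 0, 1)
    y <- rnorm(10, 0.5, 1)
    p_t <- baseline_t_test(x, y)$p
    p_perm <- perm_t_p(x, y, B = 4000)
    expect_lt(abs(p_t - p_perm), 0.1)
  }
})

test_that("Fisher's exact test reproduces the printed sex-ratio p-value", {
  p <- fisher_exact(matrix(c(7, 9, 13, 11), nrow = 2))
  expect_equal(round(p, 3), 0.748)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(33)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), fisher_enum_p(tab), tolerance = 1e-7)
  }
  expect_message(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "integer")
})
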