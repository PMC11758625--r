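# Shared fixtures and independent oracles for the test suite.

# A generic, well-conditioned truth parameter set used across tests.
test_truth <- function() {
  pk_params(CL = 1.8, C0 = 0.06, ka = 0.02, Km_prime = 25, Vd = 90,
            Vmax = 0.45)
}

kin_names <- c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax")

# A strongly saturated absorption regime with the printed disposition
# values: the kind of parameter set the calibrated model lives in, and a
# well-posed design for recovery studies (the two pathways act on distinct
# dose scales, unlike regimes where Vmax/Km' ~ ka and the pathways alias).
saturated_regime_truth <- function() {
  pk_params(CL = 1.82, C0 = 0.063, ka = 0.02, Km_prime = 2, Vd = 85.7,
            Vmax = 0.48)
}

# Printed-summary calibration inputs: fixed disposition parameters and the
# 2 g / 4 g peak summaries.
printed_disposition <- function() list(CL = 1.82, C0 = 0.063, Vd = 85.7)
printed_peak_summaries <- function() {
  data.frame(dose_g = c(2, 4), cmax_mM = c(0.266, 0.289), tmax_min = c(30, 45))
}

# Calibration is deterministic but not instant; cache it per test session.
.calib_cache <- new.env(parent = emptyenv())
calibrated_printed_params <- function() {
  if (is.null(.calib_cache$params)) {
    .calib_cache$params <- suppressWarnings(
      calibrate_absorption(printed_disposition(), printed_peak_summaries()))
  }
  .calib_cache$params
}

# Closed-form 2x2 crossover treatment contrast: the mean over sequences of
# the sequence-wise mean within-subject (active - placebo) difference.
crossover_contrast <- function(records, outcome = "change") {
  y <- records[[outcome]]
  d <- tapply(seq_len(nrow(records)), records$subject_id, function(i) {
    y[i][records$treatment[i] == "active"] -
      y[i][records$treatment[i] == "placebo"]
  })
  seq_of <- tapply(records$sequence, records$subject_id, `[`, 1)
  mean(tapply(unlist(d), seq_of, mean))
}

# Monte-Carlo permutation p-value for a two-sample mean difference.
perm_t_p <- function(x, y, B = 4000) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y)
  n <- length(x)
  hits <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(length(z), n)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# Exact two-sided Fisher p by enumerating the hypergeometric support and
# summing point probabilities no larger than the observed one.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
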