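# Independent oracles used across the suite. These deliberately avoid the
# package's own estimation code paths.

# Delay between two curves by dense cross-correlation: upsample both to a
# fine grid (periodic linear interpolation) and maximize the circular
# cross-correlation. Brute force; used as the ground-truth comparator for
# the phase- and correlation-based estimators.
oracle_xcorr_delay <- function(q_a, q_b, time_axis, period = NULL,
                               fine_dt = 1e-4, max_delay = NULL) {
  if (is.null(period)) {
    dt <- diff(time_axis)[1]
    period <- length(time_axis) * dt
  }
  if (is.null(max_delay)) max_delay <- period / 4
  tt <- seq(0, period - fine_dt, by = fine_dt)
  interp <- function(q) {
    xx <- c(time_axis, time_axis[1] + period)
    yy <- c(q, q[1])
    stats::approx(xx, yy, xout = tt, rule = 2)$y
  }
  a <- interp(q_a) - mean(interp(q_a))
  b <- interp(q_b) - mean(interp(q_b))
  K <- floor(max_delay / fine_dt)
  n <- length(tt)
  # circular cross-correlation at all lags at once:
  # c(k) = sum_t a(t) b(t+k) = ifft(Conj(fft(a)) * fft(b))
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / n
  lags <- c(0:(n - 1))
  lags[lags > n / 2] <- lags[lags > n / 2] - n
  cc[abs(lags) > K] <- -Inf
  lags[which.max(cc)] * fine_dt
}

# Naive sample-grid delay: difference of the argmax positions. Quantized
# at the sampling interval by construction.
naive_peak_delay <- function(q_a, q_b, time_axis) {
  time_axis[which.max(q_b)] - time_axis[which.max(q_a)]
}

# Trapezoidal area under the empirical ROC curve, built point by point
# from the sorted unique scores (threshold rule: score >= t is a case).
oracle_trapezoid_auc <- function(pos, neg) {
  thr <- c(-Inf, sort(unique(c(pos, neg))), Inf)
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive two-sample permutation p-value for the rank-sum statistic
# (two-sided, via the distribution of the sum of ranks of group 1 over
# all reassignments). Matches the exact Wilcoxon rank-sum test when
# there are no ties.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Exhaustive Fisher p: hypergeometric probability of tables at least as
# extreme (two-sided by probability ordering), enumerating all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled Pearson correlation of a two-component mixture with independent
# components within each group (within-group correlation 0):
# rho = p(1-p) dmu1 dmu2 / sqrt((s1b^2 + p(1-p) dmu1^2)(s2b^2 + p(1-p) dmu2^2))
# where s_b^2 is the pooled within-group variance p*s_g1^2 + (1-p)*s_g2^2.
oracle_mixture_pearson <- function(p, mu1, sd1, mu2, sd2) {
  dmu1 <- mu1[1] - mu1[2]; dmu2 <- mu2[1] - mu2[2]
  v1 <- p * sd1[1]^2 + (1 - p) * sd1[2]^2
  v2 <- p * sd2[1]^2 + (1 - p) * sd2[2]^2
  q <- p * (1 - p)
  q * dmu1 * dmu2 / sqrt((v1 + q * dmu1^2) * (v2 + q * dmu2^2))
}

# Binormal AUC: probability that a case scores above a control when both
# are Gaussian.
oracle_binormal_auc <- function(mu_case, sd_case, mu_ctrl, sd_ctrl) {
  stats::pnorm((mu_case - mu_ctrl) / sqrt(sd_case^2 + sd_ctrl^2))
}

# Shared small fixtures
default_params <- function() waveform_params()

acq_curves <- function(dense, snr_db, seed) {
  sample_and_noise(dense, effective_dt = 0.034, n_phases = 50L,
                   snr_db = snr_db, seed = seed)
}
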