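make_pair <- function(tau, dt = 0.01, params = default_params(),
                      period = 1.0) {
  tt <- seq(0, period - dt, by = dt)
  list(q_a = make_flow_waveform(params, tt),
       q_b = make_flow_waveform(params, tt - tau),
       time_axis = tt)
}

test_that("identical curves give zero delay for all estimators", {
  pr <- make_pair(0)
  expect_lt(abs(wavelet_delay(pr$q_a, pr$q_a, pr$time_axis)$delay), 1e-4)
  expect_lt(abs(upslope_xcorr_delay(pr$q_a, pr$q_a, pr$time_axis)$delay), 1e-4)
  expect_lt(abs(foot_delay(pr$q_a, pr$q_a, pr$time_axis)$delay), 1e-12)
})

test_that("a pure circular shift is recovered by each estimator", {
  pr <- make_pair(0.020, dt = 0.010)
  expect_equal(wavelet_delay(pr$q_a, pr$q_b, pr$time_axis)$delay, 0.020,
               tolerance = 0.05)
  expect_equal(upslope_xcorr_delay(pr$q_a, pr$q_b, pr$time_axis)$delay,
               0.020, tolerance = 0.075)
  expect_equal(foot_delay(pr$q_a, pr$q_b, pr$time_axis)$delay, 0.020,
               tolerance = 0.06)

  pr13 <- make_pair(0.013, dt = 0.010)
  expect_lt(abs(upslope_xcorr_delay(pr13$q_a, pr13$q_b,
                                    pr13$time_axis)$delay - 0.013), 0.0015)
})

test_that("quality scores live in [0, 1]", {
  pr <- make_pair(0.015, dt = 0.01)
  for (f in list(wavelet_delay, upslope_xcorr_delay, foot_delay)) {
    q <- f(pr$q_a, pr$q_b, pr$time_axis)$quality
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("wavelet recovers a 5 ms shift at 34 ms acquisition, SNR 20 dB", {
  params <- default_params()
  cl <- make_centerline(300, 200, seed = 1)
  # two planes 5 ms apart at 10 m/s: 50 mm spacing
  dense <- propagate_waveform(params, cl, n_planes = 7, true_PWV = 10)
  i_a <- 1; i_b <- 2   # 50 mm apart -> 5 ms
  tau_true <- diff(dense$plane_arc_lengths[c(i_a, i_b)]) / 1000 / 10
  est <- vapply(1:100, function(s) {
    curves <- acq_curves(dense, snr_db = 20, seed = s)
    wavelet_delay(curves$flow[i_a, ], curves$flow[i_b, ],
                  curves$time_axis)$delay
  }, numeric(1))
  expect_lt(abs(mean(est) - tau_true), 0.001)          # mean bias < 1 ms
  expect_lt(mean(abs(est - tau_true)), 0.002)          # MAE < 2 ms
})

test_that("foot delay is amplitude-invariant and noise-tolerant", {
  pr <- make_pair(0, dt = 0.01)
  r <- foot_delay(pr$q_a, 0.5 * pr$q_a, pr$time_axis)
  expect_lt(abs(r$delay), 0.001)

  set.seed(77)
  params <- default_params()
  errs <- vapply(1:100, function(s) {
    pr <- make_pair(0.010, dt = 0.010)
    sda <- stats::sd(pr$q_a) * 10^(-20 / 20)
    qa <- pr$q_a + stats::rnorm(length(pr$q_a), 0, sda)
    qb <- pr$q_b + stats::rnorm(length(pr$q_b), 0, sda)
    foot_delay(qa, qb, pr$time_axis)$delay - 0.010
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.003)
})

test_that("xcorr delay has sub-millisecond bias across a shift sweep", {
  for (tau in seq(0.002, 0.030, by = 0.004)) {
    pr <- make_pair(tau, dt = 0.010)
    est <- upslope_xcorr_delay(pr$q_a, pr$q_b, pr$time_axis)$delay
    expect_lt(abs(est - tau), 0.0015)
  }
})

test_that("degenerate inputs raise typed conditions", {
  pr <- make_pair(0.01, dt = 0.01)
  flat <- rep(5, length(pr$q_a))
  expect_error(wavelet_delay(flat, pr$q_b, pr$time_axis),
               class = "aortastiff_no_signal")
  expect_error(foot_delay(pr$q_a, flat, pr$time_axis),
               class = "aortastiff_no_signal")
  # anti-correlated pulses: no admissible lag reaches the correlation
  # floor within the physiological delay range
  expect_error(upslope_xcorr_delay(pr$q_a, -pr$q_a, pr$time_axis,
                                   max_delay = 0.05),
               class = "aortastiff_low_quality")
})

test_that("shift equivariance: adding a delay shifts every estimate by it", {
  params <- default_params()
  tt <- seq(0, 0.99, by = 0.01)
  q_a <- make_flow_waveform(params, tt)
  for (tau in c(-0.06, -0.02, 0.03, 0.12)) {
    q_b <- make_flow_waveform(params, tt - tau)
    for (f in list(wavelet_delay, upslope_xcorr_delay)) {
      expect_lt(abs(f(q_a, q_b, tt)$delay - tau), 5e-4)
    }
  }
})

test_that("antisymmetry: delay(a,b) = -delay(b,a)", {
  pr <- make_pair(0.018, dt = 0.01)
  for (f in list(wavelet_delay, upslope_xcorr_delay)) {
    d_ab <- f(pr$q_a, pr$q_b, pr$time_axis)$delay
    d_ba <- f(pr$q_b, pr$q_a, pr$time_axis)$delay
    expect_lt(abs(d_ab + d_ba), 5e-4)
  }
})

test_that("amplitude scaling of one curve leaves estimates unchanged", {
  pr <- make_pair(0.012, dt = 0.01)
  for (f in list(wavelet_delay, upslope_xcorr_delay, foot_delay)) {
    d1 <- f(pr$q_a, pr$q_b, pr$time_axis)$delay
    d2 <- f(pr$q_a, 3.7 * pr$q_b, pr$time_axis)$delay
    expect_lt(abs(d1 - d2), 0.001)
  }
})

test_that("plane_delays returns zero at the reference and d/PWV upstream", {
  params <- default_params()
  cl <- make_centerline(300, 200, seed = 2)
  dense <- propagate_waveform(params, cl, n_planes = 31, true_PWV = 10)
  res <- plane_delays(dense, method = "wavelet")
  expect_identical(res$delay[res$reference_plane_index], 0)
  truth <- (res$arc_lengths[31] - res$arc_lengths) / 1000 / 10
  expect_lt(max(abs(res$delay - truth)), 5e-4)
  # delays grow by 1 ms per 10 mm toward the most proximal plane
  expect_equal(diff(res$delay[1:2]) * 1000,
               -diff(res$arc_lengths[1:2]) / 10, tolerance = 0.05)
})

test_that("plane failures are marked missing; excess failures abort", {
  params <- default_params()
  cl <- make_centerline(300, 200, seed = 2)
  dense <- propagate_waveform(params, cl, n_planes = 40, true_PWV = 10)
  curves <- acq_curves(dense, snr_db = 15, seed = 8)
  res <- plane_delays(curves, method = "wavelet")
  expect_gte(mean(!is.na(res$delay)), 0.8)

  # corrupt most planes to flat lines -> insufficient data
  bad <- curves
  bad$flow[1:30, ] <- 1
  expect_error(plane_delays(bad, method = "wavelet"),
               class = "aortastiff_insufficient_data")
})
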