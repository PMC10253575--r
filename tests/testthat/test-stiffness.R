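test_that("an exact line of delays is fit exactly", {
  d <- c(0, 50, 100, 150)                      # mm from reference
  tau <- c(0, 5, 10, 15) / 1000                # s
  # convert to the plane_delays convention: reference = most distal plane
  arc <- c(0, 50, 100, 150)
  delays <- (150 - arc) / 1000 / 10            # 10 m/s
  fit <- pwv_from_delays(arc, delays)
  expect_equal(fit$PWV, 10, tolerance = 1e-10)
  expect_identical(fit$n_planes_used, 4L)

  # two planes reduce to the two-point formula
  fit2 <- pwv_from_delays(c(0, 120), c(0.012, 0), reference = 2)
  expect_equal(fit2$PWV, 10, tolerance = 1e-10)
  expect_equal(fit2$PWV, pwv_two_plane(120, 0.012), tolerance = 1e-12)
})

test_that("both regression orientations agree on noise-free lines", {
  arc <- seq(0, 300, by = 10)
  delays <- (300 - arc) / 1000 / 8
  f1 <- pwv_from_delays(arc, delays, orientation = "delay_on_distance")
  f2 <- pwv_from_delays(arc, delays, orientation = "distance_on_delay")
  expect_equal(f1$PWV, 8, tolerance = 1e-10)
  expect_equal(f2$PWV, 8, tolerance = 1e-10)
})

test_that("least squares recovers PWV from noisy delays without bias", {
  arc <- seq(0, 300, length.out = 40)
  truth <- (300 - arc) / 1000 / 12
  set.seed(101)
  est <- vapply(1:500, function(r) {
    pwv_from_delays(arc, truth + stats::rnorm(40, 0, 0.002))$PWV
  }, numeric(1))
  expect_lt(abs(mean(est) - 12) / 12, 0.03)
})

test_that("time rescaling of delays rescales PWV reciprocally", {
  arc <- seq(0, 250, by = 25)
  delays <- (250 - arc) / 1000 / 9 + c(0, 1e-4, -2e-4, 3e-4, 0, 1e-4,
                                       -1e-4, 2e-4, -3e-4, 0, 1e-4)
  f1 <- pwv_from_delays(arc, delays)
  f2 <- pwv_from_delays(arc, 2 * delays)
  expect_equal(f1$PWV / 2, f2$PWV, tolerance = 1e-9)
})

test_that("non-physiological fits raise typed errors", {
  arc <- c(0, 100, 200)
  expect_error(pwv_from_delays(arc, c(0, 0.01, 0.02)),   # delay grows downstream
               class = "aortastiff_nonphysiological")
  expect_error(pwv_two_plane(120, -0.01),
               class = "aortastiff_nonphysiological")
  expect_error(pwv_from_delays(arc, c(NA, NA, 0.01)),
               class = "aortastiff_invalid_argument")
})

test_that("two-plane PWV is length over transit time in m/s", {
  expect_equal(pwv_two_plane(120, 0.015), 8.0, tolerance = 1e-12)
  expect_equal(pwv_two_plane(120, 0.012), 10.0, tolerance = 1e-12)
})

test_that("two-plane PWV from the synthetic centerline recovers truth", {
  params <- default_params()
  cl <- make_centerline(300, 200, seed = 6)
  dense <- propagate_waveform(params, cl, n_planes = 40, true_PWV = 8)
  lm_aa <- cl$landmarks[["ascending_at_2D_slice"]]
  lm_da <- cl$landmarks[["descending_at_2D_slice"]]
  s_aa <- cl$cumulative_arc_length[lm_aa]
  s_da <- cl$cumulative_arc_length[lm_da]
  i_aa <- which.min(abs(dense$plane_arc_lengths - s_aa))
  i_da <- which.min(abs(dense$plane_arc_lengths - s_da))
  d <- upslope_xcorr_delay(dense$flow[i_aa, ], dense$flow[i_da, ],
                           dense$time_axis)
  len <- dense$plane_arc_lengths[i_da] - dense$plane_arc_lengths[i_aa]
  expect_equal(pwv_two_plane(len, d$delay), 8, tolerance = 0.05)
})

test_that("distensibility follows dA/(Amin PP), averaged over sites", {
  pr <- pressure_record(131, 81)   # PP 50
  aa <- area_curve_set("ascending", 880, 800)
  da <- area_curve_set("descending", 880, 800)
  expect_equal(distensibility(aa, da, pr), 2.0, tolerance = 1e-12)

  # unequal sites average arithmetically: 2.0 and 1.0 -> 1.5
  da2 <- area_curve_set("descending", 840, 800)
  expect_equal(distensibility(aa, da2, pr), 1.5, tolerance = 1e-12)

  # no area change -> zero
  aa0 <- area_curve_set("ascending", 800, 800)
  expect_equal(distensibility(aa0, aa0, pr), 0, tolerance = 1e-15)

  # invariant to common rescaling of both areas
  aa_s <- area_curve_set("ascending", 880 * 3, 800 * 3)
  da_s <- area_curve_set("descending", 880 * 3, 800 * 3)
  expect_equal(distensibility(aa_s, da_s, pr),
               distensibility(aa, da, pr), tolerance = 1e-12)
})

test_that("area generation inverts the distensibility definition", {
  subj <- list(true_distensibility = 2.0,
               pressure = pressure_record(131, 81))
  ap <- make_area_and_pressure(subj, Amin_AA = 800, Amin_DA = 800)
  expect_equal(ap$areas_AA$Amax - ap$areas_AA$Amin, 80, tolerance = 1e-12)
  expect_equal(distensibility(ap$areas_AA, ap$areas_DA, ap$pressure), 2.0,
               tolerance = 1e-12)

  # published ascending-aorta geometry: D 1.71e-3/mmHg, diameter 35.1 mm,
  # pressures 118/81 -> area change near 61 mm^2
  subj2 <- list(true_distensibility = 1.71,
                pressure = pressure_record(118, 81))
  amin <- pi * 35.1^2 / 4
  ap2 <- make_area_and_pressure(subj2, Amin_AA = amin, Amin_DA = amin)
  expect_equal(ap2$areas_AA$Amax - ap2$areas_AA$Amin, 61.2,
               tolerance = 0.01)

  # zero distensibility leaves the lumen area unchanged
  subj0 <- list(true_distensibility = 0,
                pressure = pressure_record(118, 81))
  ap0 <- make_area_and_pressure(subj0)
  expect_identical(ap0$areas_AA$Amax, ap0$areas_AA$Amin)
})

test_that("subject_panel recovers truth and records missing measures", {
  params <- default_params()
  cl <- make_centerline(300, 200, seed = 3)
  dense <- propagate_waveform(params, cl, n_planes = 40, true_PWV = 10)
  curves <- sample_and_noise(dense, snr_db = Inf, seed = 1)
  pr <- pressure_record(120, 80)
  ap <- make_area_and_pressure(list(true_distensibility = 1.8, pressure = pr))
  panel <- subject_panel(curves, cl, ap$areas_AA, ap$areas_DA, pr,
                         cf_PWV = 9.9)
  expect_gt(panel$PWV_4D, 9.5); expect_lt(panel$PWV_4D, 10.5)
  expect_equal(panel$cf_PWV, 9.9)
  expect_equal(panel$distensibility, 1.8, tolerance = 1e-10)
  expect_gt(panel$PWV_2D, 8); expect_lt(panel$PWV_2D, 12)

  panel2 <- subject_panel(curves, cl, ap$areas_AA, ap$areas_DA, pr)
  expect_true(is.na(panel2$cf_PWV))
  expect_false(is.na(panel2$PWV_4D))
  expect_match(panel2$failures$cf_PWV, "absent")
})

test_that("full-pipeline recovery holds across a PWV sweep at 20 dB", {
  params <- default_params()
  for (v in c(8, 12, 18)) {
    cl <- make_centerline(300, 200, seed = 20 + v)
    dense <- propagate_waveform(params, cl, n_planes = 40, true_PWV = v)
    est <- vapply(1:100, function(s) {
      curves <- acq_curves(dense, snr_db = 20, seed = 1000 * v + s)
      res <- plane_delays(curves, method = "wavelet")
      pwv_from_delays(res$arc_lengths, res$delay,
                      reference = res$reference_plane_index)$PWV
    }, numeric(1))
    expect_lt(mean(abs(est - v)) / v, 0.10)
  }
})
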