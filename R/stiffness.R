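# Conversion of transit times, lengths, areas and pressures into the
# four stiffness measures.

#' Multi-plane PWV from a distance-vs-delay fit
#'
#' Ordinary least-squares fit relating distance-to-reference (m) and
#' transit time (s). The transit-time estimates carry nearly all the
#' measurement noise, so the default orientation regresses delay on
#' distance — the noisy variable is the response, the slope (s/m) is
#' unbiased under symmetric delay noise, and PWV is its reciprocal.
#' The alternative orientation (distance on delay, slope = PWV
#' directly) is available via `orientation` but attenuates toward low
#' PWV when the delays are noisy, as with any error-in-regressor fit.
#' One outlier-rejection pass removes points with
#' |residual| > 2.5 residual SDs, then refits.
#'
#' @param arc_lengths plane arc-length positions, mm.
#' @param delays per-plane delays, s, with the convention of
#'   [plane_delays()] (reference = most distal plane, positive
#'   upstream); `NA` entries are dropped.
#' @param reference index of the reference plane (default: last).
#' @param orientation "delay_on_distance" (default) or
#'   "distance_on_delay".
#' @return a `pwv_fit`: list with `PWV` (m/s), `n_planes_used`,
#'   `residual_sd` (s, in the delay direction), `rejected` (plane
#'   indices removed by the outlier pass).
#' @export
pwv_from_delays <- function(arc_lengths, delays, reference = NULL,
                            orientation = c("delay_on_distance",
                                            "distance_on_delay")) {
  orientation <- match.arg(orientation)
  assert_that(length(arc_lengths) == length(delays),
              "arc_lengths and delays must have equal length")
  if (is.null(reference)) reference <- length(arc_lengths)
  ok <- which(!is.na(delays))
  assert_that(length(ok) >= 2, "need >= 2 valid (distance, delay) pairs")

  # distance to the reference plane, m; positive upstream
  x_all <- (arc_lengths[reference] - arc_lengths) / 1000
  fit_once <- function(idx) {
    tau <- delays[idx]; x <- x_all[idx]
    if (orientation == "distance_on_delay") {
      f <- stats::lm.fit(cbind(1, tau), x)
      slope <- f$coefficients[2]
      resid_delay <- if (abs(slope) > 0) f$residuals / slope else f$residuals
    } else {
      f <- stats::lm.fit(cbind(1, x), tau)
      slope <- 1 / f$coefficients[2]
      resid_delay <- f$residuals
    }
    list(slope = unname(slope), resid = resid_delay)
  }

  f1 <- fit_once(ok)
  rejected <- integer(0)
  rsd <- stats::sd(f1$resid)
  if (is.finite(rsd) && rsd > 0) {
    bad <- abs(f1$resid) > 2.5 * rsd
    if (any(bad) && sum(!bad) >= 2) {
      rejected <- ok[bad]
      ok <- ok[!bad]
      f1 <- fit_once(ok)
    }
  }
  pwv <- f1$slope
  if (!is.finite(pwv) || pwv <= 0) {
    stop(errorCondition(sprintf("non-physiological fit: slope %.3g m/s", pwv),
                        class = c("aortastiff_nonphysiological",
                                  "error", "condition")))
  }
  structure(list(PWV = pwv, n_planes_used = length(ok),
                 residual_sd = stats::sd(f1$resid), rejected = rejected,
                 orientation = orientation),
            class = "pwv_fit")
}

#' @export
print.pwv_fit <- function(x, ...) {
  cat(sprintf("PWV %.2f m/s (%d planes, residual SD %.2f ms)\n",
              x$PWV, x$n_planes_used, 1000 * x$residual_sd))
  invisible(x)
}

#' Two-plane PWV
#'
#' PWV from a single transit time between two sites and the centerline
#' length separating them: `PWV = length / transit_time`.
#'
#' @param aortic_length centerline distance between the two sites, mm.
#' @param transit_time ascending-to-descending transit time, s (> 0).
#' @return PWV in m/s.
#' @examples
#' pwv_two_plane(120, 0.015)  # 8 m/s
#' @export
pwv_two_plane <- function(aortic_length, transit_time) {
  assert_that(aortic_length > 0, "aortic_length must be > 0")
  if (!is.finite(transit_time) || transit_time <= 0) {
    stop(errorCondition("non-physiological transit time (<= 0)",
                        class = c("aortastiff_nonphysiological",
                                  "error", "condition")))
  }
  (aortic_length / 1000) / transit_time
}

#' Aortic distensibility from lumen areas and central pulse pressure
#'
#' Per site, D = (Amax - Amin) / (Amin * PP); the returned value is the
#' unweighted mean of the ascending and descending sites, reported in
#' 1e-3/mmHg.
#'
#' @param areas_AA,areas_DA [area_curve_set()] objects for the ascending
#'   and descending aorta.
#' @param pressure a [pressure_record()].
#' @return distensibility in 1e-3/mmHg.
#' @export
distensibility <- function(areas_AA, areas_DA, pressure) {
  assert_that(inherits(areas_AA, "area_curve_set") &&
                inherits(areas_DA, "area_curve_set"), "invalid area sets")
  assert_that(inherits(pressure, "pressure_record") && pressure$PP > 0,
              "pulse pressure must be > 0")
  site_d <- function(a) (a$Amax - a$Amin) / (a$Amin * pressure$PP)
  1e3 * mean(c(site_d(areas_AA), site_d(areas_DA)))
}

#' Assemble the four-measure stiffness panel for one subject
#'
#' Runs the full estimation chain on a subject's inputs: multi-plane
#' PWV from [plane_delays()] (wavelet estimator) and [pwv_from_delays()];
#' two-plane PWV from the delay between the planes nearest the two
#' cine-slice landmarks (upslope cross-correlation by default) and the
#' corresponding centerline length; distensibility from the area pair
#' and pulse pressure; and the device-reported carotid-femoral PWV
#' passed through. Per-measure failures are recorded as missing with a
#' reason instead of raising.
#'
#' @param curves the subject's `flow_curve_set` (reconstructed phases).
#' @param centerline the subject's `aortic_centerline`.
#' @param areas_AA,areas_DA [area_curve_set()] objects (optional).
#' @param pressure a [pressure_record()] (optional).
#' @param cf_PWV device-reported carotid-femoral PWV, m/s (optional).
#' @param two_plane_method transit-time estimator for the two-plane PWV.
#' @return a `stiffness_panel`: list with `cf_PWV`, `PWV_2D`, `PWV_4D`,
#'   `distensibility` (`NA` where not computable), `provenance` and
#'   `failures` (named reasons).
#' @export
subject_panel <- function(curves, centerline, areas_AA = NULL,
                          areas_DA = NULL, pressure = NULL, cf_PWV = NULL,
                          two_plane_method = "xcorr") {
  failures <- list()
  pwv4 <- NA_real_
  tt <- tryCatch({
    res <- plane_delays(curves, method = "wavelet")
    fit <- pwv_from_delays(res$arc_lengths, res$delay,
                           reference = res$reference_plane_index)
    fit$PWV
  }, error = function(e) { failures$PWV_4D <<- conditionMessage(e); NA_real_ })
  pwv4 <- tt

  pwv2 <- NA_real_
  pwv2 <- tryCatch({
    lm_aa <- centerline$landmarks[["ascending_at_2D_slice"]]
    lm_da <- centerline$landmarks[["descending_at_2D_slice"]]
    s_aa <- centerline$cumulative_arc_length[lm_aa]
    s_da <- centerline$cumulative_arc_length[lm_da]
    i_aa <- which.min(abs(curves$plane_arc_lengths - s_aa))
    i_da <- which.min(abs(curves$plane_arc_lengths - s_da))
    est <- switch(two_plane_method, xcorr = upslope_xcorr_delay,
                  wavelet = wavelet_delay, foot = foot_delay)
    d <- est(curves$flow[i_aa, ], curves$flow[i_da, ], curves$time_axis)
    len <- abs(curves$plane_arc_lengths[i_da] - curves$plane_arc_lengths[i_aa])
    pwv_two_plane(len, d$delay)
  }, error = function(e) { failures$PWV_2D <<- conditionMessage(e); NA_real_ })

  dist <- NA_real_
  if (!is.null(areas_AA) && !is.null(areas_DA) && !is.null(pressure)) {
    dist <- tryCatch(distensibility(areas_AA, areas_DA, pressure),
                     error = function(e) {
                       failures$distensibility <<- conditionMessage(e)
                       NA_real_
                     })
  } else {
    failures$distensibility <- "area/pressure inputs absent"
  }

  cf <- if (is.null(cf_PWV)) NA_real_ else cf_PWV
  if (is.null(cf_PWV)) failures$cf_PWV <- "tonometry input absent"

  structure(list(cf_PWV = cf, PWV_2D = pwv2, PWV_4D = pwv4,
                 distensibility = dist,
                 provenance = c(cf_PWV = "simulated-direct",
                                PWV_2D = "estimated-from-waveforms",
                                PWV_4D = "estimated-from-waveforms",
                                distensibility = "estimated-from-areas"),
                 failures = failures),
            class = "stiffness_panel")
}

#' @export
print.stiffness_panel <- function(x, ...) {
  cat(sprintf("Stiffness panel: cf %.2f | 2D %.2f | 4D %.2f m/s | D %.2f e-3/mmHg\n",
              x$cf_PWV, x$PWV_2D, x$PWV_4D, x$distensibility))
  if (length(x$failures)) {
    cat("  missing:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}
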