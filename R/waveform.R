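#' Waveform template parameters
#'
#' Parameter set for the synthetic aortic flow-rate waveform: a
#' gamma-variate systolic pulse with an optional small secondary
#' (diastolic) wave. Defaults describe a resting adult aorta: 1 s cardiac
#' period, systolic peak ~400 mL/s at 150 ms with a 100 ms upslope.
#'
#' @param cardiac_period cardiac cycle length, s.
#' @param peak_flow systolic peak flow rate, mL/s.
#' @param time_to_peak time from cycle start to the systolic peak, s.
#' @param upslope_duration duration of the systolic upslope, s; must be
#'   shorter than `time_to_peak`.
#' @param diastolic_fraction amplitude of the secondary diastolic wave as
#'   a fraction of `peak_flow`, in [0, 1).
#' @param baseline_flow diastolic baseline flow, mL/s (>= 0).
#' @return a `waveform_params` list.
#' @export
waveform_params <- function(cardiac_period = 1.0,
                            peak_flow = 400,
                            time_to_peak = 0.15,
                            upslope_duration = 0.10,
                            diastolic_fraction = 0.1,
                            baseline_flow = 0) {
  assert_that(cardiac_period > 0, "cardiac_period must be > 0")
  assert_that(upslope_duration > 0 && upslope_duration < time_to_peak &&
                time_to_peak < cardiac_period,
              "need 0 < upslope_duration < time_to_peak < cardiac_period")
  assert_that(peak_flow > baseline_flow && baseline_flow >= 0,
              "need peak_flow > baseline_flow >= 0")
  assert_that(diastolic_fraction >= 0 && diastolic_fraction < 1,
              "diastolic_fraction must be in [0, 1)")
  structure(list(cardiac_period = cardiac_period, peak_flow = peak_flow,
                 time_to_peak = time_to_peak,
                 upslope_duration = upslope_duration,
                 diastolic_fraction = diastolic_fraction,
                 baseline_flow = baseline_flow),
            class = "waveform_params")
}

# Gamma-variate pulse normalized to peak 1 at t = t_peak, starting at
# t_onset = t_peak - upslope. Shape parameter alpha controls skewness;
# alpha = 3 gives a physiological fast-upslope / slower-decay pulse.
gamma_pulse <- function(t, t_peak, upslope, alpha = 3) {
  t0 <- t_peak - upslope
  beta <- upslope / alpha           # so the mode sits at t_peak
  tt <- pmax(t - t0, 0)
  # normalized gamma variate: (tt / (alpha*beta))^alpha * exp(alpha - tt/beta)
  (tt / (alpha * beta))^alpha * exp(alpha - tt / beta)
}

#' Evaluate the synthetic flow waveform
#'
#' Gamma-variate systolic pulse peaking at `time_to_peak` with value
#' `peak_flow`, an optional delayed secondary wave scaled by
#' `diastolic_fraction`, and `baseline_flow` elsewhere. The waveform is
#' periodic with period `cardiac_period`; times are wrapped into one
#' cycle. Flow is non-negative everywhere.
#'
#' @param params a [waveform_params()] object.
#' @param time_axis times (s) at which to evaluate the waveform.
#' @return numeric vector of flow-rate samples, mL/s.
#' @examples
#' p <- waveform_params()
#' q <- make_flow_waveform(p, seq(0, 0.99, by = 0.01))
#' @export
make_flow_waveform <- function(params, time_axis) {
  assert_that(inherits(params, "waveform_params"),
              "params must be a waveform_params object")
  assert_that(is.numeric(time_axis) && length(time_axis) >= 1,
              "time_axis must be numeric")
  t <- time_axis %% params$cardiac_period
  amp <- params$peak_flow - params$baseline_flow
  q <- amp * gamma_pulse(t, params$time_to_peak, params$upslope_duration)
  if (params$diastolic_fraction > 0) {
    # secondary wave: delayed, broader copy in early diastole
    q <- q + amp * params$diastolic_fraction *
      gamma_pulse(t, params$time_to_peak + 0.25 * params$cardiac_period,
                  2 * params$upslope_duration)
  }
  pmax(q + params$baseline_flow, 0)
}

#' Propagate a flow waveform along the centerline
#'
#' Forward model for multi-plane flow-rate curves: plane i at arc length
#' d_i carries `a_i * Q(t - d_i / PWV)` with `a_i = (1 - damping)^d_i`,
#' i.e. the waveform travels at the ground-truth pulse wave velocity and
#' is exponentially attenuated with distance. Curves are evaluated on a
#' dense time grid (dt <= 1 ms) before any acquisition resampling; delays
#' wrap periodically within the cardiac cycle.
#'
#' @param params a [waveform_params()] object (defines the waveform and
#'   the cardiac period).
#' @param centerline an [make_centerline()] result.
#' @param n_planes number of equally spaced analysis planes (>= 2).
#' @param true_PWV ground-truth pulse wave velocity, m/s, in [2, 30].
#' @param damping per-mm fractional amplitude loss (default 0).
#' @param plane_extent landmark name of the most distal plane; planes are
#'   spread uniformly from the aortic valve to this landmark. Exposed
#'   because published pipelines differ on whether planes stop at the
#'   diaphragm or extend to the coeliac trunk.
#' @param dense_dt dense-grid time step, s (<= 1 ms).
#' @return a `flow_curve_set`: list with `time_axis` (s),
#'   `plane_arc_lengths` (mm), `flow` (planes x time matrix, mL/s) and
#'   `effective_dt` (NA until acquisition sampling is applied).
#' @export
propagate_waveform <- function(params, centerline, n_planes = 40L,
                               true_PWV = 10, damping = 0,
                               plane_extent = "coeliac_trunk",
                               dense_dt = 0.001) {
  assert_that(inherits(params, "waveform_params"), "params invalid")
  assert_that(inherits(centerline, "aortic_centerline"), "centerline invalid")
  assert_that(is.numeric(true_PWV) && true_PWV >= 2 && true_PWV <= 30,
              "true_PWV must be in [2, 30] m/s")
  assert_that(n_planes >= 2, "need at least 2 planes")
  assert_that(dense_dt > 0 && dense_dt <= 0.001, "dense_dt must be <= 1 ms")
  assert_that(damping >= 0 && damping < 1, "damping must be in [0, 1)")

  d_max <- centerline$cumulative_arc_length[
    centerline$landmarks[[plane_extent]]]
  d <- seq(0, d_max, length.out = as.integer(n_planes))     # mm
  tt <- seq(0, params$cardiac_period - dense_dt, by = dense_dt)
  delay_s <- (d / 1000) / true_PWV                          # mm -> m
  flow <- t(vapply(seq_along(d), function(i) {
    (1 - damping)^d[i] * make_flow_waveform(params, tt - delay_s[i])
  }, numeric(length(tt))))

  structure(list(time_axis = tt, plane_arc_lengths = d, flow = flow,
                 effective_dt = NA_real_,
                 cardiac_period = params$cardiac_period,
                 true_PWV = true_PWV),
            class = "flow_curve_set")
}

#' Construct a flow-curve set from raw components
#'
#' @param time_axis uniformly spaced times over one cardiac cycle, s.
#' @param plane_arc_lengths strictly increasing plane positions, mm.
#' @param flow matrix of flow samples (planes x time), mL/s.
#' @param effective_dt acquisition temporal resolution, s (NA if none).
#' @param cardiac_period cycle length, s; defaults to the spanned range.
#' @return a `flow_curve_set` object.
#' @export
flow_curve_set <- function(time_axis, plane_arc_lengths, flow,
                           effective_dt = NA_real_, cardiac_period = NULL) {
  flow <- as.matrix(flow)
  assert_that(length(time_axis) >= 2, "time_axis needs >= 2 samples")
  assert_that(nrow(flow) == length(plane_arc_lengths),
              "flow must have one row per plane")
  assert_that(ncol(flow) == length(time_axis),
              "flow columns must match time_axis")
  assert_that(all(diff(plane_arc_lengths) > 0),
              "plane_arc_lengths must be strictly increasing")
  if (is.null(cardiac_period)) {
    dt <- diff(time_axis)[1]
    cardiac_period <- length(time_axis) * dt
  }
  structure(list(time_axis = time_axis,
                 plane_arc_lengths = plane_arc_lengths,
                 flow = flow, effective_dt = effective_dt,
                 cardiac_period = cardiac_period, true_PWV = NA_real_),
            class = "flow_curve_set")
}

#' @export
print.flow_curve_set <- function(x, ...) {
  cat("Flow curve set:", nrow(x$flow), "planes x", ncol(x$flow), "phases;",
      sprintf("span %.0f mm, period %.2f s\n",
              diff(range(x$plane_arc_lengths)), x$cardiac_period))
  invisible(x)
}

#' Apply acquisition sampling, view-sharing and noise
#'
#' Emulates the information loss of a time-resolved flow acquisition:
#' each dense curve is sampled at the acquisition temporal resolution
#' `effective_dt`, linearly interpolated (periodically) to `n_phases`
#' uniform cardiac phases — a simple stand-in for view-sharing
#' reconstruction, which shares acquired data between displayed frames —
#' and corrupted with zero-mean Gaussian noise at the stated SNR. Signal
#' power is the variance of the noise-free resampled curve, so
#' `snr_db = 20` means a noise SD of one tenth of the signal SD.
#'
#' @param curves a dense `flow_curve_set` from [propagate_waveform()].
#' @param effective_dt acquisition temporal resolution, s (> 0).
#' @param n_phases number of reconstructed cardiac phases (>= 8).
#' @param snr_db signal-to-noise ratio in dB; `Inf` disables noise.
#' @param seed integer seed for the noise draw.
#' @return a `flow_curve_set` on the reconstructed phase grid.
#' @export
sample_and_noise <- function(curves, effective_dt = 0.034, n_phases = 50L,
                             snr_db = 20, seed = 1L) {
  assert_that(inherits(curves, "flow_curve_set"), "curves invalid")
  assert_that(effective_dt > 0, "effective_dt must be > 0")
  assert_that(n_phases >= 8, "n_phases must be >= 8")
  assert_that(is.numeric(snr_db) && !is.na(snr_db),
              "snr_db must be numeric (use Inf for noise-free)")

  period <- curves$cardiac_period
  t_acq <- seq(0, period - 1e-12, by = effective_dt)
  t_out <- seq(0, period - period / n_phases, length.out = as.integer(n_phases))
  set.seed(as.integer(seed))
  flow <- t(apply(curves$flow, 1, function(q) {
    q_acq <- periodic_approx(curves$time_axis, q, t_acq, period)
    q_out <- periodic_approx(t_acq, q_acq, t_out, period)
    if (is.finite(snr_db)) {
      sigma <- stats::sd(q_out) * 10^(-snr_db / 20)
      q_out <- q_out + stats::rnorm(length(q_out), 0, sigma)
    }
    q_out
  }))
  structure(list(time_axis = t_out,
                 plane_arc_lengths = curves$plane_arc_lengths,
                 flow = flow, effective_dt = effective_dt,
                 cardiac_period = period, true_PWV = curves$true_PWV),
            class = "flow_curve_set")
}
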