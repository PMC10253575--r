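# Transit-time estimation between aortic flow-rate curves.
#
# Three estimators are provided: the cross-wavelet phase method (the
# primary estimator for multi-plane PWV, robust to coarse temporal
# resolution), a classical intersecting-tangent foot-to-foot method, and
# a normalized cross-correlation of the systolic upslope with parabolic
# sub-sample refinement (the conventional two-plane estimator).
# All return the delay of q_b relative to q_a in seconds (positive when
# q_b lags q_a) plus a quality score in [0, 1].

validate_pair <- function(q_a, q_b, time_axis) {
  assert_that(length(q_a) == length(q_b) &&
                length(q_a) == length(time_axis) && length(q_a) >= 8,
              "curves and time_axis must share length >= 8")
  dts <- diff(time_axis)
  assert_that(max(abs(dts - dts[1])) < 1e-9, "time_axis must be uniform")
  if (stats::var(q_a) == 0 || stats::var(q_b) == 0) {
    stop_nosignal("flat (zero-variance) input curve")
  }
  invisible(dts[1])
}

# Indices of the systolic upslope of q (10% to 90% of the rise before the
# global peak), dilated by one sample each side.
upslope_indices <- function(q, dilate = 1L) {
  n <- length(q)
  ip <- which.max(q)
  if (ip < 3) stop_nosignal("no upslope detectable (peak at cycle start)")
  rise <- (q - min(q)) / (max(q) - min(q))
  below <- which(rise[seq_len(ip)] <= 0.10)
  i10 <- if (length(below)) max(below) else 1L
  above <- which(rise[seq_len(ip)] >= 0.90 & seq_len(ip) >= i10)
  i90 <- if (length(above)) min(above) else ip
  lo <- max(1L, i10 - dilate); hi <- min(n, i90 + dilate)
  if (hi - lo < 2) stop_nosignal("upslope too short to analyze")
  lo:hi
}

# Indices of the full systolic pulse complex: the contiguous region
# around the global peak where the rise exceeds `frac` of the range,
# dilated by `dilate` samples each side.
pulse_indices <- function(q, frac = 0.10, dilate = 1L) {
  n <- length(q)
  ip <- which.max(q)
  if (ip < 3) stop_nosignal("no systolic pulse detectable")
  rise <- (q - min(q)) / (max(q) - min(q))
  below <- which(rise[seq_len(ip)] <= frac)
  lo <- if (length(below)) max(below) else 1L
  after <- which(rise <= frac & seq_len(n) > ip)
  hi <- if (length(after)) min(after) else n
  lo <- max(1L, lo - dilate); hi <- min(n, hi + dilate)
  if (hi - lo < 2) stop_nosignal("pulse region too short to analyze")
  lo:hi
}

#' Cross-wavelet phase transit-time estimate
#'
#' Estimates the delay between two flow-rate curves from the phase of
#' their cross-wavelet spectrum: both curves are mean-subtracted,
#' peak-normalized and transformed with an analytic Morlet wavelet
#' (center frequency parameter `omega0`, logarithmically spaced scales
#' spanning `f_band`). Within a time-frequency region restricted to the
#' systolic upslope of `q_a` (10--90% of the rise, dilated one sample)
#' and to scales where both transform amplitudes exceed a fraction
#' `scale_gate` of their in-window maxima, the per-cell cross phase is
#' converted to a delay by dividing by the local instantaneous angular
#' frequency of the reference transform (a central-difference phase
#' derivative; for a pure time shift the cross phase equals delay times
#' that local frequency, whereas the scale's nominal pseudo-frequency
#' is only a band-center approximation). Scales are processed from low
#' to high frequency: the coarsest scale fixes an unambiguous first
#' estimate and each finer scale's phase is unwrapped around the
#' running estimate, so delays beyond a fine scale's half-period are
#' still resolved. Cells are combined by inverse-variance weights
#' `omega^2 |cross|` — the phase noise of a cell converts to delay
#' noise as 1/omega, so high-frequency cells with signal energy carry
#' proportionally more timing information. Cells landing beyond
#' `max_delay` after unwrapping are discarded as unreliable. Because
#' the delay is read from phase, not from sample-grid alignment, the
#' estimate is not quantized at the sampling interval — the property
#' that makes the method usable at coarse acquisition resolutions.
#'
#' @param q_a,q_b flow-rate curves over one cardiac cycle (equal length,
#'   uniform sampling).
#' @param time_axis sample times, s.
#' @param max_delay largest admissible |delay|, s; defaults to a quarter
#'   cardiac period.
#' @param f_band pseudo-frequency band of the analysis, Hz.
#' @param n_scales number of wavelet scales.
#' @param omega0 Morlet center-frequency parameter.
#' @param scale_gate fraction of the in-window amplitude maximum a scale
#'   row must reach (in both transforms) to enter the average.
#' @return list with `delay` (s, positive when `q_b` lags `q_a`) and
#'   `quality` (retained fraction of cross-spectral amplitude, in
#'   \[0, 1\]).
#' @export
wavelet_delay <- function(q_a, q_b, time_axis, max_delay = NULL,
                          f_band = c(1, 12), n_scales = 32L, omega0 = 6,
                          scale_gate = 0.1) {
  dt <- validate_pair(q_a, q_b, time_axis)
  n <- length(q_a)
  period <- n * dt
  if (is.null(max_delay)) max_delay <- period / 4

  a <- q_a - mean(q_a); a <- a / max(abs(a))
  b <- q_b - mean(q_b); b <- b / max(abs(b))
  win <- upslope_indices(q_a)

  sc <- morlet_scales(f_band[1], f_band[2], n_scales, omega0)
  Wa <- morlet_cwt(a, dt, sc$scales, omega0)
  Wb <- morlet_cwt(b, dt, sc$scales, omega0)

  Aa <- Mod(Wa[, win, drop = FALSE])
  Ab <- Mod(Wb[, win, drop = FALSE])
  keep <- apply(Aa, 1, max) >= scale_gate * max(Aa) &
    apply(Ab, 1, max) >= scale_gate * max(Ab)
  if (!any(keep)) stop_lowquality("empty admissible time-frequency region")

  cross <- Wa[keep, win, drop = FALSE] * Conj(Wb[keep, win, drop = FALSE])
  # local instantaneous angular frequency of the reference transform,
  # from a wrap-safe central-difference phase derivative (periodic grid)
  Wk <- Wa[keep, , drop = FALSE]
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  omega <- Arg(Wk[, nxt, drop = FALSE] * Conj(Wk[, prv, drop = FALSE])) /
    (2 * dt)
  omega <- omega[, win, drop = FALSE]
  phase <- Arg(cross)
  wts <- Mod(cross) * pmax(omega, 0)^2     # inverse-variance weighting

  # coarse-to-fine unwrapping: scale rows ordered by increasing
  # frequency; the running estimate resolves each finer row's 2*pi
  # ambiguity before it joins the average
  ord <- order(sc$freqs[keep])
  d_hat <- NA_real_; w_acc <- 0; s_acc <- 0
  delays <- matrix(NA_real_, nrow(phase), ncol(phase))
  for (r in ord) {
    om <- omega[r, ]; ph <- phase[r, ]
    good <- is.finite(om) & om > 0
    if (!any(good)) next
    if (is.finite(d_hat)) {
      k <- round((om * d_hat - ph) / (2 * pi))
      ph <- ph + 2 * pi * k
    }
    d_row <- ph / om
    d_row[!good] <- NA_real_
    delays[r, ] <- d_row
    use <- good & abs(d_row) <= max_delay
    if (any(use)) {
      s_acc <- s_acc + sum(wts[r, use] * d_row[use])
      w_acc <- w_acc + sum(wts[r, use])
      d_hat <- s_acc / w_acc
    }
  }
  ok <- is.finite(delays) & abs(delays) <= max_delay
  if (!any(ok) || w_acc == 0) {
    stop_lowquality("all phase delays outside the admissible range")
  }
  quality <- min(1, max(0, sum(wts[ok]) / sum(wts[is.finite(delays)])))
  list(delay = d_hat, quality = quality, method = "wavelet")
}

# Foot of a waveform by the intersecting-tangent construction: baseline
# (mean of the lowest-decile band) intersected with the tangent at the
# point of maximal upslope before the systolic peak.
waveform_foot <- function(q, time_axis) {
  dt <- diff(time_axis)[1]
  ip <- which.max(q)
  if (ip < 3) stop_nosignal("no upslope detectable")
  baseline <- mean(q[q <= stats::quantile(q, 0.10)])
  dq <- diff(q[seq_len(ip)]) / dt
  im <- which.max(dq)                       # slope of segment im -> im+1
  slope <- dq[im]
  if (!is.finite(slope) || slope <= 0) stop_nosignal("no rising slope found")
  t_mid <- (time_axis[im] + time_axis[im + 1]) / 2
  q_mid <- (q[im] + q[im + 1]) / 2
  t_mid + (baseline - q_mid) / slope
}

#' Foot-to-foot transit-time estimate (intersecting tangents)
#'
#' Classical estimator: the foot of each curve is the intersection of its
#' diastolic baseline (mean of the lowest-decile band) with the tangent
#' at maximal systolic upslope; the delay is the difference of the two
#' foot times. Amplitude-invariant by construction.
#'
#' @inheritParams wavelet_delay
#' @return list with `delay` (s) and `quality` (fixed at 1 when both
#'   feet are detectable; the method has no graded confidence measure).
#' @export
foot_delay <- function(q_a, q_b, time_axis) {
  validate_pair(q_a, q_b, time_axis)
  fa <- waveform_foot(q_a, time_axis)
  fb <- waveform_foot(q_b, time_axis)
  list(delay = fb - fa, quality = 1, method = "foot")
}

#' Upslope cross-correlation transit-time estimate
#'
#' Normalized cross-correlation restricted to the systolic upslope of
#' `q_a`'s systolic complex. Both curves are first upsampled on their
#' periodic grid by exact trigonometric interpolation (factor
#' `upsample`), the correlation is maximized over lags within
#' `max_delay`, and the peak is refined below the fine grid by a
#' parabolic fit through the discrete maximum and its neighbors. The
#' conventional estimator for two-plane transit times. By default the
#' correlation template spans the full systolic pulse (upslope, peak
#' and downslope, where the rise exceeds 10% of the range), which is
#' markedly less noise-sensitive than the rising limb alone;
#' `window = "upslope"` restricts it to the classical 10--90% upslope
#' segment.
#'
#' @inheritParams wavelet_delay
#' @param min_peak minimum admissible correlation peak; below it a
#'   low-quality error is raised.
#' @param upsample integer trigonometric upsampling factor applied
#'   before correlation.
#' @param window correlation template: "pulse" (full systolic complex,
#'   default) or "upslope" (10--90% of the rise).
#' @return list with `delay` (s, positive when `q_b` lags `q_a`) and
#'   `quality` (the correlation peak height, clipped to \[0, 1\]).
#' @export
upslope_xcorr_delay <- function(q_a, q_b, time_axis, max_delay = NULL,
                                min_peak = 0.5, upsample = 8L,
                                window = c("pulse", "upslope")) {
  dt <- validate_pair(q_a, q_b, time_axis)
  window <- match.arg(window)
  n <- length(q_a)
  period <- n * dt
  if (is.null(max_delay)) max_delay <- period / 4

  U <- max(1L, as.integer(upsample))
  a <- upsample_periodic(q_a - mean(q_a), U)
  b <- upsample_periodic(q_b - mean(q_b), U)
  dtf <- dt / U
  nf <- length(a)
  win <- if (window == "pulse") pulse_indices(a, dilate = U) else
    upslope_indices(a, dilate = U)
  K <- max(1L, min(nf - 1L, floor(max_delay / dtf)))
  lags <- -K:K
  ncc <- vapply(lags, function(k) {
    idx <- ((win - 1 + k) %% nf) + 1         # circular indexing
    suppressWarnings(stats::cor(a[win], b[idx]))
  }, numeric(1))
  ncc[!is.finite(ncc)] <- -1
  ibest <- which.max(ncc)
  peak <- ncc[ibest]
  if (peak < min_peak) {
    stop_lowquality(sprintf("correlation peak %.2f below %.2f", peak, min_peak))
  }
  delta <- 0
  if (ibest > 1 && ibest < length(lags)) {
    c0 <- ncc[ibest]; cm <- ncc[ibest - 1]; cp <- ncc[ibest + 1]
    denom <- cm - 2 * c0 + cp
    if (denom < 0) delta <- 0.5 * (cm - cp) / denom
    delta <- max(-0.5, min(0.5, delta))
  }
  list(delay = (lags[ibest] + delta) * dtf,
       quality = min(1, max(0, peak)), method = "xcorr")
}

#' Transit times of all planes against a reference plane
#'
#' Computes, for every plane of a flow-curve set, the delay of the
#' reference plane's waveform relative to that plane (positive when the
#' plane is upstream of the reference). The reference defaults to the
#' most distal plane. Planes on which the estimator fails with a
#' low-quality or no-signal condition are marked missing rather than
#' aborting the subject; an error is raised only when more than half the
#' planes fail.
#'
#' @param curves a `flow_curve_set`.
#' @param method one of "wavelet", "xcorr", "foot".
#' @param reference index of the reference plane (default: last).
#' @param ... passed to the chosen estimator.
#' @return a `transit_time_result`: list with `reference_plane_index`,
#'   `delay` (s, `NA` where the estimator failed; exactly 0 at the
#'   reference), `quality`, `arc_lengths` (mm) and `method`.
#' @export
plane_delays <- function(curves, method = c("wavelet", "xcorr", "foot"),
                         reference = NULL, ...) {
  assert_that(inherits(curves, "flow_curve_set"), "curves invalid")
  method <- match.arg(method)
  n_planes <- nrow(curves$flow)
  assert_that(n_planes >= 2, "need at least 2 planes")
  if (is.null(reference)) reference <- n_planes
  assert_that(reference >= 1 && reference <= n_planes, "bad reference index")

  est <- switch(method, wavelet = wavelet_delay, xcorr = upslope_xcorr_delay,
                foot = foot_delay)
  q_ref <- curves$flow[reference, ]
  delay <- rep(NA_real_, n_planes)
  quality <- rep(NA_real_, n_planes)
  for (i in seq_len(n_planes)) {
    if (i == reference) { delay[i] <- 0; quality[i] <- 1; next }
    r <- tryCatch(est(curves$flow[i, ], q_ref, curves$time_axis, ...),
                  aortastiff_low_quality = function(e) NULL,
                  aortastiff_no_signal = function(e) NULL)
    if (!is.null(r)) { delay[i] <- r$delay; quality[i] <- r$quality }
  }
  if (mean(is.na(delay)) > 0.5) {
    stop(errorCondition("more than half the planes failed quality checks",
                        class = c("aortastiff_insufficient_data",
                                  "error", "condition")))
  }
  structure(list(reference_plane_index = reference, delay = delay,
                 quality = quality,
                 arc_lengths = curves$plane_arc_lengths, method = method),
            class = "transit_time_result")
}

#' @export
print.transit_time_result <- function(x, ...) {
  cat(sprintf("Transit times (%s): %d planes, reference %d, %d missing\n",
              x$method, length(x$delay), x$reference_plane_index,
              sum(is.na(x$delay))))
  invisible(x)
}
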