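# Continuous wavelet transform with an analytic Morlet wavelet,
# computed in the Fourier domain with circular (periodic) extension --
# appropriate for cardiac-cycle signals, which are cyclic by nature.
#
# Conventions follow the standard geophysical CWT formulation:
# psi_hat(s*w) = pi^(-1/4) * exp(-(s*w - omega0)^2 / 2) for w > 0,
# W(s, t) = ifft( fft(x) * Conj(psi_hat(s*w)) * sqrt(2*pi*s/dt) ).
# The Fourier factor converting scale to pseudo-frequency is
# lambda = 4*pi / (omega0 + sqrt(2 + omega0^2)).

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Scales spanning a pseudo-frequency band
#'
#' @param f_min,f_max pseudo-frequency band, Hz.
#' @param n_scales number of logarithmically spaced scales.
#' @param omega0 Morlet center-frequency parameter.
#' @return list with `scales` (s) and `freqs` (Hz), ordered from high to
#'   low frequency.
#' @keywords internal
morlet_scales <- function(f_min = 1, f_max = 12, n_scales = 32L, omega0 = 6) {
  lambda <- morlet_fourier_factor(omega0)
  freqs <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  list(scales = 1 / (lambda * freqs), freqs = freqs)
}

# Exact trigonometric upsampling of a periodic signal by integer factor
# U (Fourier zero-padding). Used for sub-sample correlation alignment.
upsample_periodic <- function(x, U) {
  n <- length(x)
  if (U <= 1) return(x)
  m <- n * U
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  if (n %% 2 == 0) {
    h <- n / 2
    Y[1:h] <- X[1:h]
    Y[h + 1] <- X[h + 1] / 2        # split the Nyquist bin symmetrically
    Y[m - h + 1] <- X[h + 1] / 2
    if (h >= 2) Y[(m - h + 2):m] <- X[(h + 2):n]
  } else {
    h <- (n - 1) / 2
    Y[1:(h + 1)] <- X[1:(h + 1)]
    Y[(m - h + 1):m] <- X[(h + 2):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Continuous wavelet transform (analytic Morlet, periodic extension)
#'
#' @param x real signal, uniformly sampled over one cycle.
#' @param dt sample interval, s.
#' @param scales wavelet scales, s (see [morlet_scales()]).
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @return complex matrix, one row per scale, one column per time sample.
#' @keywords internal
morlet_cwt <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  fx <- stats::fft(x)
  w <- 2 * pi * seq(0, n - 1) / (n * dt)
  # analytic wavelet: support on positive frequencies only
  w[w > pi / dt] <- 0   # fold-over bins carry negative frequencies
  pos <- w > 0
  out <- matrix(complex(real = 0), length(scales), n)
  norm4 <- pi^(-1 / 4)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi <- numeric(n)
    psi[pos] <- norm4 * exp(-(s * w[pos] - omega0)^2 / 2)
    out[k, ] <- stats::fft(fx * psi * sqrt(2 * pi * s / dt),
                           inverse = TRUE) / n
  }
  out
}
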