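#' @keywords internal
"_PACKAGE"

# Internal validation helper: stop with a consistent error class so callers
# (and tests) can distinguish argument errors from numerical failures.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("aortastiff_invalid_argument",
                                             "error", "condition")))
}

stop_nosignal <- function(...) {
  stop(errorCondition(paste0(...), class = c("aortastiff_no_signal",
                                             "error", "condition")))
}

stop_lowquality <- function(...) {
  stop(errorCondition(paste0(...), class = c("aortastiff_low_quality",
                                             "error", "condition")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

#' Project a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Used to
#' repair copula correlation matrices assembled from independently
#' calibrated pairs.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param eps smallest admissible eigenvalue after clipping.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_psd_corr <- function(m, eps = 1e-8) {
  assert_that(is.matrix(m) && nrow(m) == ncol(m), "m must be square")
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

# Linear interpolation with periodic wrap over one cardiac cycle: the
# sample grid covers [0, period) and the curve is treated as cyclic.
periodic_approx <- function(x, y, xout, period) {
  xx <- c(x, x[1] + period)
  yy <- c(y, y[1])
  stats::approx(xx, yy, xout = xout %% period, rule = 2)$y
}

# Derive a reproducible child seed (kept inside 32-bit integer range).
child_seed <- function(root_seed, k) {
  as.integer((as.numeric(root_seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}
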