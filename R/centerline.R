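#' Synthetic aortic centerline
#'
#' Builds a smooth "candy-cane" shaped 3D curve emulating the thoracic and
#' proximal abdominal aorta: an ascending limb, an arch, and a descending
#' limb, with a slight out-of-plane bow. Eight anatomical landmarks
#' (aortic valve through coeliac trunk) are placed at fixed fractions of
#' the total arc length; only their ordering matters downstream, where
#' they select measurement planes.
#'
#' @param total_length target arc length of the curve, in mm. Must lie in
#'   the physiological range 200--450 mm.
#' @param n_points number of points along the curve (>= 16).
#' @param seed integer seed controlling the small random shape
#'   perturbation; identical seeds give identical curves.
#' @return an object of class `aortic_centerline`: a list with `points`
#'   (`n_points` x 3 matrix, mm), `cumulative_arc_length` (mm, starting at
#'   0) and `landmarks` (named integer vector of point indices).
#' @examples
#' cl <- make_centerline(300, 200, seed = 1)
#' range(cl$cumulative_arc_length)
#' @export
make_centerline <- function(total_length = 300, n_points = 200L, seed = 1L) {
  assert_that(is.numeric(total_length) && length(total_length) == 1 &&
                total_length >= 200 && total_length <= 450,
              "total_length must be a single value in [200, 450] mm")
  assert_that(is.numeric(n_points) && n_points >= 16,
              "n_points must be >= 16")
  n_points <- as.integer(n_points)

  set.seed(as.integer(seed))
  # Shape template: parameter u in [0,1]; arch opening angle ~200 degrees
  # so the descending limb runs past the diaphragm. Unit-scale curve,
  # rescaled to the requested arc length afterwards.
  u <- seq(0, 1, length.out = 8L * n_points)
  arch_frac <- 0.45                      # fraction of u spent in the arch
  r_arch <- 0.35                         # arch radius, unit scale
  jitter <- stats::rnorm(3, 0, 0.01)     # seed-controlled shape variation

  theta <- pmin(u / arch_frac, 1) * pi   # 0..pi across the arch
  # ascending limb -> arch: semicircle in the x-z plane
  x <- r_arch * sin(theta)
  z <- r_arch * (1 - cos(theta))
  # descending limb: straight continuation downwards (negative x side)
  desc <- pmax(u - arch_frac, 0) / (1 - arch_frac)
  z <- z - desc * (2 * r_arch + 0.9 + jitter[1])
  z <- z - 2 * r_arch                    # valve at z ~ 0, descending below
  z <- -z                                # z decreases toward coeliac trunk
  # gentle out-of-plane bow (aorta is not planar)
  y <- (0.06 + jitter[2]) * sin(pi * u) + (0.03 + jitter[3]) * sin(2 * pi * u)

  pts <- cbind(x = x, y = y, z = -z)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  pts <- pts * (total_length / s[length(s)])
  s <- s * (total_length / s[length(s)])

  # resample to n_points uniformly in arc length
  s_out <- seq(0, total_length, length.out = n_points)
  pts_out <- apply(pts, 2, function(col) stats::approx(s, col, xout = s_out)$y)
  seg_out <- sqrt(rowSums(diff(pts_out)^2))
  arc <- c(0, cumsum(seg_out))

  fr <- landmark_fractions()
  idx <- vapply(fr, function(f) which.min(abs(arc - f * arc[n_points])), 1L)
  # enforce strict ordering even for coarse n_points
  for (i in seq_along(idx)[-1]) if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + 1L
  idx[idx > n_points] <- n_points

  structure(list(points = pts_out,
                 cumulative_arc_length = arc,
                 landmarks = idx),
            class = "aortic_centerline")
}

#' Landmark positions as fractions of total arc length
#'
#' Fixed fractional positions of the 8 anatomical landmarks used to place
#' measurement planes, from the aortic valve (0) to the coeliac trunk (1).
#'
#' @return named numeric vector of arc-length fractions.
#' @export
landmark_fractions <- function() {
  c(aortic_valve = 0,
    sinotubular_junction = 0.04,
    ascending_at_2D_slice = 0.18,
    brachiocephalic_bifurcation = 0.30,
    isthmus = 0.42,
    descending_at_2D_slice = 0.55,
    diaphragmatic_aorta = 0.80,
    coeliac_trunk = 1.0)
}

#' @export
print.aortic_centerline <- function(x, ...) {
  cat("Aortic centerline:", nrow(x$points), "points,",
      sprintf("%.1f mm arc length\n", max(x$cumulative_arc_length)))
  cat("Landmarks (mm):\n")
  print(round(x$cumulative_arc_length[x$landmarks], 1))
  invisible(x)
}

#' Arc length between two named landmarks
#'
#' @param centerline an `aortic_centerline`.
#' @param from,to landmark names (see [landmark_fractions()]).
#' @return distance along the centerline in mm.
#' @export
landmark_distance <- function(centerline, from, to) {
  lm <- centerline$landmarks
  assert_that(all(c(from, to) %in% names(lm)), "unknown landmark name")
  abs(centerline$cumulative_arc_length[lm[[to]]] -
        centerline$cumulative_arc_length[lm[[from]]])
}
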