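#' Draw a cohort of subjects with ground-truth stiffness values
#'
#' Per subject, a within-group Gaussian-copula vector is mapped through
#' the group-specific marginal laws: normal quantiles for the three PWVs,
#' log-normal for distensibility. Auxiliary variables (pressures, heart
#' rate, covariates) are drawn independently of the stiffness vector.
#' Group sizes are fixed at the spec's `n_patients` / `n_controls` by
#' default; with `by_proportion = TRUE` each subject's group is an
#' independent Bernoulli draw at `proportion_patients` instead.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical (spec, seed) give identical
#'   cohorts.
#' @param n total cohort size when `by_proportion = TRUE`; ignored
#'   otherwise.
#' @param by_proportion draw group labels by proportion instead of using
#'   fixed group sizes.
#' @return data.frame, one row per subject: `id`, `group`
#'   (factor CAD/control), the four ground-truth stiffness values
#'   (`cf_PWV`, `PWV_2D`, `PWV_4D` in m/s; `distensibility` in
#'   1e-3/mmHg), `central_SBP`, `central_DBP`, `PP` (mmHg),
#'   `heart_rate` (bpm), `age` (y), `LVMi` (g/m^2),
#'   `infarcted_segments` (0 for controls). The root seed is stored in
#'   `attr(, "seed")`.
#' @export
draw_cohort <- function(spec, seed = 1L, n = NULL, by_proportion = FALSE) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(as.integer(seed))
  if (by_proportion) {
    assert_that(!is.null(n) && n >= 4, "n required when drawing by proportion")
    group <- ifelse(stats::runif(n) < spec$proportion_patients,
                    "CAD", "control")
  } else {
    group <- c(rep("CAD", spec$n_patients), rep("control", spec$n_controls))
  }
  n <- length(group)
  R <- chol(nearest_psd_corr(spec$copula))
  Z <- matrix(stats::rnorm(n * 4), n, 4) %*% R
  U <- stats::pnorm(Z)

  vals <- matrix(NA_real_, n, 4, dimnames = list(NULL, spec$measures))
  for (g in c("CAD", "control")) {
    rows <- group == g
    if (!any(rows)) next
    for (j in seq_along(spec$measures)) {
      vals[rows, j] <- marginal_quantile(U[rows, j],
                                         spec$marginals[[g]][[spec$measures[j]]])
    }
  }

  draw_aux <- function(field) {
    out <- numeric(n)
    for (g in c("CAD", "control")) {
      rows <- group == g
      if (any(rows)) {
        out[rows] <- marginal_quantile(stats::runif(sum(rows)),
                                       spec$aux[[g]][[field]])
      }
    }
    out
  }
  sbp <- draw_aux("central_SBP")
  dbp <- draw_aux("central_DBP")
  # keep the pulse pressure physiological (PP >= 10 mmHg)
  dbp <- pmin(dbp, sbp - 10)
  hr <- draw_aux("heart_rate")
  age <- draw_aux("age")
  lvmi <- draw_aux("LVMi")
  seg <- integer(n)
  lam <- spec$aux$CAD$infarct_lambda
  if (lam > 0 && any(group == "CAD")) {
    seg[group == "CAD"] <- 1L + stats::rpois(sum(group == "CAD"), lam - 1)
  }

  out <- data.frame(id = sprintf("S%03d", seq_len(n)),
                    group = factor(group, levels = c("CAD", "control")),
                    cf_PWV = vals[, "cf_PWV"],
                    PWV_2D = vals[, "PWV_2D"],
                    PWV_4D = vals[, "PWV_4D"],
                    distensibility = vals[, "distensibility"],
                    central_SBP = sbp, central_DBP = dbp, PP = sbp - dbp,
                    heart_rate = hr, age = age, LVMi = lvmi,
                    infarcted_segments = seg,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Extract one subject's ground truth as a list
#'
#' @param cohort a [draw_cohort()] data.frame.
#' @param i row index.
#' @return a `subject_truth` list with `group`, `true_PWV` (the aortic
#'   PWV driving waveform propagation, taken from the multi-plane PWV
#'   marginal), `true_cf_PWV`, `true_distensibility`, `pressure`,
#'   `heart_rate` and covariates.
#' @export
subject_truth <- function(cohort, i) {
  r <- cohort[i, ]
  structure(list(group = as.character(r$group),
                 true_PWV = r$PWV_4D,
                 true_cf_PWV = r$cf_PWV,
                 true_2D_PWV = r$PWV_2D,
                 true_distensibility = r$distensibility,
                 pressure = pressure_record(r$central_SBP, r$central_DBP),
                 heart_rate = r$heart_rate,
                 covariates = list(age = r$age, LVMi = r$LVMi,
                                   infarcted_segments = r$infarcted_segments)),
            class = "subject_truth")
}

# Pooled Spearman correlation between two measures under the two-group
# mixture, as a function of the shared within-group copula correlation r.
# Uses common random numbers (fixed z1, z2, group labels) so the map
# r -> rho is smooth and monotone, the basis for bisection.
pooled_spearman_at <- function(r, z1, z2, group, m1, m2) {
  x2 <- r * z1 + sqrt(1 - r^2) * z2
  v1 <- numeric(length(z1)); v2 <- numeric(length(z1))
  for (g in c("CAD", "control")) {
    rows <- group == g
    v1[rows] <- marginal_quantile(stats::pnorm(z1[rows]), m1[[g]])
    v2[rows] <- marginal_quantile(stats::pnorm(x2[rows]), m2[[g]])
  }
  stats::cor(v1, v2, method = "spearman")
}

#' Calibrate the within-group copula against pooled correlation targets
#'
#' The printed cross-method correlations of a case-control study are
#' pooled over both groups, so they mix the within-group association with
#' the between-group mean separation. For each targeted measure pair this
#' routine finds, by monotone bisection, the scalar within-group copula
#' correlation under which the Monte-Carlo pooled Spearman correlation
#' (groups mixed at the spec's 35:18 proportions) matches the target.
#' Pairs with an `NA` target keep within-group correlation 0. The
#' assembled matrix is projected to the nearest positive semi-definite
#' correlation matrix if needed.
#'
#' @param spec a [cohort_spec()].
#' @param target_pooled_spearman 4x4 matrix of pooled Spearman targets in
#'   (-1, 1), `NA` off-diagonals left uncalibrated; see
#'   [default_pooled_targets()].
#' @param n_mc Monte-Carlo sample size per bisection evaluation (>= 1e4).
#' @param tol absolute tolerance on the pooled correlation.
#' @param seed integer seed for the common-random-number draws.
#' @return the calibrated 4x4 within-group copula correlation matrix.
#' @export
calibrate_copula <- function(spec, target_pooled_spearman = default_pooled_targets(),
                             n_mc = 2e4, tol = 0.005, seed = 1L) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  tg <- as.matrix(target_pooled_spearman)
  assert_that(all(dim(tg) == c(4, 4)), "targets must be 4x4")
  off <- tg[row(tg) != col(tg)]
  assert_that(all(abs(off[!is.na(off)]) < 1),
              "targets must be in (-1, 1)")
  assert_that(n_mc >= 1e4, "n_mc must be >= 1e4")

  set.seed(as.integer(seed))
  n_pat <- round(spec$proportion_patients * n_mc)
  group <- c(rep("CAD", n_pat), rep("control", n_mc - n_pat))
  cop <- diag(4)
  dimnames(cop) <- dimnames(spec$copula)
  for (i in 1:3) for (j in (i + 1):4) {
    target <- tg[i, j]
    if (is.na(target)) next
    z1 <- stats::rnorm(n_mc); z2 <- stats::rnorm(n_mc)
    m1 <- list(CAD = spec$marginals$CAD[[spec$measures[i]]],
               control = spec$marginals$control[[spec$measures[i]]])
    m2 <- list(CAD = spec$marginals$CAD[[spec$measures[j]]],
               control = spec$marginals$control[[spec$measures[j]]])
    f <- function(r) pooled_spearman_at(r, z1, z2, group, m1, m2)
    lo <- -0.999; hi <- 0.999
    f_lo <- f(lo); f_hi <- f(hi)
    if (target < f_lo - tol || target > f_hi + tol) {
      stop(errorCondition(
        sprintf("pooled correlation target %.3f for (%s, %s) unreachable; attainable range [%.3f, %.3f]",
                target, spec$measures[i], spec$measures[j], f_lo, f_hi),
        class = c("aortastiff_calibration_failure", "error", "condition")))
    }
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target) <= tol) break
      if (fm < target) lo <- mid else hi <- mid
    }
    cop[i, j] <- cop[j, i] <- mid
  }
  nearest_psd_corr(cop)
}

#' Default pooled Spearman correlation targets
#'
#' Published pooled cross-method correlations of the multi-plane 4D PWV
#' with the other three stiffness measures: 0.66 with carotid-femoral
#' PWV, 0.51 with two-plane PWV, -0.33 with distensibility. Pairs not
#' reported are left `NA` (uncalibrated).
#'
#' @return 4x4 matrix (measure order cf_PWV, PWV_2D, PWV_4D,
#'   distensibility).
#' @export
default_pooled_targets <- function() {
  m <- matrix(NA_real_, 4, 4,
              dimnames = list(c("cf_PWV", "PWV_2D", "PWV_4D", "distensibility"),
                              c("cf_PWV", "PWV_2D", "PWV_4D", "distensibility")))
  diag(m) <- 1
  m["PWV_4D", "cf_PWV"] <- m["cf_PWV", "PWV_4D"] <- 0.66
  m["PWV_4D", "PWV_2D"] <- m["PWV_2D", "PWV_4D"] <- 0.51
  m["PWV_4D", "distensibility"] <- m["distensibility", "PWV_4D"] <- -0.33
  m
}
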