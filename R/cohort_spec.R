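#' Log-normal parameters from a printed median and quartiles
#'
#' Clinical tables report skewed measures as median \[IQR\]. A log-normal
#' is matched so that its median equals the printed median exactly and
#' its inter-quartile width equals the printed width:
#' `mu = log(median)`, and `sigma` solves
#' `2 * median * sinh(z75 * sigma) = q75 - q25` with `z75 = qnorm(0.75)`.
#'
#' @param median printed median (> 0).
#' @param q25,q75 printed quartiles.
#' @return list with `meanlog` and `sdlog` for [stats::qlnorm()].
#' @export
lognormal_from_quartiles <- function(median, q25, q75) {
  assert_that(median > 0 && q75 > q25 && q25 > 0,
              "need median > 0 and q75 > q25 > 0")
  z75 <- stats::qnorm(0.75)
  list(meanlog = log(median),
       sdlog = asinh((q75 - q25) / (2 * median)) / z75)
}

marginal_normal <- function(mean, sd) {
  assert_that(sd > 0, "marginal SD must be > 0")
  list(type = "normal", mean = mean, sd = sd)
}

marginal_lognormal <- function(median, q25, q75) {
  p <- lognormal_from_quartiles(median, q25, q75)
  list(type = "lognormal", meanlog = p$meanlog, sdlog = p$sdlog,
       median = median, q25 = q25, q75 = q75)
}

marginal_quantile <- function(u, m) {
  switch(m$type,
         normal = stats::qnorm(u, m$mean, m$sd),
         lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
         stop_invalid("unknown marginal type: ", m$type))
}

#' Case-control cohort specification
#'
#' Generative model for a two-group arterial-stiffness cohort: per-group
#' marginal laws for the four stiffness measures (normal for the three
#' PWVs, log-normal for distensibility), a within-group Gaussian-copula
#' correlation matrix shared by both groups, group sizes, and auxiliary
#' marginals (pressures, heart rate, covariates). Defaults reproduce the
#' printed group distributions of a 35-patient / 18-control coronary
#' artery disease case-control study.
#'
#' @param n_patients,n_controls group sizes (>= 2).
#' @param patients,controls named lists of marginals for `cf_PWV`,
#'   `PWV_2D`, `PWV_4D` (m/s, normal) and `distensibility`
#'   (1e-3/mmHg, log-normal).
#' @param copula 4x4 within-group copula correlation matrix (measure
#'   order cf_PWV, PWV_2D, PWV_4D, distensibility); must be symmetric,
#'   unit-diagonal, positive semi-definite.
#' @param aux per-group auxiliary marginals (pressures, heart rate, age,
#'   left-ventricular mass index); see defaults.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 35L, n_controls = 18L,
                        patients = list(
                          cf_PWV = marginal_normal(12.67, 2.86),
                          PWV_2D = marginal_normal(10.97, 3.43),
                          PWV_4D = marginal_normal(17.3, 4.04),
                          distensibility = marginal_lognormal(1.71, 1.19, 2.17)),
                        controls = list(
                          cf_PWV = marginal_normal(9.58, 1.13),
                          PWV_2D = marginal_normal(8.01, 2.05),
                          PWV_4D = marginal_normal(8.69, 2.54),
                          distensibility = marginal_lognormal(1.77, 1.46, 2.70)),
                        copula = diag(4),
                        aux = default_aux_marginals()) {
  measures <- c("cf_PWV", "PWV_2D", "PWV_4D", "distensibility")
  assert_that(n_patients >= 2 && n_controls >= 2, "group sizes must be >= 2")
  assert_that(all(measures %in% names(patients)) &&
                all(measures %in% names(controls)),
              "marginals must cover all four stiffness measures")
  copula <- as.matrix(copula)
  assert_that(all(dim(copula) == c(4, 4)), "copula must be 4x4")
  assert_that(max(abs(copula - t(copula))) < 1e-8 &&
                max(abs(diag(copula) - 1)) < 1e-8,
              "copula must be symmetric with unit diagonal")
  ev <- eigen(copula, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "copula must be positive semi-definite")
  dimnames(copula) <- list(measures, measures)
  structure(list(measures = measures,
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 proportion_patients = n_patients / (n_patients + n_controls),
                 marginals = list(CAD = patients[measures],
                                  control = controls[measures]),
                 copula = copula, aux = aux),
            class = "cohort_spec")
}

#' Default auxiliary marginals (pressures, heart rate, covariates)
#'
#' Central pressures and heart rate feed the distensibility generator and
#' the waveform simulator; age and left-ventricular mass index are
#' carried as covariates for the correlation tables.
#'
#' @return per-group named list of marginals.
#' @export
default_aux_marginals <- function() {
  list(CAD = list(central_SBP = marginal_normal(118, 12.5),
                  central_DBP = marginal_normal(81.0, 10.6),
                  heart_rate = marginal_normal(61.1, 8.8),
                  age = marginal_normal(64.3, 11.7),
                  LVMi = marginal_lognormal(66.5, 58.1, 78.9),
                  infarct_lambda = 3),
       control = list(central_SBP = marginal_normal(116, 9.7),
                      central_DBP = marginal_normal(82.9, 7.2),
                      heart_rate = marginal_normal(67.3, 7.1),
                      age = marginal_normal(62.0, 10.1),
                      LVMi = marginal_lognormal(57.8, 52.11, 61.25),
                      infarct_lambda = 0))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec:", x$n_patients, "patients /", x$n_controls, "controls\n")
  for (g in names(x$marginals)) {
    m <- x$marginals[[g]]
    cat(sprintf("  %s: 4D PWV %.2f+/-%.2f m/s, cf %.2f+/-%.2f, 2D %.2f+/-%.2f, D median %.2f\n",
                g, m$PWV_4D$mean, m$PWV_4D$sd, m$cf_PWV$mean, m$cf_PWV$sd,
                m$PWV_2D$mean, m$PWV_2D$sd, m$distensibility$median))
  }
  invisible(x)
}
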