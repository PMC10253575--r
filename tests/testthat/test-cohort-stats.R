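test_that("identical groups give t = 0, p = 1", {
  set.seed(1)
  x <- stats::rnorm(10, 10, 1)
  cmp <- compare_groups(x, x, measure = "pwv")
  expect_identical(cmp$test, "t")
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)
})

test_that("the normality gate switches to the rank-sum test", {
  set.seed(2)
  x <- stats::rlnorm(40, 0, 1.5)^2     # heavily skewed
  y <- stats::rlnorm(40, 0.5, 1.5)^2
  cmp <- compare_groups(x, y)
  expect_identical(cmp$test, "wilcoxon")
  expect_match(cmp$summary[1], "\\[")   # median [IQR] formatting
})

test_that("Fisher test on the published sex table gives p = 1", {
  cmp <- compare_groups(matrix(c(32, 16, 3, 2), 2, 2), kind = "categorical",
                        measure = "sex")
  expect_identical(cmp$test, "fisher")
  expect_equal(cmp$p_value, 1, tolerance = 1e-3)
})

test_that("small-sample p-values match exhaustive enumeration oracles", {
  set.seed(3)
  for (rep in 1:5) {
    x <- round(stats::rnorm(7, 10, 2), 2)
    y <- round(stats::rnorm(8, 12, 2), 2)
    p_pkg <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lt(abs(p_pkg - oracle_ranksum_p(x, y)), 0.01)
  }
  for (tab in list(matrix(c(32, 16, 3, 2), 2, 2),
                   matrix(c(5, 1, 2, 7), 2, 2),
                   matrix(c(8, 2, 1, 6), 2, 2))) {
    cmp <- compare_groups(tab, kind = "categorical")
    expect_equal(cmp$p_value, oracle_fisher_p(tab), tolerance = 1e-7)
  }
})

test_that("degenerate constant groups are reported without a test", {
  cmp <- compare_groups(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_identical(cmp$test, "none")
  expect_true(is.na(cmp$p_value))
})

test_that("Spearman correlation is monotone-invariant with exact extremes", {
  x <- c(-2, -1, 0, 1, 2, 3)
  cm <- correlation_matrix(data.frame(x = x, y = exp(x)))
  expect_equal(cm$rho["x", "y"], 1, tolerance = 1e-12)
  cm2 <- correlation_matrix(data.frame(x = x, y = -x))
  expect_equal(cm2$rho["x", "y"], -1, tolerance = 1e-12)

  # printed toy vectors against the rank-formula value 1 - 6*sum(d^2)/(n(n^2-1))
  x6 <- 1:6; y6 <- c(2, 1, 4, 3, 6, 5)
  d2 <- sum((rank(x6) - rank(y6))^2)
  expect_equal(unname(correlation_matrix(data.frame(x6, y6))$rho[1, 2]),
               1 - 6 * d2 / (6 * 35), tolerance = 1e-12)
})

test_that("correlation matrix handles missing values pairwise and flags ties", {
  df <- data.frame(a = c(1, 2, 3, 4, 5, NA), b = c(2, 1, 4, 3, 6, 5),
                   c = rep(7, 6))
  cm <- correlation_matrix(df)
  expect_false(is.na(cm$rho["a", "b"]))
  expect_true(is.na(cm$rho["a", "c"]))     # undefined for an all-tied vector
  expect_identical(diag(cm$rho), c(a = 1, b = 1, c = 1))
  expect_equal(cm$rho, t(cm$rho))
})

test_that("perfect separation yields AUC 1 and a perfect operating point", {
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$AUC, 1, tolerance = 1e-12)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_true(r$threshold > 3 && r$threshold <= 11)
})

test_that("overlapping classes give the concordance-count AUC", {
  # pairs: (1.5,1) +, (1.5,2) -, (3,1) +, (3,2) + -> 3/4
  r <- roc_analysis(c(1, 2, 1.5, 3), c(0, 0, 1, 1))
  expect_equal(r$AUC, 0.75, tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(9)
  sc <- stats::rnorm(4000)
  lb <- rep(c(0, 1), 2000)
  expect_equal(roc_analysis(sc, lb)$AUC, 0.5, tolerance = 0.04)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(10)
  sc <- stats::rnorm(60)
  lb <- stats::rbinom(60, 1, 0.4)
  a1 <- roc_analysis(sc, lb)$AUC
  a2 <- roc_analysis(exp(sc), lb)$AUC
  a3 <- roc_analysis(stats::qlogis(stats::pnorm(sc)), lb)$AUC
  expect_identical(a1, a2)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("trapezoidal AUC equals tie-corrected Mann-Whitney on random instances", {
  set.seed(12)
  for (i in 1:200) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    # integer scores force ties
    pos <- sample(0:8, n1, replace = TRUE)
    neg <- sample(0:8, n0, replace = TRUE)
    a_pkg <- roc_analysis(c(pos, neg), rep(c(1, 0), c(n1, n0)))$AUC
    expect_equal(a_pkg, oracle_trapezoid_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(14)
  for (i in 1:10) {
    sc <- round(stats::rnorm(40), 1)          # ties included
    lb <- stats::rbinom(40, 1, 0.5)
    if (sum(lb) %in% c(0, 40)) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_analysis(sc, lb)$AUC, ref, tolerance = 1e-12)
  }
})

test_that("Youden ties break toward the lower (more sensitive) threshold", {
  # two thresholds attain the maximal J: choose the lower one
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))
  curve <- r$curve
  best_j <- max(curve$J)
  expect_equal(r$threshold, min(curve$threshold[curve$J == best_j]))
  expect_equal(r$sensitivity + r$specificity - 100, 100 * best_j,
               tolerance = 1e-9)
})

test_that("single-class input is refused", {
  expect_error(roc_analysis(1:5, rep(1, 5)),
               class = "aortastiff_invalid_argument")
})

test_that("the study report assembles comparisons, ROC and correlations", {
  spec <- cohort_spec(copula = calibrate_copula(cohort_spec(), seed = 3))
  co <- simulate_cohort(spec, seed = 77, mode = "A")
  rep1 <- study_report(data.frame(group = co$group, cf_PWV = co$meas_cf_PWV,
                                  PWV_2D = co$meas_PWV_2D,
                                  PWV_4D = co$meas_PWV_4D,
                                  distensibility = co$meas_distensibility,
                                  age = co$age, LVMi = co$LVMi,
                                  infarcted_segments = co$infarcted_segments))
  expect_s3_class(rep1, "study_report")
  expect_named(rep1$roc, c("cf_PWV", "PWV_2D", "PWV_4D", "distensibility"))
  expect_true(all(vapply(rep1$roc, function(r) r$AUC, 1) >= 0))
  expect_identical(rep1$n_patients, 35L)
  out <- utils::capture.output(print(rep1))
  expect_true(any(grepl("ROC", out)))

  empty <- data.frame(group = factor(rep("CAD", 5), c("CAD", "control")),
                      cf_PWV = 1:5, PWV_2D = 1:5, PWV_4D = 1:5,
                      distensibility = 1:5)
  expect_error(study_report(empty), class = "aortastiff_invalid_argument")
})

test_that("replicate cf PWV AUC matches the binormal oracle", {
  oracle <- oracle_binormal_auc(12.67, 2.86, 9.58, 1.13)
  expect_equal(oracle, 0.84, tolerance = 0.01)
  spec <- cohort_spec()
  aucs <- vapply(1:300, function(s) {
    co <- draw_cohort(spec, seed = 5000 + s)
    roc_analysis(co$cf_PWV, co$group == "CAD")$AUC
  }, numeric(1))
  expect_gt(mean(aucs), 0.80)
  expect_lt(mean(aucs), 0.90)
})
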