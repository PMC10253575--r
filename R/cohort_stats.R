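# Case-control statistical machinery: normality-gated two-group
# comparisons, cross-method correlation matrix, ROC analysis with the
# Youden-optimal threshold, and report assembly.

#' Compare one measure between two groups
#'
#' Continuous measures: Shapiro-Wilk normality is tested in each group
#' at `alpha`; if both groups are compatible with normality an unpaired
#' t-test is used and the summary is mean +/- SD, otherwise a Wilcoxon
#' rank-sum test with median \[IQR\] summaries. Categorical measures
#' (2x2 counts) use Fisher's exact test.
#'
#' @param x,y values in group 1 (cases) and group 2 (controls), or for
#'   `kind = "categorical"` a 2x2 count matrix passed as `x` (`y`
#'   ignored).
#' @param kind "continuous" or "categorical".
#' @param measure label carried into the result.
#' @param alpha normality-gate significance level.
#' @return a `group_comparison`: list with `measure`, `test`
#'   ("t" | "wilcoxon" | "fisher" | "none"), per-group `summary`
#'   strings, `p_value`, and the raw group statistics.
#' @export
compare_groups <- function(x, y = NULL, kind = c("continuous", "categorical"),
                           measure = "measure", alpha = 0.05) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    tab <- as.matrix(x)
    assert_that(all(dim(tab) == c(2, 2)), "categorical input must be 2x2 counts")
    ft <- stats::fisher.test(tab)
    return(structure(list(measure = measure, test = "fisher",
                          summary = apply(tab, 2, paste, collapse = "/"),
                          p_value = ft$p.value, table = tab),
                     class = "group_comparison"))
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  assert_that(length(x) >= 3 && length(y) >= 3,
              "need >= 3 values per group")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(measure = measure, test = "none",
                          summary = c(sprintf("%.2f (constant)", mean(x)),
                                      sprintf("%.2f (constant)", mean(y))),
                          p_value = NA_real_),
                     class = "group_comparison"))
  }
  normal <- stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    summ <- c(sprintf("%.2f ± %.2f", mean(x), stats::sd(x)),
              sprintf("%.2f ± %.2f", mean(y), stats::sd(y)))
    test <- "t"; p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    qx <- stats::quantile(x, c(0.25, 0.5, 0.75))
    qy <- stats::quantile(y, c(0.25, 0.5, 0.75))
    summ <- c(sprintf("%.2f [%.2f-%.2f]", qx[2], qx[1], qx[3]),
              sprintf("%.2f [%.2f-%.2f]", qy[2], qy[1], qy[3]))
    test <- "wilcoxon"; p <- wt$p.value
  }
  structure(list(measure = measure, test = test, summary = summ,
                 p_value = p,
                 group1 = list(n = length(x), mean = mean(x), sd = stats::sd(x),
                               median = stats::median(x)),
                 group2 = list(n = length(y), mean = mean(y), sd = stats::sd(y),
                               median = stats::median(y))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s (%s test, p = %.4g)\n", x$measure,
              x$summary[1], x$summary[2], x$test, x$p_value))
  invisible(x)
}

#' Cross-method correlation matrix
#'
#' Pairwise correlations across a panel of measures with
#' pairwise-complete handling of missing values. Spearman's rho is the
#' default for stiffness panels (rank-based, monotone-invariant);
#' with `gate_normality = TRUE`, Pearson's r is used for pairs whose
#' two margins both pass Shapiro-Wilk normality at `alpha`.
#'
#' @param panel data.frame of numeric columns.
#' @param method "spearman" or "pearson".
#' @param gate_normality choose Pearson vs Spearman per pair by
#'   normality of both margins.
#' @param alpha normality-gate level.
#' @return a `correlation_matrix`: list with `rho` (coefficients,
#'   `NA` where undefined), `p` (p-values), `method` (per-cell label).
#' @export
correlation_matrix <- function(panel, method = c("spearman", "pearson"),
                               gate_normality = FALSE, alpha = 0.05) {
  method <- match.arg(method)
  panel <- as.data.frame(panel)
  k <- ncol(panel)
  assert_that(k >= 2, "panel needs >= 2 columns")
  rho <- matrix(NA_real_, k, k, dimnames = list(names(panel), names(panel)))
  pm <- rho
  mm <- matrix(NA_character_, k, k, dimnames = dimnames(rho))
  diag(rho) <- 1
  normal_col <- vapply(panel, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 3 && stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > alpha
  }, logical(1))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(panel[[i]], panel[[j]])
    if (sum(ok) < 4) next
    x <- panel[[i]][ok]; y <- panel[[j]][ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next   # undefined: all tied
    use <- if (gate_normality && normal_col[i] && normal_col[j]) {
      "pearson"
    } else method
    ct <- suppressWarnings(stats::cor.test(x, y, method = use, exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pm[i, j] <- pm[j, i] <- ct$p.value
    mm[i, j] <- mm[j, i] <- use
  }
  structure(list(rho = rho, p = pm, method = mm),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Correlation matrix:\n")
  print(round(x$rho, 2))
  invisible(x)
}

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC over all observed score values: AUC by the trapezoidal
#' rule (equal to the tie-corrected Mann-Whitney statistic U/(n1*n2)),
#' and the operating point maximizing the Youden index
#' J = sensitivity + specificity - 1. Thresholds are placed at observed
#' score values, with the decision rule `score >= threshold` calling a
#' case; ties in J are broken toward the lower threshold (the more
#' sensitive rule). Assumes cases score higher than controls on
#' average.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector, TRUE/1 = case.
#' @return a `roc_result`: list with `AUC`, `threshold`, `sensitivity`
#'   and `specificity` (percent), and `curve` (data.frame of threshold,
#'   sensitivity, specificity, J).
#' @export
roc_analysis <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  assert_that(any(labels) && any(!labels),
              "both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  ibest <- which(j == max(j))[1]           # lowest threshold among ties

  # tie-corrected Mann-Whitney AUC (== trapezoidal area of the ROC)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  structure(list(AUC = auc, threshold = thr[ibest],
                 sensitivity = 100 * sens[ibest],
                 specificity = 100 * spec[ibest],
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec, J = j)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; threshold %.2f (sens %.1f%%, spec %.1f%%)\n",
              x$AUC, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Full case-control study report
#'
#' Assembles the study-level outputs from a subject table: group
#' comparisons of the four stiffness measures (normality-gated),
#' ROC analysis of each measure for separating cases from controls
#' (distensibility is entered negated, since lower distensibility
#' indicates stiffer walls), the cross-method Spearman correlation
#' matrix, and correlations of the multi-plane PWV with covariates
#' within each group and pooled.
#'
#' @param subjects data.frame with a `group` column (levels CAD,
#'   control) and columns `cf_PWV`, `PWV_2D`, `PWV_4D`,
#'   `distensibility`; covariate columns `age`, `LVMi`,
#'   `infarcted_segments` are used when present.
#' @return a `study_report`: list with `comparisons`, `roc`,
#'   `correlations`, `covariate_correlations`, `n_patients`,
#'   `n_controls`.
#' @export
study_report <- function(subjects) {
  assert_that(is.data.frame(subjects) && "group" %in% names(subjects),
              "subjects must have a group column")
  g <- as.character(subjects$group)
  assert_that(all(g %in% c("CAD", "control")), "group must be CAD/control")
  if (!any(g == "CAD") || !any(g == "control")) {
    stop_invalid("both groups must be non-empty")
  }
  measures <- c("cf_PWV", "PWV_2D", "PWV_4D", "distensibility")
  assert_that(all(measures %in% names(subjects)),
              "subjects must carry the four stiffness measures")
  cases <- g == "CAD"

  comparisons <- lapply(measures, function(m) {
    tryCatch(compare_groups(subjects[[m]][cases], subjects[[m]][!cases],
                            measure = m),
             aortastiff_invalid_argument = function(e) {
               structure(list(measure = m, test = "none",
                              summary = c("insufficient data",
                                          "insufficient data"),
                              p_value = NA_real_),
                         class = "group_comparison")
             })
  })
  names(comparisons) <- measures

  roc <- lapply(measures, function(m) {
    sc <- subjects[[m]]
    if (m == "distensibility") sc <- -sc    # stiffer = lower distensibility
    r <- tryCatch(roc_analysis(sc, cases),
                  aortastiff_invalid_argument = function(e) {
                    structure(list(AUC = NA_real_, threshold = NA_real_,
                                   sensitivity = NA_real_,
                                   specificity = NA_real_, curve = NULL),
                              class = "roc_result")
                  })
    if (m == "distensibility" && !is.na(r$threshold)) {
      r$threshold <- -r$threshold           # report on the original scale
    }
    r
  })
  names(roc) <- measures

  correlations <- correlation_matrix(subjects[measures], method = "spearman")

  covars <- intersect(c("age", "LVMi", "infarcted_segments"), names(subjects))
  covariate_correlations <- NULL
  if (length(covars)) {
    blocks <- list(CAD = cases, control = !cases,
                   all = rep(TRUE, nrow(subjects)))
    covariate_correlations <- lapply(blocks, function(rows) {
      sub <- subjects[rows, , drop = FALSE]
      out <- lapply(covars, function(cv) {
        x <- sub$PWV_4D; y <- sub[[cv]]
        ok <- stats::complete.cases(x, y)
        if (sum(ok) < 4 || stats::sd(y[ok]) == 0) {
          return(list(rho = NA_real_, p = NA_real_))
        }
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        list(rho = unname(ct$estimate), p = ct$p.value)
      })
      names(out) <- covars
      out
    })
  }

  structure(list(comparisons = comparisons, roc = roc,
                 correlations = correlations,
                 covariate_correlations = covariate_correlations,
                 n_patients = sum(cases), n_controls = sum(!cases)),
            class = "study_report")
}

#' Render a study report as text
#'
#' @param x a `study_report`.
#' @param ... unused.
#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Case-control study report (%d patients / %d controls)\n\n",
              x$n_patients, x$n_controls))
  cat("Group comparisons:\n")
  for (cmp in x$comparisons) print(cmp)
  cat("\nROC analysis (cases vs controls):\n")
  for (m in names(x$roc)) {
    r <- x$roc[[m]]
    cat(sprintf("  %-15s AUC %.2f, threshold %.2f, sens %.1f%%, spec %.1f%%\n",
                m, r$AUC, r$threshold, r$sensitivity, r$specificity))
  }
  cat("\n")
  print(x$correlations)
  invisible(x)
}
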