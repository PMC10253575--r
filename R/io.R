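# Tabular file schemas and the end-to-end study runner.
#
# All files are header-keyed CSV (UTF-8, '.' decimal separator); every
# numeric column carries its unit in the header. Column order is not
# significant on read.

subjects_schema <- c("id", "group", "cf_pwv_m_per_s", "pwv_2d_m_per_s",
                     "pwv_4d_m_per_s", "distensibility_1e3_per_mmhg",
                     "central_sbp_mmhg", "central_dbp_mmhg", "pp_mmhg",
                     "heart_rate_bpm", "age_y", "lvmi_g_per_m2",
                     "infarcted_segments_n",
                     "meas_cf_pwv_m_per_s", "meas_pwv_2d_m_per_s",
                     "meas_pwv_4d_m_per_s", "meas_distensibility_1e3_per_mmhg")

flow_schema <- c("plane_index", "arc_length_mm", "time_s", "flow_ml_s")

check_schema <- function(df, schema, path) {
  missing <- setdiff(schema, names(df))
  extra <- setdiff(names(df), schema)
  if (length(missing) || length(extra)) {
    stop_invalid("schema mismatch in ", path,
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")),
                 if (length(extra)) paste0("; unexpected: ",
                                           paste(extra, collapse = ", ")))
  }
  df[schema]
}

check_numeric <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop_invalid("non-numeric value in column '", cc, "' of ", path,
                     " at row ", bad[1])
      }
      df[[cc]] <- vn
    }
  }
  df
}

#' Write / read a simulated subject table
#'
#' @param subjects a [simulate_cohort()] data.frame.
#' @param path CSV file path.
#' @return `read_subjects` returns the table with package-internal
#'   column names; `write_subjects` returns `path` invisibly.
#' @export
write_subjects <- function(subjects, path) {
  out <- data.frame(id = subjects$id, group = as.character(subjects$group),
                    cf_pwv_m_per_s = subjects$cf_PWV,
                    pwv_2d_m_per_s = subjects$PWV_2D,
                    pwv_4d_m_per_s = subjects$PWV_4D,
                    distensibility_1e3_per_mmhg = subjects$distensibility,
                    central_sbp_mmhg = subjects$central_SBP,
                    central_dbp_mmhg = subjects$central_DBP,
                    pp_mmhg = subjects$PP,
                    heart_rate_bpm = subjects$heart_rate,
                    age_y = subjects$age,
                    lvmi_g_per_m2 = subjects$LVMi,
                    infarcted_segments_n = subjects$infarcted_segments,
                    meas_cf_pwv_m_per_s = subjects$meas_cf_PWV,
                    meas_pwv_2d_m_per_s = subjects$meas_PWV_2D,
                    meas_pwv_4d_m_per_s = subjects$meas_PWV_4D,
                    meas_distensibility_1e3_per_mmhg = subjects$meas_distensibility)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_schema(df, subjects_schema, path)
  df <- check_numeric(df, setdiff(subjects_schema, c("id", "group")), path)
  data.frame(id = df$id, group = factor(df$group, c("CAD", "control")),
             cf_PWV = df$cf_pwv_m_per_s, PWV_2D = df$pwv_2d_m_per_s,
             PWV_4D = df$pwv_4d_m_per_s,
             distensibility = df$distensibility_1e3_per_mmhg,
             central_SBP = df$central_sbp_mmhg,
             central_DBP = df$central_dbp_mmhg, PP = df$pp_mmhg,
             heart_rate = df$heart_rate_bpm, age = df$age_y,
             LVMi = df$lvmi_g_per_m2,
             infarcted_segments = df$infarcted_segments_n,
             meas_cf_PWV = df$meas_cf_pwv_m_per_s,
             meas_PWV_2D = df$meas_pwv_2d_m_per_s,
             meas_PWV_4D = df$meas_pwv_4d_m_per_s,
             meas_distensibility = df$meas_distensibility_1e3_per_mmhg,
             stringsAsFactors = FALSE)
}

#' Write / read a flow-curve set in long CSV format
#'
#' One row per (plane, phase): `plane_index, arc_length_mm, time_s,
#' flow_ml_s`.
#'
#' @param curves a `flow_curve_set`.
#' @param path CSV file path.
#' @return `read_flow_curves` reconstructs the `flow_curve_set`;
#'   `write_flow_curves` returns `path` invisibly.
#' @export
write_flow_curves <- function(curves, path) {
  assert_that(inherits(curves, "flow_curve_set"), "curves invalid")
  np <- nrow(curves$flow); nt <- ncol(curves$flow)
  out <- data.frame(plane_index = rep(seq_len(np), each = nt),
                    arc_length_mm = rep(curves$plane_arc_lengths, each = nt),
                    time_s = rep(curves$time_axis, np),
                    flow_ml_s = as.vector(t(curves$flow)))
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_curves
#' @export
read_flow_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_schema(df, flow_schema, path)
  df <- check_numeric(df, flow_schema, path)
  planes <- sort(unique(df$plane_index))
  tt <- sort(unique(df$time_s))
  flow <- matrix(NA_real_, length(planes), length(tt))
  arc <- numeric(length(planes))
  for (k in seq_along(planes)) {
    sub <- df[df$plane_index == planes[k], ]
    sub <- sub[order(sub$time_s), ]
    flow[k, ] <- sub$flow_ml_s
    arc[k] <- sub$arc_length_mm[1]
  }
  flow_curve_set(tt, arc, flow)
}

#' Default study configuration
#'
#' Configuration list mirroring [cohort_spec()], serializable to YAML.
#' All marginal defaults equal the published group distributions.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(cohort = list(n_patients = 35L, n_controls = 18L),
       panel_mode = "A",
       calibrate_copula = TRUE,
       n_mc_calibration = 2e4,
       waveform = list(n_planes = 40L, snr_db = 20,
                       effective_dt_s = 0.034, n_phases = 50L),
       write_flow_curves = FALSE)
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  need <- c("cohort", "panel_mode")
  for (k in need) {
    if (is.null(cfg[[k]])) stop_invalid("missing config key: ", k)
  }
  for (k in names(base)) if (is.null(cfg[[k]])) cfg[[k]] <- base[[k]]
  for (k in names(base$waveform)) {
    if (is.null(cfg$waveform[[k]])) cfg$waveform[[k]] <- base$waveform[[k]]
  }
  cfg
}

#' Run the full study end-to-end
#'
#' Simulate a cohort from the configuration, estimate the stiffness
#' panels, run the case-control statistics, and write all outputs with a
#' manifest: `subjects.csv`, optional per-subject `flow_<id>.csv`,
#' `panel.csv`, `report.json`, `report.txt` and `manifest.json`.
#' Identical (config, seed) yield byte-identical outputs.
#'
#' @param config path to a YAML configuration (see [default_config()]),
#'   or a configuration list.
#' @param seed root seed.
#' @param out_dir output directory (created if absent).
#' @return the run manifest (list), invisibly.
#' @export
run_study <- function(config = default_config(), seed = 1L, out_dir) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- if (is.character(config)) read_config(config) else config
  assert_that(!is.null(cfg$cohort$n_patients) &&
                !is.null(cfg$cohort$n_controls),
              "missing config key: cohort$n_patients / cohort$n_controls")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), "cannot create output directory")

  spec <- cohort_spec(n_patients = cfg$cohort$n_patients,
                      n_controls = cfg$cohort$n_controls)
  timings <- c()
  if (isTRUE(cfg$calibrate_copula)) {
    cop <- calibrate_copula(spec, n_mc = cfg$n_mc_calibration,
                            seed = child_seed(seed, 101))
    spec <- cohort_spec(n_patients = cfg$cohort$n_patients,
                        n_controls = cfg$cohort$n_controls, copula = cop)
    timings["calibrate_s"] <- proc.time()[["elapsed"]] - t0
  }

  subjects <- simulate_cohort(spec, seed = seed, mode = cfg$panel_mode,
                              n_planes = cfg$waveform$n_planes,
                              snr_db = cfg$waveform$snr_db,
                              effective_dt = cfg$waveform$effective_dt_s,
                              n_phases = cfg$waveform$n_phases,
                              keep_curves = isTRUE(cfg$write_flow_curves))
  timings["simulate_s"] <- proc.time()[["elapsed"]] - t0

  files <- character(0)
  p_sub <- file.path(out_dir, "subjects.csv")
  write_subjects(subjects, p_sub)
  files <- c(files, p_sub)

  if (isTRUE(cfg$write_flow_curves) && !is.null(attr(subjects, "curves"))) {
    cl <- attr(subjects, "curves")
    for (i in seq_along(cl)) {
      p <- file.path(out_dir, sprintf("flow_%s.csv", subjects$id[i]))
      write_flow_curves(cl[[i]], p)
      files <- c(files, p)
    }
  }

  panel <- data.frame(id = subjects$id, group = as.character(subjects$group),
                      cf_PWV = subjects$meas_cf_PWV,
                      PWV_2D = subjects$meas_PWV_2D,
                      PWV_4D = subjects$meas_PWV_4D,
                      distensibility = subjects$meas_distensibility)
  p_panel <- file.path(out_dir, "panel.csv")
  utils::write.csv(format(panel, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   p_panel, row.names = FALSE, quote = FALSE)
  files <- c(files, p_panel)

  report <- study_report(cbind(panel[c("group", "cf_PWV", "PWV_2D", "PWV_4D",
                                       "distensibility")],
                               subjects[c("age", "LVMi",
                                          "infarcted_segments")]))
  timings["report_s"] <- proc.time()[["elapsed"]] - t0

  p_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), p_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  p_txt <- file.path(out_dir, "report.txt")
  txt <- utils::capture.output(print(report))
  writeLines(txt, p_txt)
  files <- c(files, p_json, p_txt)

  manifest <- list(package_version = as.character(utils::packageVersion("aortastiff")),
                   root_seed = as.integer(seed),
                   config = cfg,
                   timings_s = as.list(round(timings, 3)),
                   file_digests = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

report_to_list <- function(report) {
  list(n_patients = report$n_patients, n_controls = report$n_controls,
       comparisons = lapply(report$comparisons, function(cmp) {
         list(measure = cmp$measure, test = cmp$test,
              summary_patients = cmp$summary[1],
              summary_controls = cmp$summary[2], p_value = cmp$p_value)
       }),
       roc = lapply(report$roc, function(r) {
         list(AUC = r$AUC, threshold = r$threshold,
              sensitivity_pct = r$sensitivity,
              specificity_pct = r$specificity)
       }),
       spearman = as.data.frame(report$correlations$rho),
       covariates = report$covariate_correlations)
}
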