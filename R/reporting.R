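#' Mean and standard deviation of per-patient values
#'
#' The "mean +/- SD" summary used throughout cohort reports. Sample SD
#' (n - 1 denominator) is the default; population SD is available by flag.
#' A single value yields SD 0.
#'
#' @param x Numeric vector of per-patient values (non-empty).
#' @param population If `TRUE`, use the population (n denominator) SD.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
#' @examples
#' cohort_summary(c(2, 4))  # 3 +/- 1.414
cohort_summary <- function(x, population = FALSE) {
  x <- as.numeric(x)
  if (!length(x) || any(!is.finite(x))) {
    stop("cohort_summary needs at least one finite value", call. = FALSE)
  }
  m <- mean(x)
  s <- if (length(x) == 1L) 0 else stats::sd(x)
  if (population) s <- s * sqrt((length(x) - 1) / length(x))
  c(mean = m, sd = s)
}

#' Run the dose-to-risk pipeline
#'
#' Orchestrates the full chain from inputs to a [study_report]: organ
#' equivalent doses per acquisition mode, effective dose, per-organ
#' per-sex EAR at the reference ages, the EAR-versus-time series, and (in
#' simulation mode) the BMI-stratified effective-dose summary.
#'
#' Two input modes:
#' \describe{
#'   \item{fixture}{`cohort` is `"lung"` or `"liver"`: the packaged cohort
#'     mean-dose tables are loaded and fed through the risk computations
#'     directly (no simulation; bit-identical across runs).}
#'   \item{simulation}{`cohort` is a [cohort_spec()]: patients are
#'     sampled, voxelized, irradiated with the synthetic rotational beam
#'     under the first protocol, per-patient organ doses are extracted and
#'     rescaled to the remaining protocols by their exact N x mAs ratios,
#'     then summarised. Reproducible given the spec's seed.}
#' }
#'
#' @param cohort `"lung"`, `"liver"`, or a [cohort_spec()].
#' @param protocols Named list of [acquisition_protocol()]s (default the
#'   three shipped modes).
#' @param scheme A `tissue_weighting` scheme (default [icrp103_weights()]).
#' @param params A [beir_parameters()] set.
#' @param beam A [beam_model()] (simulation mode only).
#' @param voxel_size_mm Simulation voxel size (default 5 mm; coarser than
#'   the 2.5 mm planning grid to keep desk-scale runtimes).
#' @param angles_deg Gantry angles for simulation (default 10-degree
#'   steps over the full rotation).
#' @param attained_age,exposure_ages EAR evaluation ages (defaults 70 and
#'   30/40/50/60 y).
#' @return A `study_report` object.
#' @export
#' @examples
#' rep <- run_pipeline("lung")
#' rep$effective_dose
run_pipeline <- function(cohort = "lung",
                         protocols = list(thorax = cbct_protocol("thorax"),
                                          pelvis = cbct_protocol("pelvis"),
                                          fourD = cbct_protocol("fourD")),
                         scheme = icrp103_weights(),
                         params = beir_parameters(),
                         beam = beam_model(),
                         voxel_size_mm = 5,
                         angles_deg = seq(-180, 170, by = 10),
                         attained_age = 70,
                         exposure_ages = c(30, 40, 50, 60)) {
  if (inherits(cohort, "cohort_spec")) {
    .run_pipeline_sim(cohort, protocols, scheme, params, beam,
                      voxel_size_mm, angles_deg, attained_age,
                      exposure_ages)
  } else {
    site <- match.arg(cohort, c("lung", "liver"))
    .run_pipeline_fixture(site, protocols, scheme, params, attained_age,
                          exposure_ages)
  }
}

.ear_tables <- function(dose_tables, params, attained_age, exposure_ages) {
  ear <- list()
  series <- list()
  for (mode in names(dose_tables)) {
    dt <- dose_tables[[mode]]
    for (sx in c("male", "female")) {
      tab <- ear_time_series(dt, sx, attained_age, exposure_ages = 30,
                             params = params)
      tab$mode <- mode
      ear[[paste(mode, sx)]] <- tab
    }
  }
  for (sx in c("male", "female")) {
    s <- ear_time_series(dose_tables[[length(dose_tables)]], sx,
                         attained_age, exposure_ages, params = params)
    s$mode <- names(dose_tables)[length(dose_tables)]
    series[[sx]] <- s
  }
  list(ear = do.call(rbind, unname(ear)),
       series = do.call(rbind, unname(series)))
}

.run_pipeline_fixture <- function(site, protocols, scheme, params,
                                  attained_age, exposure_ages) {
  modes <- names(protocols)
  dose_tables <- stats::setNames(
    lapply(modes, function(m) cbct_dose_fixture(site, m)), modes)
  organ_summary <- stats::setNames(lapply(modes, function(m) {
    dt <- as.data.frame(dose_tables[[m]])
    sdcol <- cbct_dose_fixture_sd(site, m)
    merge(dt, sdcol, by = "organ_id", sort = FALSE)
  }), modes)
  eff <- vapply(dose_tables, effective_dose, numeric(1), scheme = scheme)
  eff_summary <- data.frame(mode = modes, mean_mSv = unname(eff),
                            sd_mSv = NA_real_, stringsAsFactors = FALSE)
  et <- .ear_tables(dose_tables, params, attained_age, exposure_ages)
  study_report(site = site, source = "fixture",
               organ_summary = organ_summary,
               effective_dose = eff_summary,
               ear = et$ear, ear_series = et$series,
               bmi_summary = NULL, n_patients = NA_integer_)
}

.run_pipeline_sim <- function(spec, protocols, scheme, params, beam,
                              voxel_size_mm, angles_deg, attained_age,
                              exposure_ages) {
  cohort <- sample_cohort(spec)
  modes <- names(protocols)
  ref <- protocols[[1]]
  ref_exposure <- ref$n_acquisitions * total_mas(ref)
  per_patient <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ph <- tryCatch(
      generate_phantom(cohort$phantom[[i]], voxel_size_mm = voxel_size_mm),
      error = function(e) stop("stage generate_phantom, patient ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    grid <- tryCatch(
      simulate_rotational_dose(ph$phantom, beam, ref, angles_deg),
      error = function(e) stop("stage simulate_rotational_dose, patient ",
                               i, ": ", conditionMessage(e), call. = FALSE))
    base <- extract_organ_doses(grid, ph$structures)
    per_patient[[i]] <- stats::setNames(lapply(modes, function(m) {
      p <- protocols[[m]]
      k <- p$n_acquisitions * total_mas(p) / ref_exposure
      organ_dose_table(base$organ_id, base$mean_dose_mGy * k,
                       base$volume_cm3)
    }), modes)
  }
  organ_summary <- stats::setNames(lapply(modes, function(m) {
    organs <- per_patient[[1]][[m]]$organ_id
    do.call(rbind, lapply(seq_along(organs), function(j) {
      vals <- vapply(per_patient,
                     function(pp) pp[[m]]$mean_dose_mGy[j], numeric(1))
      cs <- cohort_summary(vals)
      data.frame(organ_id = organs[j], mean_dose_mGy = cs[["mean"]],
                 sd_mGy = cs[["sd"]], stringsAsFactors = FALSE)
    }))
  }), modes)
  eff_mat <- sapply(modes, function(m) {
    vapply(per_patient, function(pp) effective_dose(pp[[m]], scheme),
           numeric(1))
  })
  eff_mat <- matrix(eff_mat, nrow = nrow(cohort),
                    dimnames = list(NULL, modes))
  eff_summary <- do.call(rbind, lapply(modes, function(m) {
    cs <- cohort_summary(eff_mat[, m])
    data.frame(mode = m, mean_mSv = cs[["mean"]], sd_mSv = cs[["sd"]],
               stringsAsFactors = FALSE)
  }))
  # cohort-mean dose tables drive the EARs (sexes share the cohort means)
  dose_tables <- stats::setNames(lapply(modes, function(m) {
    s <- organ_summary[[m]]
    organ_dose_table(s$organ_id, s$mean_dose_mGy)
  }), modes)
  et <- .ear_tables(dose_tables, params, attained_age, exposure_ages)
  last <- modes[length(modes)]
  bmi_summary <- do.call(rbind, lapply(
    c("underweight", "normal", "overweight"), function(cl) {
      idx <- cohort$bmi_class == cl
      if (!any(idx)) return(NULL)
      cs <- cohort_summary(eff_mat[idx, last])
      data.frame(bmi_class = cl, n = sum(idx), mode = last,
                 mean_mSv = cs[["mean"]], sd_mSv = cs[["sd"]],
                 stringsAsFactors = FALSE)
    }))
  study_report(site = spec$site, source = "simulation",
               organ_summary = organ_summary,
               effective_dose = eff_summary,
               ear = et$ear, ear_series = et$series,
               bmi_summary = bmi_summary, n_patients = nrow(cohort),
               cohort = cohort)
}

#' Study report container
#'
#' Assembles the result surfaces of a dose-to-risk study: per-mode organ
#' equivalent-dose summaries (mean +/- SD), per-mode effective doses, the
#' per-organ/per-sex EAR table at the reference ages, the EAR-versus-time
#' series for the last (typically 4D) mode, and, for simulated cohorts,
#' the BMI-class effective-dose summary.
#'
#' @param site Cohort site label.
#' @param source `"fixture"` or `"simulation"`.
#' @param organ_summary Named list (per mode) of organ dose data.frames.
#' @param effective_dose data.frame `mode`, `mean_mSv`, `sd_mSv`.
#' @param ear EAR data.frame at the reference exposure age.
#' @param ear_series EAR-versus-time data.frame.
#' @param bmi_summary Optional BMI-class data.frame.
#' @param n_patients Number of patients (NA for fixture mode).
#' @param cohort Optional cohort manifest.
#' @return Object of class `study_report`.
#' @export
study_report <- function(site, source, organ_summary, effective_dose, ear,
                         ear_series, bmi_summary = NULL,
                         n_patients = NA_integer_, cohort = NULL) {
  stopifnot(is.list(organ_summary), is.data.frame(effective_dose))
  for (m in names(organ_summary)) {
    s <- organ_summary[[m]]
    if (any(stats::na.omit(s$sd_mGy) < 0)) {
      stop("negative SD in organ summary", call. = FALSE)
    }
    bad <- setdiff(s$organ_id, organ_registry())
    if (length(bad)) stop("unregistered organ in report: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(site = site, source = source, organ_summary = organ_summary,
         effective_dose = effective_dose, ear = ear,
         ear_series = ear_series, bmi_summary = bmi_summary,
         n_patients = n_patients, cohort = cohort),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report [%s cohort, %s mode]\n", x$site, x$source))
  cat("\nEffective dose (mSv):\n")
  print(x$effective_dose, row.names = FALSE, digits = 3)
  cat("\nEAR at reference ages (cases per 10^6 person-years):\n")
  ear <- x$ear
  ear$ear_per_1e6_py <- round(ear$ear_per_1e6_py, 1)
  print(utils::head(ear[, c("mode", "organ_id", "sex", "ear_per_1e6_py")],
                    12), row.names = FALSE)
  if (nrow(ear) > 12) cat("  ... (", nrow(ear), " rows)\n", sep = "")
  if (!is.null(x$bmi_summary)) {
    cat("\nEffective dose by BMI class:\n")
    print(x$bmi_summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Lossless round-trip via [read_report()] (the phantom list-column of a
#' simulated cohort is dropped; numeric content is preserved in full
#' precision).
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  x <- unclass(report)
  if (!is.null(x$cohort)) {
    x$cohort <- as.data.frame(x$cohort)
    x$cohort$phantom <- NULL
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a study report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return A `study_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_na <- function(d) {
    # all-NA numeric columns come back logical from JSON null
    for (nm in names(d)) {
      if (is.logical(d[[nm]]) && all(is.na(d[[nm]]))) {
        d[[nm]] <- as.numeric(d[[nm]])
      }
    }
    d
  }
  as_df <- function(d) if (is.null(d)) NULL else fix_na(as.data.frame(d))
  study_report(site = x$site, source = x$source,
               organ_summary = lapply(x$organ_summary,
                                      function(d) fix_na(as.data.frame(d))),
               effective_dose = fix_na(as.data.frame(x$effective_dose)),
               ear = as_df(x$ear), ear_series = as_df(x$ear_series),
               bmi_summary = as_df(x$bmi_summary),
               n_patients = x$n_patients %||% NA_integer_,
               cohort = as_df(x$cohort))
}
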