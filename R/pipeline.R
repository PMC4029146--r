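#' Run configuration for the full analysis
#'
#' Bundles everything one analysis run needs: either paths to a DVH CSV and
#' a cohort metadata CSV, or a synthetic [cohort_config()]; the EUD
#' parameter set; the equivalent-sphere cut radii for the volume
#' dichotomies; and the output directory. Exactly one input source must be
#' active.
#'
#' @param dvh_csv,cohort_csv Paths to input files (real-data mode).
#' @param synthetic A [cohort_config()] (synthetic mode).
#' @param params An [eud_params()] set.
#' @param dichotomy_radii_cm Cut radii in cm for the tumour-volume
#'   dichotomy (default 2).
#' @param endpoints Endpoints to analyse (subset of `c("prs","pfs","os")`).
#' @param covariates Covariate columns for the univariate table.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param rng_seed Seed recorded in the manifest (synthetic mode reuses the
#'   cohort config's own seed).
#' @return A `run_config` list.
#' @export
run_config <- function(dvh_csv = NULL, cohort_csv = NULL, synthetic = NULL,
                       params = eud_params(),
                       dichotomy_radii_cm = 2,
                       endpoints = c("prs", "pfs", "os"),
                       covariates = c("kps_ge70", "sex", "who_grade",
                                      "surgery", "age"),
                       out_dir = NULL, rng_seed = 1L) {
  real <- !is.null(dvh_csv) || !is.null(cohort_csv)
  if (real && (is.null(dvh_csv) || is.null(cohort_csv)))
    abort_validation("real-data mode needs both dvh_csv and cohort_csv")
  if (real && !is.null(synthetic))
    abort_validation("give either input paths or a synthetic config, not both")
  if (!real && is.null(synthetic))
    abort_validation("one of {input paths, synthetic config} must be set")
  if (any(dichotomy_radii_cm <= 0))
    abort_validation("dichotomy radii must be > 0")
  structure(list(dvh_csv = dvh_csv, cohort_csv = cohort_csv,
                 synthetic = synthetic, params = params,
                 dichotomy_radii_cm = dichotomy_radii_cm,
                 endpoints = endpoints, covariates = covariates,
                 out_dir = out_dir, rng_seed = rng_seed),
            class = "run_config")
}

#' Per-patient, per-course dose metrics from a DVH table
#'
#' Computes EUD (class-specific model), maximum, mean and minimum dose for
#' every histogram in a DVH table.
#'
#' @param dvh_tbl Tibble with `patient_id`, `course`, `structure`, `dvh`
#'   (as from [generate_cohort()] or [read_dvh_csv()]).
#' @param params An [eud_params()] set.
#' @return Long tibble `patient_id`, `course`, `structure`, `metric`
#'   (`eud`, `d_max`, `d_mean`, `d_min`), `value` (Gy).
#' @export
dose_metrics <- function(dvh_tbl, params = eud_params()) {
  purrr::pmap(dvh_tbl[c("patient_id", "course", "structure", "dvh")],
              function(patient_id, course, structure, dvh) {
    s <- dose_summary(dvh)
    tibble::tibble(
      patient_id = patient_id, course = course, structure = structure,
      metric = c("eud", "d_max", "d_mean", "d_min"),
      value = c(eud_for_structure(dvh, params = params),
                s$d_max, s$d_mean, s$d_min))
  }) |>
    dplyr::bind_rows()
}

#' Run the full dose-accumulation and outcome analysis
#'
#' Orchestrates the pipeline: load (or generate) the cohort and its DVHs,
#' compute per-course dose metrics and EUDs, build the cohort dose table and
#' the cumulative table with recovery-corrected sums, construct survival
#' endpoints, run the Kaplan-Meier/log-rank analysis by KPS group and by
#' tumour-volume dichotomy, and fit the univariate Cox table. When
#' `config$out_dir` is set the rendered TSV tables and a machine-readable
#' run manifest (seed, parameters, package version) are written there.
#'
#' @param config A [run_config()].
#' @return A `reirrad_run` list with elements `patient_characteristics`,
#'   `dose_table`, `endpoints`, `km_kps`, `logrank_kps`,
#'   `volume_dichotomy` (one row per cut radius), `univariate`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    patients <- cohort$patients
    dvh_tbl <- cohort$dvh
    seed <- config$synthetic$rng_seed
  } else {
    if (!file.exists(config$dvh_csv) || !file.exists(config$cohort_csv))
      abort_validation("input file(s) not found")
    dvh_tbl <- read_dvh_csv(config$dvh_csv)
    patients <- readr::read_csv(config$cohort_csv, show_col_types = FALSE,
                                progress = FALSE)
    seed <- config$rng_seed
  }
  if (nrow(patients) == 0L) abort_validation("empty cohort")

  metrics <- dose_metrics(dvh_tbl, config$params)
  dose_tbl <- cohort_dose_table(
    dplyr::filter(metrics, .data$metric %in% c("eud", "d_max", "d_mean")),
    recovery_r = config$params$recovery_r)

  ep <- compute_endpoints(patients)
  surv_dat <- dplyr::inner_join(patients, ep, by = "patient_id")
  km_kps <- km_estimate(surv_dat, time = "prs_days", event = "prs_event",
                        group = "kps_ge70")
  lr_kps <- logrank(surv_dat, time = "prs_days", event = "prs_event",
                    group = "kps_ge70")

  dich <- purrr::map(config$dichotomy_radii_cm, function(r_cut) {
    grp <- volume_dichotomy(surv_dat, r_cut_cm = r_cut)
    sizes <- dichotomy_sizes(grp)
    grp2 <- dplyr::filter(grp, !is.na(.data$volume_group))
    lr <- if (all(table(grp2$volume_group) > 0))
      logrank(grp2, time = "prs_days", event = "prs_event",
              group = "volume_group")
    else tibble::tibble(chisq = NA_real_, df = 1L, p = NA_real_)
    tibble::tibble(r_cut_cm = r_cut, v_cut_cc = sphere_volume(r_cut),
                   n_small = sizes[["small"]], n_large = sizes[["large"]],
                   n_excluded = sizes[["excluded"]],
                   logrank_chisq = lr$chisq, logrank_p = lr$p)
  }) |> dplyr::bind_rows()

  uni <- univariate_table(patients, ep,
                          covariates = intersect(config$covariates,
                                                 names(patients)),
                          endpoint_names = config$endpoints)

  characteristics <- patient_characteristics(patients)

  manifest <- list(
    package = "reirrad", version = as.character(utils::packageVersion("reirrad")),
    rng_seed = seed,
    eud_params = unclass(config$params),
    dichotomy_radii_cm = config$dichotomy_radii_cm,
    n_patients = nrow(patients),
    n_dvhs = nrow(dvh_tbl),
    input_mode = if (is.null(config$synthetic)) "files" else "synthetic"
  )

  run <- structure(list(
    patient_characteristics = characteristics,
    dose_table = dose_tbl,
    metrics = metrics,
    endpoints = ep,
    km_kps = km_kps,
    logrank_kps = lr_kps,
    volume_dichotomy = dich,
    univariate = uni,
    manifest = manifest
  ), class = "reirrad_run")

  if (!is.null(config$out_dir)) render_tables(run, config$out_dir)
  run
}

#' @export
print.reirrad_run <- function(x, ...) {
  cat(sprintf("<reirrad_run> %d patients, %d dose metrics\n",
              x$manifest$n_patients, nrow(x$metrics)))
  cat("tables: patient_characteristics, dose_table, endpoints, km_kps,",
      "volume_dichotomy, univariate\n")
  invisible(x)
}

#' Patient characteristics summary
#'
#' Count/percentage table of the cohort demographics (sex, MGMT status,
#' surgery, WHO grade, KPS group) plus the median age and range.
#'
#' @param patients Patient tibble.
#' @return Tibble with `characteristic`, `level`, `n`, `percent`.
#' @export
patient_characteristics <- function(patients) {
  n <- nrow(patients)
  count_tab <- function(col, name) {
    patients |>
      dplyr::count(level = as.character(.data[[col]]), name = "n") |>
      dplyr::mutate(characteristic = name,
                    percent = round_half_up(100 * n / !!n, 1)) |>
      dplyr::select("characteristic", "level", "n", "percent")
  }
  dplyr::bind_rows(
    count_tab("sex", "sex"),
    tibble::tibble(characteristic = "age", level = sprintf(
      "median %s (%s - %s)", stats::median(patients$age),
      min(patients$age), max(patients$age)), n = n, percent = 100),
    count_tab("mgmt", "mgmt"),
    count_tab("surgery", "surgery"),
    count_tab("who_grade", "who_grade"),
    count_tab("kps_ge70", "kps_ge70")
  )
}

#' Render the run's report tables to TSV
#'
#' Writes the Table 1-4 analogues with display rounding (half-up, one
#' decimal for doses and radii) and `NR` for not-reached medians, plus the
#' JSON run manifest. Every cell is recomputable from the run object's
#' tibbles; rendering only formats.
#'
#' @param run A `reirrad_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
render_tables <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "NR", format(round_half_up(x, 1),
                                                   trim = TRUE, nsmall = 1))
  paths <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  w(run$patient_characteristics, "table1_patient_characteristics.tsv")

  dt <- run$dose_table |>
    dplyr::mutate(dplyr::across(dplyr::starts_with(c("median", "max", "cum",
                                                     "corrected")), fmt))
  w(dt, "table2_3_dose_parameters.tsv")

  km <- glance(run$km_kps) |>
    dplyr::mutate(median = ifelse(is.na(.data$median), "NR",
                                  format(.data$median, trim = TRUE)))
  w(km, "km_medians_by_kps.tsv")
  w(run$volume_dichotomy |>
      dplyr::mutate(dplyr::across(c("v_cut_cc"), fmt)),
    "volume_dichotomy.tsv")
  w(run$univariate |>
      dplyr::mutate(dplyr::across(c("hr", "conf_low", "conf_high"),
                                  ~ round_half_up(.x, 2)),
                    p = signif(.data$p, 2)),
    "table4_univariate.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, file.path(out_dir, "manifest.json"))
  invisible(paths)
}
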