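#' Configuration for the synthetic re-irradiation cohort
#'
#' Defines every distribution the generator draws from. The defaults
#' emulate a single-institution recurrent malignant-glioma cohort treated
#' with two radiation courses: a ~60 Gy primary course (2 Gy fractions)
#' and a 36 Gy re-irradiation (2 Gy fractions); demographic marginals
#' (62.1% male, median age 52 with range 18-68, 79.3% WHO grade IV at
#' relapse, 75.9% KPS >= 70, MGMT methylated/unmethylated/unknown
#' 34.5/48.3/17.2%, 81% prior surgery); per-structure logistic DVH shapes;
#' Weibull survival with a KPS effect targeting group medians of 308 days
#' (KPS >= 70) vs 176 days (KPS < 70) and ~20% censoring; and structure-wise
#' missingness of first-course DVHs (only 12-29 of 58 plans per structure
#' have usable primary DVH data).
#'
#' @param n_patients Cohort size (default 58).
#' @param p_male Probability male (default 0.621).
#' @param age_median,age_range Age distribution target median and range in
#'   years.
#' @param p_mgmt Named probabilities for MGMT status
#'   (`methylated`/`not_methylated`/`unknown`), must sum to 1.
#' @param p_surgery,p_grade_iv,p_kps_ge70,p_brachy Marginal probabilities.
#' @param rx_rt1_gy,rx_rert_gy Prescription doses in Gy.
#' @param dvh_params Tibble of per-course, per-structure logistic DVH shape
#'   parameters (`course`, `structure`, `d50`, `spread`, `spared_fraction`);
#'   see [synth_dvh()].
#' @param rt1_availability,rert_availability Named per-structure
#'   probabilities that a course's DVH is available.
#' @param survival List: `shape` (Weibull shape), `median_kps_ge70` (days),
#'   `kps_hazard_ratio` (hazard of KPS < 70 vs >= 70), `censoring_rate`,
#'   `family` (`"weibull"` or `"exponential"`).
#' @param gtv_volume List: lognormal `median_rt1_cc`, `median_rert_cc`,
#'   `sdlog_rt1`, `sdlog_rert`.
#' @param interval List: lognormal `median_days` and `sdlog` for the
#'   inter-treatment interval, truncated at `min_days`.
#' @param d50_cv,spread_cv Patient-level multiplicative (lognormal)
#'   variation of the DVH shape parameters.
#' @param n_distant Number of patients flagged with distant, distinct
#'   lesions (excluded from the volume dichotomy; default 2).
#' @param rng_seed Integer seed making the generated cohort fully
#'   deterministic.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 58,
    p_male = 0.621,
    age_median = 52, age_range = c(18, 68),
    p_mgmt = c(methylated = 0.345, not_methylated = 0.483, unknown = 0.172),
    p_surgery = 0.81,
    p_grade_iv = 0.793,
    p_kps_ge70 = 0.759,
    p_brachy = 0.138,
    rx_rt1_gy = 60, rx_rert_gy = 36,
    dvh_params = default_dvh_params(),
    rt1_availability = c(optic_chiasm = 25, brainstem = 27,
                         optic_nerve_left = 26, optic_nerve_right = 23,
                         brain = 12, gtv = 21, ptv = 22) / 58,
    rert_availability = c(optic_chiasm = 1, brainstem = 1,
                          optic_nerve_left = 1, optic_nerve_right = 1,
                          brain = 55 / 58, gtv = 51 / 58, ptv = 50 / 58),
    survival = list(shape = 1.2, median_kps_ge70 = 308,
                    kps_hazard_ratio = (308 / 176)^1.2,
                    censoring_rate = 0.2, family = "weibull"),
    gtv_volume = list(median_rt1_cc = 36.6, sdlog_rt1 = 1.0,
                      median_rert_cc = 33.9, sdlog_rert = 0.85),
    interval = list(median_days = 642, sdlog = 0.9, min_days = 173),
    d50_cv = 0.12, spread_cv = 0.10,
    n_distant = 2,
    rng_seed = 1L) {
  probs <- c(p_male, p_surgery, p_grade_iv, p_kps_ge70, p_brachy, p_mgmt,
             rt1_availability, rert_availability)
  if (any(probs < 0 | probs > 1))
    abort_validation("all probabilities must lie in [0, 1]")
  if (abs(sum(p_mgmt) - 1) > 1e-9)
    abort_validation("MGMT category probabilities must sum to 1")
  if (rx_rt1_gy <= 0 || rx_rert_gy <= 0)
    abort_validation("prescription doses must be > 0")
  if (n_patients < 2) abort_validation("n_patients must be >= 2")
  if (!survival$family %in% c("weibull", "exponential"))
    abort_validation("survival family must be weibull or exponential")
  structure(as.list(environment())[names(formals(cohort_config))],
            class = "cohort_config")
}

#' Default per-structure logistic DVH shape parameters
#'
#' Illustrative shapes chosen so that cohort EUD/Dmax medians land at the
#' order of magnitude typical for glioma irradiation (primary course near
#' full prescription in target and midline structures, substantially lower
#' re-irradiation OAR doses); they are not fits to any measured DVH set.
#'
#' @return Tibble with `course`, `structure`, `d50`, `spread`,
#'   `spared_fraction`.
#' @export
default_dvh_params <- function() {
  tibble::tribble(
    ~course, ~structure,          ~d50, ~spread, ~spared_fraction,
    "RT1",   "optic_chiasm",       42,   3,      0.05,
    "RT1",   "brainstem",          44,   3,      0.05,
    "RT1",   "optic_nerve_left",   16,   6,      0.25,
    "RT1",   "optic_nerve_right",  16,   6,      0.25,
    "RT1",   "brain",              22,   7,      0.05,
    "RT1",   "gtv",                60,   0.8,    0,
    "RT1",   "ptv",                59.5, 1.0,    0,
    "ReRT",  "optic_chiasm",        6,   3,      0.30,
    "ReRT",  "brainstem",          14,   5,      0.20,
    "ReRT",  "optic_nerve_left",    1.5, 1.5,    0.40,
    "ReRT",  "optic_nerve_right",   2,   1.8,    0.40,
    "ReRT",  "brain",              10,   6,      0.10,
    "ReRT",  "gtv",                36,   0.8,    0,
    "ReRT",  "ptv",                34,   1.5,    0
  )
}

#' Synthetic cumulative DVH from a logistic family
#'
#' The cumulative curve follows a logistic tail
#' `(1 - spared_fraction) * L((d50 - D)/spread)` for `D > 0`, rescaled to
#' reach exactly 0 at the top of the grid and pinned to 1 at `D = 0` (the
#' spared fraction of the structure receives essentially no dose). `d50` is
#' the dose at which the unspared volume fraction has fallen to one half,
#' `spread` controls the fall-off width in Gy. In the limit `spread -> 0`,
#' `spared_fraction = 0`, the structure receives the uniform dose `d50`.
#'
#' @param structure Structure label.
#' @param d50 Half-coverage dose in Gy, `>= 0`.
#' @param spread Fall-off width in Gy, `> 0`.
#' @param spared_fraction Fraction of the structure receiving ~0 Gy, in
#'   `[0, 1)`.
#' @param grid Dose grid (default [default_dose_grid()] up to
#'   `d50 + 6 * spread`).
#' @param absolute_volume_cc Optional absolute volume metadata.
#' @return A valid cumulative `dvh`.
#' @export
#' @examples
#' synth_dvh("optic_chiasm", d50 = 42, spread = 4, spared_fraction = 0.05)
synth_dvh <- function(structure, d50, spread, spared_fraction = 0,
                      grid = NULL, absolute_volume_cc = NA_real_) {
  if (d50 < 0) abort_validation("d50 must be >= 0")
  if (spread <= 0) abort_validation("spread must be > 0")
  if (spared_fraction < 0 || spared_fraction >= 1)
    abort_validation("spared_fraction must lie in [0, 1)")
  grid <- grid %||% default_dose_grid(d50 + 6 * spread)
  top <- max(grid)
  l <- stats::plogis((d50 - grid) / spread)
  l_top <- stats::plogis((d50 - top) / spread)
  l0 <- stats::plogis(d50 / spread)
  base <- (l - l_top) / (l0 - l_top)   # 1 at D = 0, 0 at grid top
  v <- (1 - spared_fraction) * base
  v[1L] <- 1
  v <- cummin(pmin(pmax(v, 0), 1))
  dvh_cumulative(grid, v, structure = structure,
                 absolute_volume_cc = absolute_volume_cc)
}

#' Emulate hardcopy digitisation of a DVH curve
#'
#' Samples `n_points` doses evenly across the curve's support and perturbs
#' both coordinates with additive Gaussian jitter, imitating manual
#' extraction of points from a printed DVH. Feed the result to
#' [ingest_digitized_points()] to recover a clean cumulative DVH.
#'
#' @param dvh A cumulative `dvh`.
#' @param n_points Number of digitised points, `>= 5` (default 30).
#' @param dose_jitter_gy Dose-axis jitter SD in Gy (default 0.2).
#' @param volume_jitter Volume-fraction jitter SD (default 0.005).
#' @param seed Integer seed; the point list is deterministic per seed.
#' @return Tibble with `dose_gy`, `volume_fraction`.
#' @export
emulate_hardcopy <- function(dvh, n_points = 30, dose_jitter_gy = 0.2,
                             volume_jitter = 0.005, seed = 1L) {
  if (n_points < 5) abort_validation("need at least 5 digitised points")
  cum <- to_cumulative(dvh)
  withr::with_seed(seed, {
    doses <- seq(min(cum$dose_gy), max(cum$dose_gy), length.out = n_points)
    doses <- pmax(doses + stats::rnorm(n_points, 0, dose_jitter_gy), 0)
    vols <- stats::approx(cum$dose_gy, cum$volume_fraction, xout = doses,
                          rule = 2)$y
    vols[doses > max(cum$dose_gy)] <- 0
    vols <- vols + stats::rnorm(n_points, 0, volume_jitter)
    tibble::tibble(dose_gy = doses, volume_fraction = vols)
  })
}

#' Generate a synthetic two-course re-irradiation cohort
#'
#' Draws a fully synthetic patient table (demographics, dates, survival
#' outcomes, tumour volumes) and, optionally, per-patient per-course
#' cumulative DVHs for optic chiasm, brainstem, both optic nerves, brain,
#' GTV and PTV. First-course DVHs are missing at the configured
#' per-structure rates (emulating plans for which only hardcopies exist);
#' `n_distant` patients are flagged with distant, distinct lesions for
#' exclusion from volume analyses. Deterministic given `config$rng_seed`.
#'
#' @param config A [cohort_config()].
#' @param dvhs Generate the DVH table as well (default `TRUE`; turn off for
#'   large demographic-only cohorts).
#' @return A list of class `reirrad_cohort` with elements `patients` (one
#'   row per patient) and `dvh` (tibble `patient_id`, `course`, `structure`,
#'   `dvh` list-column; `NULL` when `dvhs = FALSE`), plus the config.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 10, rng_seed = 7))
#' coh$patients
generate_cohort <- function(config = cohort_config(), dvhs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$rng_seed, {
    n <- config$n_patients
    id <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    # beta-shaped ages matching the target median/range
    ar <- config$age_range
    age <- round(ar[1] + (ar[2] - ar[1]) * stats::rbeta(n, 2.8, 1.5))
    p_hi <- config$p_kps_ge70
    kps <- sample(c(50, 60, 70, 80, 90, 100), n, replace = TRUE,
                  prob = c((1 - p_hi) * c(0.42, 0.58),
                           p_hi * c(0.20, 0.46, 0.26, 0.08)))
    mgmt <- sample(names(config$p_mgmt), n, replace = TRUE,
                   prob = config$p_mgmt)
    surgery <- stats::runif(n) < config$p_surgery
    who_grade <- ifelse(stats::runif(n) < config$p_grade_iv, "IV", "III")
    brachy <- stats::runif(n) < config$p_brachy

    # inter-treatment interval: lognormal, truncated below
    iv <- config$interval
    interval_days <- stats::rlnorm(n, log(iv$median_days), iv$sdlog)
    while (any(interval_days < iv$min_days)) {
      bad <- interval_days < iv$min_days
      interval_days[bad] <- stats::rlnorm(sum(bad), log(iv$median_days),
                                          iv$sdlog)
    }
    interval_days <- round(interval_days)
    rert_start <- as.Date("2009-06-01") + sample.int(600, n, replace = TRUE)
    rt1_start <- rert_start - interval_days

    # survival: proportional-hazards Weibull, KPS < 70 at elevated hazard
    sv <- config$survival
    shape <- if (sv$family == "exponential") 1 else sv$shape
    scale_good <- sv$median_kps_ge70 / log(2)^(1 / shape)
    hr <- ifelse(kps < 70, sv$kps_hazard_ratio, 1)
    t_event <- scale_good * (-log(stats::runif(n)) / hr)^(1 / shape)
    p_c <- sv$censoring_rate
    scale_cens <- scale_good * ((1 - p_c) / p_c)^(1 / shape)
    t_cens <- scale_cens * (-log(stats::runif(n)) / hr)^(1 / shape)
    prs_days <- pmax(1, round(pmin(t_event, t_cens)))
    event <- as.integer(t_event <= t_cens)
    death_date <- as.Date(ifelse(event == 1, rert_start + prs_days, NA),
                          origin = "1970-01-01")
    last_followup <- rert_start + prs_days
    prog_days <- pmax(1, round(t_event * stats::runif(n, 0.4, 0.9)))
    prog_seen <- prog_days <= prs_days
    progression_date <- as.Date(ifelse(prog_seen, rert_start + prog_days, NA),
                                origin = "1970-01-01")

    gv <- config$gtv_volume
    gtv_rt1_cc <- stats::rlnorm(n, log(gv$median_rt1_cc), gv$sdlog_rt1)
    gtv_rert_cc <- stats::rlnorm(n, log(gv$median_rert_cc), gv$sdlog_rert)
    distant <- rep(FALSE, n)
    distant[sample.int(n, min(config$n_distant, n))] <- TRUE

    patients <- tibble::tibble(
      patient_id = id, sex = sex, age = age, kps = kps,
      kps_ge70 = kps >= 70, mgmt = mgmt, surgery = surgery,
      who_grade = who_grade, brachytherapy = brachy,
      rt1_start = rt1_start, rert_start = rert_start,
      death_date = death_date, progression_date = progression_date,
      last_followup = last_followup,
      gtv_rt1_cc = gtv_rt1_cc, gtv_rert_cc = gtv_rert_cc,
      distant_lesions = distant
    )

    dvh_tbl <- NULL
    if (dvhs) {
      grid_combo <- tidyr::expand_grid(patient_id = id,
                                       config$dvh_params)
      keep <- stats::runif(nrow(grid_combo)) <
        ifelse(grid_combo$course == "RT1",
               config$rt1_availability[grid_combo$structure],
               config$rert_availability[grid_combo$structure])
      grid_combo <- grid_combo[keep, ]
      vols <- stats::setNames(patients$gtv_rt1_cc, id)
      vols2 <- stats::setNames(patients$gtv_rert_cc, id)
      dvh_tbl <- grid_combo |>
        dplyr::mutate(
          d50_i = .data$d50 * stats::rlnorm(dplyr::n(), 0, config$d50_cv),
          spread_i = .data$spread * stats::rlnorm(dplyr::n(), 0,
                                                  config$spread_cv)
        ) |>
        dplyr::mutate(dvh = purrr::pmap(
          list(.data$structure, .data$d50_i, .data$spread_i,
               .data$spared_fraction, .data$patient_id, .data$course),
          function(structure, d50, spread, spared, pid, course) {
            vol <- if (structure == "gtv") {
              if (course == "RT1") vols[[pid]] else vols2[[pid]]
            } else NA_real_
            synth_dvh(structure, d50, spread, spared,
                      absolute_volume_cc = vol)
          })) |>
        dplyr::select("patient_id", "course", "structure", "dvh")
    }

    structure(list(patients = patients, dvh = dvh_tbl, config = config),
              class = "reirrad_cohort")
  })
}

#' @export
print.reirrad_cohort <- function(x, ...) {
  cat(sprintf("<reirrad_cohort> %d patients, %s DVHs (seed %s)\n",
              nrow(x$patients),
              if (is.null(x$dvh)) "no" else nrow(x$dvh),
              format(x$config$rng_seed)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort metadata CSV and (if present) the DVH CSV in the
#' standard dialect, so the analysis can be re-run from files.
#'
#' @param cohort A `reirrad_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- file.path(dir, "cohort.csv")
  readr::write_csv(cohort$patients, meta, progress = FALSE)
  paths <- meta
  if (!is.null(cohort$dvh)) {
    dvhp <- file.path(dir, "dvh.csv")
    write_dvh_csv(cohort$dvh, dvhp)
    paths <- c(paths, dvhp)
  }
  invisible(paths)
}
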