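#' Biologically effective dose of a fractionated course
#'
#' Linear-quadratic BED: n * d * (1 + d / (alpha/beta)) for the main
#' course, plus the same expression for any boost course. The alpha/beta
#' ratio is conventionally 10 Gy for acute endpoints (erythema) and 3 Gy
#' for late endpoints (atrophy).
#'
#' @param n_fractions Number of fractions of the main course.
#' @param dose_per_fraction Dose per fraction (Gy).
#' @param alpha_beta Tissue alpha/beta ratio (Gy), > 0.
#' @param boost_n_fractions Boost fraction count (0 for no boost).
#' @param boost_dose_per_fraction Boost dose per fraction (Gy); defaults to
#'   the main-course dose per fraction when a boost is present.
#' @return BED in Gy. All arguments vectorized.
#' @examples
#' compute_bed(15, 2.667, alpha_beta = 3) # 75.57 Gy
#' @export
compute_bed <- function(n_fractions, dose_per_fraction, alpha_beta,
                        boost_n_fractions = 0,
                        boost_dose_per_fraction = NULL) {
  if (any(alpha_beta <= 0)) stop("`alpha_beta` must be > 0", call. = FALSE)
  if (any(n_fractions <= 0) || any(dose_per_fraction <= 0)) {
    stop("main course needs positive fraction count and dose", call. = FALSE)
  }
  if (is.null(boost_dose_per_fraction)) {
    boost_dose_per_fraction <- dose_per_fraction
  }
  if (any(boost_n_fractions > 0 & boost_dose_per_fraction <= 0)) {
    stop("boost course present but boost dose is not positive", call. = FALSE)
  }
  main <- n_fractions * dose_per_fraction *
    (1 + dose_per_fraction / alpha_beta)
  boost <- ifelse(
    boost_n_fractions > 0,
    boost_n_fractions * boost_dose_per_fraction *
      (1 + boost_dose_per_fraction / alpha_beta),
    0
  )
  main + boost
}

#' Summarize a patient's fraction times
#'
#' Arithmetic mean and sample standard deviation (divisor n - 1) of the
#' per-fraction apparent solar times. Arithmetic rather than circular
#' statistics are appropriate because treatments fall in a bounded daytime
#' window far from midnight.
#'
#' @param solar_times Decimal solar hours of the timed fractions.
#' @return One-row tibble: `mean_solar_time`, `sd_solar_time`,
#'   `n_fractions_timed`.
#' @export
summarize_schedule <- function(solar_times) {
  solar_times <- solar_times[!is.na(solar_times)]
  if (!length(solar_times)) {
    stop("no timed fractions to summarize", call. = FALSE)
  }
  tibble::tibble(
    mean_solar_time = mean(solar_times),
    sd_solar_time = if (length(solar_times) > 1) stats::sd(solar_times) else 0,
    n_fractions_timed = length(solar_times)
  )
}

#' Hours between a treatment time and a reference time origin
#'
#' Plain absolute difference, not circular distance: all treatments fall in
#' a ~07:00-20:00 window, so day wraparound never binds. With a midnight
#' origin the distance reduces to the raw hours-from-midnight, which is how
#' the acute (erythema) model's linear time-of-day term arises.
#'
#' @param mean_solar_time Hours in \[0, 24).
#' @param origin Reference hour in \[0, 24) (e.g. 15.5 for the late-atrophy
#'   peak, 0 for the acute model).
#' @return Hours, >= 0. Vectorized.
#' @export
time_distance <- function(mean_solar_time, origin) {
  stopifnot(all(mean_solar_time >= 0 & mean_solar_time < 24),
            all(origin >= 0 & origin < 24))
  abs(mean_solar_time - origin)
}

check_grade <- function(grade, what) {
  ok <- is.na(grade) | (grade >= 0 & grade <= 4 & grade == round(grade))
  if (!all(ok)) {
    stop(what, " grades must be integers 0-4 (no half grades)",
         call. = FALSE)
  }
  invisible(grade)
}

#' Dichotomize acute erythema
#'
#' Patients with any baseline (post-surgery, pre-radiotherapy) erythema are
#' excluded; among the rest the outcome is 1 when follow-up erythema
#' reaches CTCAE grade 2 or more.
#'
#' @param baseline,followup Integer CTCAE grades 0-4 (NA = missing).
#' @return A tibble with `outcome` (0/1, NA otherwise) and `status`
#'   (`"included"`, `"baseline_excluded"`, `"missing"`).
#' @export
dichotomize_erythema <- function(baseline, followup) {
  check_grade(baseline, "baseline erythema")
  check_grade(followup, "follow-up erythema")
  status <- rep("included", length(baseline))
  status[is.na(baseline) | is.na(followup)] <- "missing"
  status[!is.na(baseline) & baseline > 0] <- "baseline_excluded"
  outcome <- ifelse(status == "included", as.integer(followup >= 2), NA)
  tibble::tibble(outcome = as.integer(outcome), status = status)
}

#' Dichotomize late atrophy deterioration
#'
#' Outcome is 1 for worsening of >= 1 grade at 24 months versus baseline.
#' The main analysis excludes baseline atrophy >= grade 2 (gross
#' surgery-related tissue loss); the sensitivity analysis excludes any
#' baseline atrophy.
#'
#' @param baseline,grade_24m Integer CTCAE grades 0-4 (NA = missing).
#' @param sensitivity If TRUE, exclude baseline atrophy > 0.
#' @return As [dichotomize_erythema()].
#' @export
dichotomize_atrophy <- function(baseline, grade_24m, sensitivity = FALSE) {
  check_grade(baseline, "baseline atrophy")
  check_grade(grade_24m, "24-month atrophy")
  status <- rep("included", length(baseline))
  status[is.na(baseline) | is.na(grade_24m)] <- "missing"
  cut <- if (sensitivity) 0L else 1L
  status[!is.na(baseline) & baseline > cut] <- "baseline_excluded"
  outcome <- ifelse(status == "included",
                    as.integer(grade_24m - baseline >= 1), NA)
  tibble::tibble(outcome = as.integer(outcome), status = status)
}

#' Apply the cohort exclusion rules for one endpoint
#'
#' Rules are applied in a fixed, reported order: (1) the endpoint's
#' baseline-grade rule, (2) treatment-time spread (SD of solar fraction
#' times > `sd_limit` hours), (3) completeness of the model covariates.
#' A patient failing several rules is counted once, under the first rule.
#'
#' @param cohort Tibble holding, per patient, the endpoint grade columns,
#'   `sd_solar_time`, and every column named in `required`.
#' @param endpoint `"erythema"` or `"atrophy"`.
#' @param required Columns that must be non-missing for a row to enter
#'   model fitting (the outcome is always required).
#' @param sd_limit Exclusion threshold on the solar-time SD (hours).
#' @param sensitivity Passed to [dichotomize_atrophy()].
#' @return `list(data = analysis tibble with an `outcome` column,
#'   report = named integer counts of exclusions in order applied)`.
#' @export
apply_exclusions <- function(cohort,
                             endpoint = c("erythema", "atrophy"),
                             required = character(),
                             sd_limit = 2,
                             sensitivity = FALSE) {
  endpoint <- match.arg(endpoint)
  d <- dichotomize_endpoint(cohort, endpoint, sensitivity)
  cohort$outcome <- d$outcome

  baseline_out <- d$status == "baseline_excluded"
  sd_out <- !baseline_out &
    (is.na(cohort$sd_solar_time) | cohort$sd_solar_time > sd_limit)
  required <- union(required, "outcome")
  have <- stats::complete.cases(cohort[, required, drop = FALSE])
  incomplete <- !baseline_out & !sd_out & !have

  keep <- !(baseline_out | sd_out | incomplete)
  report <- c(
    n_input = nrow(cohort),
    baseline = sum(baseline_out),
    sd_over_limit = sum(sd_out),
    incomplete = sum(incomplete),
    n_analysis = sum(keep)
  )
  if (!any(keep)) stop("all patients excluded; nothing to analyse",
                       call. = FALSE)
  list(data = cohort[keep, , drop = FALSE], report = report)
}

dichotomize_endpoint <- function(cohort, endpoint, sensitivity = FALSE) {
  if (endpoint == "erythema") {
    dichotomize_erythema(cohort$baseline_erythema, cohort$followup_erythema)
  } else {
    dichotomize_atrophy(cohort$baseline_atrophy, cohort$atrophy_24m,
                        sensitivity = sensitivity)
  }
}

#' Default alpha/beta ratio for an endpoint
#' @param endpoint `"erythema"` (acute, 10 Gy) or `"atrophy"` (late, 3 Gy).
#' @return Gy.
#' @export
default_alpha_beta <- function(endpoint = c("erythema", "atrophy")) {
  switch(match.arg(endpoint), erythema = 10, atrophy = 3)
}

#' Default peak-toxicity time origin for an endpoint
#' @param endpoint `"erythema"` (solar midnight) or `"atrophy"` (solar
#'   15:30).
#' @return Decimal hours.
#' @export
default_origin <- function(endpoint = c("erythema", "atrophy")) {
  switch(match.arg(endpoint), erythema = 0, atrophy = 15.5)
}

#' Assemble the analysis dataset from raw tables
#'
#' Runs the full preprocessing chain: converts each fraction's local time
#' to apparent solar time, summarizes per-patient schedules, computes BED
#' at the endpoint's alpha/beta, derives seasonal covariates (mean day
#' length, maximum solar elevation over the treatment dates), recodes the
#' time term as distance from `origin`, dichotomizes the endpoint and
#' applies the exclusion rules.
#'
#' @param patients Patient table (see the package vignette for the schema).
#' @param fractions Fraction table: `patient_id`, `site_name`, `date`,
#'   `local_time` (decimal hours or "HH:MM"), optional `utc_offset`.
#' @param sites Site table as from [requite_sites()] or [read_sites()].
#' @param endpoint `"erythema"` or `"atrophy"`.
#' @param origin Time origin in hours; defaults per endpoint.
#' @param alpha_beta alpha/beta ratio; defaults per endpoint.
#' @param required Extra covariates that must be complete; defaults to the
#'   endpoint's published model terms.
#' @param sensitivity Sensitivity variant of the atrophy baseline rule.
#' @param sd_limit Treatment-time spread threshold (hours).
#' @return `list(data, report)` as [apply_exclusions()], where `data` also
#'   carries `bed`, `mean_solar_time`, `sd_solar_time`, `time_distance`,
#'   `day_length_mean`, `max_elevation_mean`, `latitude`.
#' @export
prepare_cohort <- function(patients, fractions, sites,
                           endpoint = c("erythema", "atrophy"),
                           origin = NULL, alpha_beta = NULL,
                           required = NULL, sensitivity = FALSE,
                           sd_limit = 2) {
  endpoint <- match.arg(endpoint)
  if (is.null(origin)) origin <- default_origin(endpoint)
  if (is.null(alpha_beta)) alpha_beta <- default_alpha_beta(endpoint)

  idx <- match(fractions$site_name, sites$name)
  if (anyNA(idx)) {
    stop("fraction table references unknown site(s): ",
         paste(unique(fractions$site_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ct <- parse_clock_time(fractions$local_time)
  uo <- if ("utc_offset" %in% names(fractions)) fractions$utc_offset
  solar <- local_to_solar(fractions$date, ct, sites[idx, ],
                          utc_offset = uo)
  doy <- as.integer(format(as.Date(fractions$date), "%j"))
  lat <- sites$latitude[idx]
  per_frac <- tibble::tibble(
    patient_id = fractions$patient_id,
    solar = solar,
    dl = as.numeric(day_length(doy, lat)),
    elev = max_solar_elevation(doy, lat)
  )
  sched <- aggregate_schedules(per_frac)

  cohort <- merge(patients, sched, by = "patient_id", all.x = TRUE)
  cohort <- tibble::as_tibble(cohort)
  cohort$latitude <- sites$latitude[match(cohort$site_name, sites$name)]
  bn <- if ("boost_n_fractions" %in% names(cohort)) {
    ifelse(is.na(cohort$boost_n_fractions), 0, cohort$boost_n_fractions)
  } else 0
  bd <- if ("boost_dose_per_fraction" %in% names(cohort)) {
    ifelse(is.na(cohort$boost_dose_per_fraction),
           cohort$dose_per_fraction, cohort$boost_dose_per_fraction)
  } else NULL
  cohort$bed <- compute_bed(cohort$n_fractions, cohort$dose_per_fraction,
                            alpha_beta, bn, bd)
  cohort$time_distance <- ifelse(
    is.na(cohort$mean_solar_time), NA_real_,
    time_distance(cohort$mean_solar_time, origin)
  )

  if (is.null(required)) required <- endpoint_model_terms(endpoint)
  required <- intersect(required, names(cohort))
  out <- apply_exclusions(cohort, endpoint, required = required,
                          sd_limit = sd_limit, sensitivity = sensitivity)
  out$origin <- origin
  out$alpha_beta <- alpha_beta
  out$endpoint <- endpoint
  out
}

endpoint_model_terms <- function(endpoint) {
  if (endpoint == "erythema") {
    c("bmi", "bed", "mean_solar_time", "sd_solar_time")
  } else {
    c("bmi", "bed", "surgery", "time_distance")
  }
}

aggregate_schedules <- function(per_frac) {
  sp <- split(per_frac, per_frac$patient_id)
  out <- lapply(sp, function(g) {
    s <- summarize_schedule(g$solar)
    s$day_length_mean <- mean(g$dl)
    s$max_elevation_mean <- mean(g$elev)
    s
  })
  res <- do.call(rbind, out)
  res$patient_id <- names(sp)
  res
}

parse_clock_time <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.numeric(p[1]) + as.numeric(p[2]) / 60 +
      if (length(p) > 2) as.numeric(p[3]) / 3600 else 0
  }, numeric(1))
}
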