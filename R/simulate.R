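#' Configuration of the synthetic multi-site cohort generator
#'
#' Defaults emulate the published structure of the European breast
#' radiotherapy cohort: the eight recruiting centres with their printed
#' geography, per-site sample weights and treatment-time distributions
#' (local clock hours), covariate frequencies matching the cohort summary
#' table, Hardy-Weinberg genotypes at the published allele-2 frequencies,
#' and dichotomous outcomes drawn from a logistic model with a published
#' coefficient set plus a site-level random intercept.
#'
#' @param n Total cohort size (default 1727).
#' @param model A coefficient set from [requite_coefficients()].
#' @param sites Site table joined with per-site `weight`,
#'   `mean_local_time`, `sd_local_time` columns; default
#'   [requite_site_profiles()].
#' @param snps SNP definition table ([circadian_snps()] by default).
#' @param site_sd Standard deviation of the site-level random intercept on
#'   the log-odds scale (published erythema value 0.59). Set 0 for pure
#'   fixed-effects recovery experiments.
#' @param intercept Model intercept; NULL means calibrate to
#'   `model$prevalence` via [calibrate_intercept()] at generation time.
#' @param site_effects Optional fixed vector of site-level intercept
#'   shifts (log-odds), one per site row. NULL with `site_sd > 0` means
#'   the effects are drawn once, before intercept calibration, so that the
#'   realized cohort prevalence still matches the target -- centres are
#'   fixed entities, not redrawn per cohort.
#' @param jitter_meanlog,jitter_sdlog Log-normal parameters of the
#'   per-patient fraction-time jitter SD (hours); the defaults put ~20% of
#'   patients above the 2 h spread-exclusion threshold.
#' @param year Calendar year the treatment courses are drawn from.
#' @param site_confounding If TRUE, adds site-specific BMI shifts so that
#'   covariates are confounded with centre (used to exercise the
#'   mixed-model confirmation step); default FALSE.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 1727,
                          model = requite_coefficients("atrophy_base"),
                          sites = requite_site_profiles(),
                          snps = circadian_snps(),
                          site_sd = 0.59,
                          intercept = NULL,
                          site_effects = NULL,
                          jitter_meanlog = log(1.22),
                          jitter_sdlog = 0.6,
                          year = 2015,
                          site_confounding = FALSE) {
  stopifnot(n >= 1, model$prevalence > 0, model$prevalence < 1,
            site_sd >= 0,
            is.null(site_effects) || length(site_effects) == nrow(sites))
  structure(
    list(n = n, model = model, sites = sites, snps = snps,
         site_sd = site_sd, intercept = intercept,
         site_effects = site_effects,
         jitter_meanlog = jitter_meanlog, jitter_sdlog = jitter_sdlog,
         year = year, site_confounding = site_confounding),
    class = "cohort_config"
  )
}

#' Site geography plus treatment-time and size profiles
#'
#' [requite_sites()] augmented with each centre's published share of the
#' cohort and the mean (SD) of per-patient mean local treatment times.
#'
#' @return Tibble with `weight`, `mean_local_time`, `sd_local_time` added.
#' @export
requite_site_profiles <- function() {
  s <- requite_sites()
  s$weight <- c(193, 295, 343, 252, 37, 102, 405, 100)
  s$mean_local_time <- c(13.89, 11.75, 12.60, 11.76, 10.49, 12.40,
                         12.94, 14.83)
  s$sd_local_time <- c(3.60, 1.76, 1.89, 2.02, 1.72, 2.38, 3.18, 3.34)
  s
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# weekday-index helpers (index counts Mon-Fri since Monday 2001-01-01);
# consecutive weekday sequences then skip weekends exactly.
wday_index_to_date <- function(w) {
  as.Date("2001-01-01") + 7L * (w %/% 5L) + (w %% 5L)
}

date_to_wday <- function(date) {
  d <- as.integer(as.Date(date) - as.Date("2001-01-01"))
  5L * (d %/% 7L) + pmin(d %% 7L, 4L)
}

# Draw covariates, fraction schedules and genotypes (everything except the
# outcome) for n patients. Returns the analysis-level truth covariates and
# the raw patient/fraction tables.
sim_covariates <- function(config, n) {
  s <- config$sites
  site_idx <- sample(nrow(s), n, replace = TRUE,
                     prob = s$weight / sum(s$weight))

  mean_local <- rtruncnorm(n, s$mean_local_time[site_idx],
                           s$sd_local_time[site_idx], 6, 20)
  sigma <- stats::rlnorm(n, config$jitter_meanlog, config$jitter_sdlog)
  n_frac <- sample(15:25, n, replace = TRUE)

  # consecutive weekday fraction dates starting on a random weekday
  start <- as.Date(sprintf("%d-01-01", config$year)) +
    sample.int(330, n, replace = TRUE)
  w0 <- date_to_wday(start)
  pid_row <- rep.int(seq_len(n), n_frac)
  frac_date <- wday_index_to_date(w0[pid_row] +
                                    sequence(n_frac) - 1L)
  frac_local <- pmin(21, pmax(
    5, mean_local[pid_row] + stats::rnorm(length(pid_row),
                                          0, sigma[pid_row])))

  frac_sites <- s[site_idx[pid_row], ]
  solar <- local_to_solar(frac_date, frac_local, frac_sites)
  mean_solar <- as.numeric(rowsum(solar, pid_row)) / n_frac
  sd_solar <- sqrt(pmax(0,
    (as.numeric(rowsum(solar^2, pid_row)) -
       n_frac * mean_solar^2) / (n_frac - 1)))

  bmi <- rtruncnorm(n, 26.4, 5.6, 15, 55)
  if (config$site_confounding) {
    shift <- stats::rnorm(nrow(s), 0, 2)
    bmi <- bmi + shift[site_idx]
  }
  dose <- rtruncnorm(n, 2.35, 0.25, 1.8, 3.2)
  boost <- stats::rbinom(n, 1, 0.67)
  boost_n <- ifelse(boost == 1, sample(4:8, n, replace = TRUE), 0)
  boost_d <- ifelse(boost == 1, 2.0, NA_real_)
  ab <- default_alpha_beta(config$model$endpoint)
  bed <- compute_bed(n_frac, dose, ab, boost_n,
                     ifelse(boost == 1, 2.0, dose))
  surgery <- factor(
    sample(c("seg_quad", "wle"), n, replace = TRUE, prob = c(0.49, 0.51)),
    levels = c("seg_quad", "wle")
  )

  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    site_name = s$name[site_idx],
    age = round(rtruncnorm(n, 58, 11, 25, 90)),
    bmi = bmi,
    diabetes = stats::rbinom(n, 1, 0.061),
    smoking = factor(
      sample(c("never", "ex_before", "ex_since", "current"), n,
             replace = TRUE, prob = c(0.553, 0.261, 0.043, 0.143)),
      levels = c("never", "ex_before", "ex_since", "current")
    ),
    menopausal = factor(
      sample(c("post", "pre", "peri"), n, replace = TRUE,
             prob = c(0.688, 0.238, 0.075)),
      levels = c("post", "pre", "peri")
    ),
    surgery = surgery,
    imrt = stats::rbinom(n, 1, 0.52),
    neoadj_anthra = stats::rbinom(n, 1, 0.080),
    neoadj_non_anthra = stats::rbinom(n, 1, 0.089),
    adj_anthra = stats::rbinom(n, 1, 0.204),
    adj_non_anthra = stats::rbinom(n, 1, 0.217),
    n_fractions = n_frac,
    dose_per_fraction = dose,
    boost_n_fractions = boost_n,
    boost_dose_per_fraction = boost_d,
    baseline_erythema = stats::rbinom(n, 1, 0.068),
    baseline_atrophy = sample(0:2, n, replace = TRUE,
                              prob = c(0.848, 0.100, 0.052))
  )

  geno <- lapply(config$snps$allele2_freq, function(q) {
    sample(0:2, n, replace = TRUE, prob = hwe_genotype_probs(q))
  })
  names(geno) <- config$snps$rsid
  genotypes <- tibble::as_tibble(
    c(list(patient_id = patients$patient_id), geno))

  fractions <- tibble::tibble(
    patient_id = patients$patient_id[pid_row],
    site_name = patients$site_name[pid_row],
    date = frac_date,
    local_time = frac_local
  )

  list(
    patients = patients, fractions = fractions, genotypes = genotypes,
    truth_cov = tibble::tibble(
      patient_id = patients$patient_id, site_idx = site_idx,
      mean_solar_time = mean_solar, sd_solar_time = sd_solar,
      bmi = bmi, bed = bed, surgery_wle = as.integer(surgery == "wle")
    )
  )
}

# Linear predictor without intercept or site effect, from the truth
# covariates and genotype table.
truth_eta <- function(config, cov, genotypes) {
  m <- config$model
  eta <- numeric(nrow(cov))
  time_dist <- abs(cov$mean_solar_time - m$origin)
  covs <- list(
    bmi = cov$bmi, bed = cov$bed, surgery_wle = cov$surgery_wle,
    time_distance = time_dist,
    mean_solar_time = cov$mean_solar_time,
    sd_solar_time = cov$sd_solar_time
  )
  for (term in names(m$terms)) {
    if (is.null(covs[[term]])) {
      stop("generating coefficient references unknown covariate: ", term,
           call. = FALSE)
    }
    eta <- eta + m$terms[[term]] * covs[[term]]
  }
  if (!is.null(m$snp)) {
    g <- if (isTRUE(m$snp$composite)) {
      comp <- config$snps$rsid[config$snps$composite]
      unweighted_prs(genotypes[, comp, drop = FALSE])
    } else {
      genotypes[[m$snp$col]]
    }
    eta <- eta + m$snp$main * g + m$snp$interaction * g * time_dist
  }
  eta
}

# Exclusion mask matching the pipeline's baseline + spread rules.
truth_included <- function(config, patients, cov) {
  if (config$model$endpoint == "erythema") {
    base_ok <- patients$baseline_erythema == 0
  } else {
    base_ok <- patients$baseline_atrophy <= 1
  }
  base_ok & cov$sd_solar_time <= 2
}

#' Calibrate the generator intercept to a target prevalence
#'
#' Draws a large covariate-only cohort from the config and root-finds the
#' intercept at which the post-exclusion marginal outcome prevalence
#' equals the target (Monte-Carlo over >= 100,000 patients, accurate to
#' well under half a percentage point).
#'
#' @param config A [cohort_config()].
#' @param target Target prevalence; defaults to the model's published
#'   prevalence.
#' @param n_mc Monte-Carlo cohort size.
#' @param seed Integer seed for the calibration draw.
#' @return Intercept on the log-odds scale.
#' @export
calibrate_intercept <- function(config, target = NULL, n_mc = 100000,
                                seed = 1) {
  if (is.null(target)) target <- config$model$prevalence
  stopifnot(target > 0, target < 1)
  withr::with_seed(seed, {
    sim <- sim_covariates(config, n_mc)
    eta <- truth_eta(config, sim$truth_cov, sim$genotypes)
    if (!is.null(config$site_effects)) {
      eta <- eta + config$site_effects[sim$truth_cov$site_idx]
    } else if (config$site_sd > 0) {
      # no fixed effects supplied: integrate over the site distribution
      eta <- eta + stats::rnorm(n_mc, 0, config$site_sd)
    }
    keep <- truth_included(config, sim$patients, sim$truth_cov)
    eta <- eta[keep]
    stats::uniroot(function(b0) mean(stats::plogis(b0 + eta)) - target,
                   c(-40, 40), tol = 1e-8)$root
  })
}

#' Fill in fixed site effects and a calibrated intercept
#'
#' Draws the site-level intercept shifts once (if `site_sd > 0` and none
#' were supplied) and then calibrates the intercept conditional on them,
#' so that cohorts generated from the returned config have the target
#' prevalence despite the between-site heterogeneity.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the site-effect draw and calibration.
#' @param n_mc Monte-Carlo size passed to [calibrate_intercept()].
#' @return The config with `site_effects` and `intercept` set.
#' @export
calibrated_config <- function(config, seed = 1, n_mc = 100000) {
  if (is.null(config$site_effects) && config$site_sd > 0) {
    config$site_effects <- withr::with_seed(
      bitwXor(as.integer(seed), 1234567L),
      stats::rnorm(nrow(config$sites), 0, config$site_sd)
    )
  }
  config$intercept <- calibrate_intercept(config, n_mc = n_mc, seed = seed)
  config
}

#' Generate a synthetic multi-site cohort
#'
#' Draws patients, per-fraction radiotherapy schedules (consecutive
#' weekdays, per-patient mean local time from the site's distribution,
#' per-fraction jitter controlling the schedule spread), Hardy-Weinberg
#' genotypes, and Bernoulli outcomes from the config's logistic model with
#' a site-level random intercept. Deterministic given the seed. The
#' output tables round-trip through [prepare_cohort()] unchanged, and a
#' truth record carries the generating coefficients, intercept, site
#' effects and seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of tibbles `patients`, `fractions`, `genotypes`, `sites`,
#'   plus `truth` (list: `intercept`, `coefficients`, `site_effects`,
#'   `eta`, `seed`, `config`).
#' @export
simulate_cohort <- function(config, seed = 1) {
  if (is.null(config$intercept)) {
    config <- calibrated_config(
      config, seed = bitwXor(as.integer(seed), 7654321L))
  }
  b0 <- config$intercept
  withr::with_seed(seed, {
    sim <- sim_covariates(config, config$n)
    eta0 <- truth_eta(config, sim$truth_cov, sim$genotypes)
    u <- if (!is.null(config$site_effects)) {
      config$site_effects
    } else if (config$site_sd > 0) {
      stats::rnorm(nrow(config$sites), 0, config$site_sd)
    } else {
      rep(0, nrow(config$sites))
    }
    eta <- b0 + eta0 + u[sim$truth_cov$site_idx]
    y <- stats::rbinom(config$n, 1, stats::plogis(eta))

    p <- sim$patients
    if (config$model$endpoint == "erythema") {
      p$followup_erythema <- ifelse(
        y == 1, 2L, sample(0:1, config$n, replace = TRUE))
      p$atrophy_24m <- p$baseline_atrophy # untouched endpoint
    } else {
      p$atrophy_24m <- pmin(4L, p$baseline_atrophy + y)
      p$followup_erythema <- ifelse(
        stats::rbinom(config$n, 1, 0.2) == 1, 2L,
        sample(0:1, config$n, replace = TRUE))
    }

    list(
      patients = p,
      fractions = sim$fractions,
      genotypes = sim$genotypes,
      sites = config$sites,
      truth = list(
        intercept = b0,
        coefficients = config$model,
        site_effects = stats::setNames(u, config$sites$name),
        eta = eta,
        outcome = y,
        mean_solar_time = sim$truth_cov$mean_solar_time,
        seed = seed
      )
    )
  })
}
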