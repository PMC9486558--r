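# Brute-force Newton-Raphson logistic MLE, written independently of
# stats::glm, used as the dual-route oracle for fit_logistic().
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - p)
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# Small random dataset with two continuous predictors.
random_logistic_data <- function(n = 80, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    x2 <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * x1 - 0.5 * x2))
    tibble::tibble(outcome = y, x1 = x1, x2 = x2)
  })
}

# 2x2 table expanded to unit records: a/b exposed cases/controls,
# c/d unexposed cases/controls.
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    outcome = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)),
    x = c(rep(1, a + b), rep(0, c + d))
  )
}

# Calibrated generator configs are expensive (~5 s each); cache them per
# coefficient set so every test file can reuse the same calibration.
.calib_cache <- new.env(parent = emptyenv())

calibrated_cfg <- function(model, n, site_sd = 0, seed = 1) {
  key <- paste(model, site_sd, seed, sep = "|")
  if (is.null(.calib_cache[[key]])) {
    cfg <- cohort_config(n = n, model = requite_coefficients(model),
                         site_sd = site_sd)
    .calib_cache[[key]] <- calibrated_config(cfg, seed = seed)
  }
  cfg <- .calib_cache[[key]]
  cfg$n <- n
  cfg
}

# Generate, preprocess and merge genotypes: an analysis-ready table plus
# the raw simulation and prep objects.
sim_analysis_data <- function(model = "atrophy_base", n = 2000, seed = 1,
                              site_sd = 0) {
  cfg <- calibrated_cfg(model, n, site_sd = site_sd)
  m <- cfg$model
  sim <- simulate_cohort(cfg, seed = seed)
  prep <- prepare_cohort(sim$patients, sim$fractions, sim$sites,
                         endpoint = m$endpoint, origin = m$origin)
  d <- tibble::as_tibble(merge(prep$data, sim$genotypes,
                               by = "patient_id"))
  snps <- circadian_snps()
  d$prs3 <- unweighted_prs(d[, snps$rsid[snps$composite], drop = FALSE])
  list(data = d, sim = sim, prep = prep, model = m, config = cfg)
}
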