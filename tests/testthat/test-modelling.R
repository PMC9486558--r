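test_that("fit_logistic equals a brute-force Newton oracle on random data", {
  for (s in 1:10) {
    d <- random_logistic_data(n = 80, seed = s)
    fit <- fit_logistic(outcome ~ x1 + x2, d)
    oracle <- newton_logistic(cbind(1, d$x1, d$x2), d$outcome)
    expect_equal(unname(stats::coef(fit$model)), oracle, tolerance = 1e-6)
  }
})

test_that("the 2x2 odds ratio equals the cross-product ratio", {
  d <- expand_2x2(20, 30, 15, 35)
  fit <- fit_logistic(outcome ~ x, d)
  expect_equal(fit$tidy$or[fit$tidy$term == "x"], (20 * 35) / (30 * 15),
               tolerance = 1e-8)
})

test_that("an intercept-only fit recovers the logit prevalence", {
  d <- tibble::tibble(outcome = rep(c(0L, 1L), c(70, 30)))
  fit <- fit_logistic(outcome ~ 1, d)
  expect_equal(fit$tidy$estimate[1], stats::qlogis(0.3), tolerance = 1e-8)
})

test_that("tidy output satisfies its own algebra", {
  d <- random_logistic_data(n = 120, seed = 3)
  fit <- fit_logistic(outcome ~ x1 + x2, d)
  t <- fit$tidy
  expect_equal(t$or, exp(t$estimate))
  expect_equal(t$ci_lo, exp(t$estimate - 1.96 * t$se))
  expect_equal(t$ci_hi, exp(t$estimate + 1.96 * t$se))
  expect_true(all(t$p >= 0 & t$p <= 1))
  k <- length(stats::coef(fit$model))
  expect_equal(fit$aic, 2 * k - 2 * fit$loglik, tolerance = 1e-9)
  expect_equal(fit$n, nrow(d))
})

test_that("degenerate designs are surfaced as errors", {
  withr::with_seed(5, {
    x <- stats::rnorm(60)
    sep <- tibble::tibble(outcome = as.integer(x > 0), x = x)
  })
  expect_error(fit_logistic(outcome ~ x, sep), "separation")
  d <- random_logistic_data(n = 60, seed = 6)
  d$x3 <- d$x1
  expect_error(fit_logistic(outcome ~ x1 + x2 + x3, d), "collinear")
  d$outcome <- 1L
  expect_error(fit_logistic(outcome ~ x1, d), "single class")
})

test_that("latent ICC follows the logistic-variance formula", {
  expect_equal(latent_icc(0), 0)
  expect_equal(latent_icc(0.59), 0.59^2 / (0.59^2 + pi^2 / 3))
  expect_lt(abs(latent_icc(0.59) - 0.096), 5e-4)
  expect_gt(latent_icc(100), 0.999)
  expect_true(latent_icc(1) > latent_icc(0.5))
  expect_error(latent_icc(-1))
})

test_that("with no real site heterogeneity the mixed model collapses to the GLM", {
  h <- sim_analysis_data("atrophy_base", n = 2000, seed = 4, site_sd = 0)
  f <- outcome ~ bmi + bed + surgery + time_distance
  mm <- suppressMessages(fit_mixed_logistic(f, h$data))
  gg <- fit_logistic(f, h$data)
  expect_lt(mm$ranef_sd, 0.15)
  expect_lt(max(abs(mm$tidy$estimate - gg$tidy$estimate)), 0.03)
  expect_equal(mm$icc, latent_icc(mm$ranef_sd))
})

test_that("the mixed model recovers a generating site SD of 0.59", {
  h <- sim_analysis_data("atrophy_base", n = 1727, seed = 2, site_sd = 0.59)
  mm <- suppressWarnings(suppressMessages(
    fit_mixed_logistic(outcome ~ bmi + bed + surgery + time_distance,
                       h$data)))
  # ~3 analytic s.e. of an SD estimated from 8 sites
  expect_gt(mm$ranef_sd, 0.12)
  expect_lt(mm$ranef_sd, 1.06)
})

test_that("the mixed model requires at least two sites", {
  h <- sim_analysis_data("atrophy_base", n = 300, seed = 4)
  d <- h$data
  d$site_name <- "only"
  expect_error(fit_mixed_logistic(outcome ~ bmi, d), "at least 2 sites")
})

test_that("augment_with_snp adds the dosage and interaction terms", {
  h <- sim_analysis_data("atrophy_clock", n = 2500, seed = 5)
  base <- fit_logistic(outcome ~ bmi + bed + surgery + time_distance,
                       h$data, origin = 15.5)
  fit <- augment_with_snp(base, h$data, "rs1801260")
  labs <- attr(stats::terms(fit$model), "term.labels")
  expect_true("rs1801260" %in% labs)
  # terms() may canonicalize the interaction's factor order
  expect_true(any(labs %in% c("rs1801260:time_distance",
                              "time_distance:rs1801260")))
  expect_equal(fit$origin, 15.5)
  main_only <- augment_with_snp(base, h$data, "rs1801260",
                                interaction = FALSE)
  labs2 <- attr(stats::terms(main_only$model), "term.labels")
  expect_true("rs1801260" %in% labs2)
  expect_false(any(grepl(":", labs2)))
  expect_error(augment_with_snp(c("bmi"), h$data, "rs1801260"),
               "time term")
})

test_that("stepwise selection keeps real effects and honors forced terms", {
  h <- sim_analysis_data("atrophy_base", n = 4000, seed = 11)
  cand <- c("bmi", "bed", "surgery", "time_distance", "age", "diabetes",
            "imrt")
  fit <- stepwise_select(h$data, cand, forced = "time_distance",
                         origin = 15.5)
  labs <- attr(stats::terms(fit$model), "term.labels")
  expect_true(all(c("bmi", "bed", "surgery", "time_distance") %in% labs))
  # accepted stepwise moves strictly improve AIC until the pruning stage
  tr <- attr(fit, "trace")
  pre <- tr$aic[tr$move != "prune"]
  if (length(pre) > 1) expect_true(all(diff(pre) < 0))
  # every droppable survivor is significant after pruning
  for (t in setdiff(labs, "time_distance")) {
    expect_lt(chronotox:::wald_term_p(fit$model, t), 0.05)
  }
  expect_equal(fit$origin, 15.5)
})

test_that("a forced term survives even with no effect", {
  d <- random_logistic_data(n = 300, seed = 13)
  withr::with_seed(14, d$noise <- stats::rnorm(300))
  fit <- stepwise_select(d, c("x1", "x2", "noise"), forced = "noise")
  expect_true("noise" %in% attr(stats::terms(fit$model), "term.labels"))
})

test_that("the time-origin scan minimizes AIC on its own profile", {
  h <- sim_analysis_data("atrophy_base", n = 800, seed = 15)
  sc <- scan_time_origin(h$data,
                         c("bmi", "bed", "surgery", "time_distance"),
                         grid_step = 2)
  expect_s3_class(sc, "time_scan")
  expect_equal(sc$best_aic, min(sc$profile$aic, na.rm = TRUE))
  expect_equal(sc$best_origin,
               sc$profile$origin[which(sc$profile$aic == sc$best_aic)][1])
  expect_error(scan_time_origin(h$data, c("bmi"), grid_step = 2),
               "time_distance")
  expect_error(scan_time_origin(h$data, c("bmi", "time_distance"),
                                grid_step = 7), "divide 24")
})

test_that("the scan profile is flat on a permuted-outcome cohort", {
  h <- sim_analysis_data("atrophy_base", n = 1500, seed = 16)
  d <- h$data
  withr::with_seed(17, d$outcome <- sample(d$outcome))
  sc <- scan_time_origin(d, c("bmi", "bed", "surgery", "time_distance"),
                         grid_step = 1)
  expect_lt(diff(range(sc$profile$aic, na.rm = TRUE)), 15)
})

test_that("the scan localizes a strong planted peak on a coarse grid", {
  h <- sim_analysis_data("atrophy_prs", n = 3000, seed = 18)
  sc <- scan_time_origin(
    h$data,
    c("bmi", "bed", "surgery", "time_distance", "prs3",
      "prs3:time_distance"),
    grid_step = 2
  )
  expect_true(sc$best_origin %in% c(14, 16))
})
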