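test_that("BED follows the linear-quadratic closed form", {
  expect_lt(abs(compute_bed(15, 2.667, alpha_beta = 3) - 75.57), 0.01)
  expect_lt(abs(compute_bed(15, 2.667, alpha_beta = 10) - 50.67), 0.01)
  # boost course adds its own LQ term
  expect_equal(compute_bed(15, 2.667, 3, boost_n_fractions = 8,
                           boost_dose_per_fraction = 2),
               compute_bed(15, 2.667, 3) + 8 * 2 * (1 + 2 / 3),
               tolerance = 1e-12)
  # boost defaults to the main-course dose per fraction
  expect_equal(compute_bed(15, 2, 3, boost_n_fractions = 5),
               compute_bed(15, 2, 3, boost_n_fractions = 5,
                           boost_dose_per_fraction = 2))
})

test_that("BED tends to the physical dose as dose per fraction shrinks", {
  expect_lt(abs(compute_bed(10000, 0.005, alpha_beta = 3) - 50), 0.1)
})

test_that("BED is monotone in dose and inversely in alpha/beta", {
  expect_gt(compute_bed(15, 2.5, 3), compute_bed(15, 2.0, 3))
  expect_gt(compute_bed(20, 2, 3), compute_bed(15, 2, 3))
  expect_gt(compute_bed(15, 2, 3), compute_bed(15, 2, 10))
})

test_that("BED rejects non-physical inputs", {
  expect_error(compute_bed(15, -1, 3), "positive")
  expect_error(compute_bed(0, 2, 3), "positive")
  expect_error(compute_bed(15, 2, 0), "alpha_beta")
  expect_error(compute_bed(15, 2, 3, boost_n_fractions = 4,
                           boost_dose_per_fraction = 0), "boost")
})

test_that("schedule summaries use mean and sample SD", {
  s <- summarize_schedule(c(10, 12, 14))
  expect_equal(s$mean_solar_time, 12)
  expect_equal(s$sd_solar_time, 2)
  expect_equal(s$n_fractions_timed, 3L)
  one <- summarize_schedule(9.5)
  expect_equal(one$sd_solar_time, 0)
  expect_equal(one$n_fractions_timed, 1L)
  na <- summarize_schedule(c(11, NA, 13))
  expect_equal(na$n_fractions_timed, 2L)
  expect_error(summarize_schedule(NA_real_), "no timed fractions")
})

test_that("time distance is a plain absolute difference", {
  expect_equal(time_distance(16.5, 15.5), 1)
  expect_equal(time_distance(10, 15.5), 5.5)
  expect_equal(time_distance(0.5, 0), 0.5)
  expect_equal(time_distance(c(14, 17), 15.5), c(1.5, 1.5))
  expect_error(time_distance(25, 15.5))
  expect_error(time_distance(12, -1))
})

test_that("erythema dichotomization excludes baseline cases and cuts at grade 2", {
  r <- dichotomize_erythema(baseline = c(0, 0, 1, 0, NA),
                            followup = c(2, 1, 2, NA, 1))
  expect_equal(r$outcome, c(1L, 0L, NA, NA, NA))
  expect_equal(r$status, c("included", "included", "baseline_excluded",
                           "missing", "missing"))
})

test_that("atrophy dichotomization scores deterioration with the baseline rule", {
  r <- dichotomize_atrophy(baseline = c(1, 1, 2, 0), grade_24m = c(2, 1, 3, 1))
  expect_equal(r$outcome, c(1L, 0L, NA, 1L))
  expect_equal(r$status[3], "baseline_excluded")
  # sensitivity variant excludes any baseline atrophy
  s <- dichotomize_atrophy(baseline = c(1, 0), grade_24m = c(2, 1),
                           sensitivity = TRUE)
  expect_equal(s$status, c("baseline_excluded", "included"))
  expect_equal(s$outcome, c(NA_integer_, 1L))
})

test_that("half grades are rejected", {
  expect_error(dichotomize_erythema(0.5, 2), "half grades")
  expect_error(dichotomize_atrophy(0, 2.5), "half grades")
})

toy_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    baseline_atrophy = c(2, 3, 0, 0, rep(0, 6)),
    atrophy_24m =      c(3, 3, 1, 1, 1, 0, 1, 0, 1, 0),
    sd_solar_time =    c(1, 3, 2.5, 1, 1, 2, 1, 1, 1, 1),
    bmi =              c(25, 25, 25, NA, 24, 27, 23, 26, 28, 22)
  )
}

test_that("exclusions are counted once, in baseline -> spread -> completeness order", {
  r <- apply_exclusions(toy_cohort(), "atrophy", required = "bmi")
  expect_equal(unname(r$report), c(10L, 2L, 1L, 1L, 6L))
  expect_equal(names(r$report),
               c("n_input", "baseline", "sd_over_limit", "incomplete",
                 "n_analysis"))
  # P02 fails baseline AND spread but is counted under baseline only
  expect_false("P02" %in% r$data$patient_id)
  # a spread of exactly 2 h is retained (rule is strict >)
  expect_true("P06" %in% r$data$patient_id)
})

test_that("exclusions are idempotent", {
  r1 <- apply_exclusions(toy_cohort(), "atrophy", required = "bmi")
  r2 <- apply_exclusions(r1$data, "atrophy", required = "bmi")
  expect_equal(r2$report[["n_analysis"]], r1$report[["n_analysis"]])
  expect_equal(unname(r2$report[c("baseline", "sd_over_limit",
                                  "incomplete")]), c(0L, 0L, 0L))
  expect_equal(r2$data$patient_id, r1$data$patient_id)
})

test_that("an empty analysis set is an error", {
  c0 <- toy_cohort()
  c0$sd_solar_time <- 5
  c0$baseline_atrophy[1:2] <- 0
  expect_error(apply_exclusions(c0, "atrophy"), "all patients excluded")
})

test_that("endpoint defaults are the published conventions", {
  expect_equal(default_alpha_beta("erythema"), 10)
  expect_equal(default_alpha_beta("atrophy"), 3)
  expect_equal(default_origin("erythema"), 0)
  expect_equal(default_origin("atrophy"), 15.5)
})

test_that("prepare_cohort assembles the analysis table end to end", {
  h <- sim_analysis_data("atrophy_base", n = 400, seed = 7)
  d <- h$prep$data
  expect_true(all(c("bed", "mean_solar_time", "sd_solar_time",
                    "time_distance", "day_length_mean",
                    "max_elevation_mean", "latitude", "outcome")
                  %in% names(d)))
  expect_true(all(d$bed > 0))
  expect_true(all(d$sd_solar_time <= 2))
  expect_equal(d$time_distance, abs(d$mean_solar_time - 15.5),
               tolerance = 1e-12)
  expect_true(all(d$outcome %in% 0:1))
  # alpha/beta switches with the endpoint: acute BED is much smaller
  ery <- prepare_cohort(h$sim$patients, h$sim$fractions, h$sim$sites,
                        endpoint = "erythema", origin = 0)
  shared <- intersect(ery$data$patient_id, d$patient_id)
  expect_true(mean(ery$data$bed[match(shared, ery$data$patient_id)]) <
                mean(d$bed[match(shared, d$patient_id)]))
})

test_that("prepare_cohort rejects fractions at unknown sites", {
  h <- sim_analysis_data("atrophy_base", n = 50, seed = 8)
  fr <- h$sim$fractions
  fr$site_name[1] <- "Atlantis"
  expect_error(prepare_cohort(h$sim$patients, fr, h$sim$sites,
                              endpoint = "atrophy"), "Atlantis")
})

test_that("HH:MM clock strings parse to the same solar times as decimals", {
  h <- sim_analysis_data("atrophy_base", n = 30, seed = 9)
  fr <- h$sim$fractions
  fr2 <- fr
  fr2$local_time <- sprintf("%02d:%02d", floor(fr$local_time),
                            round((fr$local_time %% 1) * 60))
  fr$local_time <- floor(fr$local_time) + round((fr$local_time %% 1) * 60) / 60
  p1 <- prepare_cohort(h$sim$patients, fr, h$sim$sites, "atrophy")
  p2 <- prepare_cohort(h$sim$patients, fr2, h$sim$sites, "atrophy")
  expect_equal(p1$data$mean_solar_time, p2$data$mean_solar_time,
               tolerance = 1e-9)
})
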