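test_that("solar declination hits the solstices and equinox", {
  expect_lt(abs(solar_declination(172) - 23.44), 0.05)
  expect_lt(abs(solar_declination(355) + 23.44), 0.05)
  expect_lt(abs(solar_declination(80)), 1)
  expect_length(solar_declination(c(172, 355)), 2)
})

test_that("equation of time matches its known extremes and integrates to ~0", {
  expect_lt(abs(equation_of_time(42) + 14.2), 1)
  expect_gt(equation_of_time(307), 15)
  expect_lt(equation_of_time(307), 17)
  expect_lt(abs(mean(equation_of_time(1:365))), 0.5)
})

test_that("day-of-year inputs are validated", {
  expect_error(solar_declination(0), "1..366")
  expect_error(solar_declination(367), "1..366")
  expect_error(equation_of_time(NA_real_), "1..366")
})

test_that("EU daylight-saving rule switches on the last Sundays", {
  expect_false(eu_dst_active(as.Date("2015-03-28")))
  expect_true(eu_dst_active(as.Date("2015-03-29")))
  expect_true(eu_dst_active(as.Date("2015-10-24")))
  expect_false(eu_dst_active(as.Date("2015-10-25")))
  # 2016 transitions fall on different dates
  expect_false(eu_dst_active(as.Date("2016-03-26")))
  expect_true(eu_dst_active(as.Date("2016-03-27")))
  expect_false(eu_dst_active(as.Date("2016-10-30")))
})

test_that("Milan summer clock time runs ~90 minutes ahead of solar time", {
  milan <- geo_site("Milan", 45.5, 9.2, utc_base_offset = 1)
  solar <- local_to_solar(as.Date("2015-07-24"), 10, milan)
  diff_min <- (10 - solar) * 60
  expect_gt(diff_min, 85)
  expect_lt(diff_min, 100)
})

test_that("conversion is a pure shift within one site-day", {
  site <- geo_site("X", 48, 5, utc_base_offset = 1)
  d <- as.Date("2015-05-11")
  t <- c(7.25, 9.5, 12, 15.75)
  s <- local_to_solar(d, t, site)
  expect_equal(diff(s), diff(t), tolerance = 1e-12)
  expect_equal(local_to_solar(d, 9, site) - local_to_solar(d, 6, site), 3,
               tolerance = 1e-12)
})

test_that("at longitude 15 east, UTC+1, no DST, clock time is solar time when the equation of time vanishes", {
  site <- geo_site("Meridian", 50, 15, utc_base_offset = 1,
                   dst_offset = 0, dst_rule = "none")
  doy <- which.min(abs(equation_of_time(1:365)))
  d <- as.Date(doy - 1, origin = "2015-01-01")
  expect_lt(abs(local_to_solar(d, 12, site) - 12), 0.01)
})

test_that("explicit utc_offset overrides site resolution consistently", {
  milan <- geo_site("Milan", 45.5, 9.2, utc_base_offset = 1)
  d <- as.Date("2015-01-15") # winter: offset is the base offset
  expect_equal(local_to_solar(d, 10, milan),
               local_to_solar(d, 10, milan, utc_offset = 1))
  d2 <- as.Date("2015-07-15") # summer: base + 1
  expect_equal(local_to_solar(d2, 10, milan),
               local_to_solar(d2, 10, milan, utc_offset = 2))
})

test_that("unknown DST rules and bad clock times are rejected", {
  odd <- tibble::tibble(name = "odd", latitude = 40, longitude = 0,
                        utc_base_offset = -5, dst_offset = 1,
                        dst_rule = "US")
  expect_error(local_to_solar(as.Date("2015-06-01"), 10, odd),
               "unknown DST rule")
  # ... but an explicit offset sidesteps rule resolution
  expect_silent(local_to_solar(as.Date("2015-06-01"), 10, odd,
                               utc_offset = -4))
  milan <- geo_site("Milan", 45.5, 9.2, utc_base_offset = 1)
  expect_error(local_to_solar(as.Date("2015-06-01"), 24, milan),
               "clock_time")
})

test_that("day length reproduces temperate-latitude reference points", {
  expect_lt(abs(day_length(as.Date("2015-12-21"), 52.6) - 7.6), 0.1)
  expect_lt(abs(day_length(as.Date("2015-06-21"), 41.4) - 15.2), 0.1)
  eq <- day_length(as.Date("2015-03-20"), 0)
  expect_gt(eq, 12)    # refraction + semidiameter lengthen the day
  expect_lt(eq, 12.3)
})

test_that("polar day and night are flagged, not errors", {
  dn <- day_length(as.Date("2015-12-21"), 80)
  expect_equal(as.numeric(dn), 0)
  expect_true(attr(dn, "polar"))
  dd <- day_length(as.Date("2015-06-21"), 80)
  expect_equal(as.numeric(dd), 24)
  expect_true(attr(dd, "polar"))
  ok <- day_length(as.Date("2015-06-21"), 45)
  expect_false(attr(ok, "polar"))
})

test_that("winter and summer day lengths are complementary up to the horizon convention", {
  for (lat in c(40, 45, 50, 55)) {
    s <- as.numeric(day_length(as.Date("2015-06-21"), lat)) +
      as.numeric(day_length(as.Date("2015-12-21"), lat))
    expect_gt(s, 24)    # both halves gain from the 90.833 deg zenith
    expect_lt(s, 24.6)
  }
})

test_that("December day length decreases with latitude in [0, 60]", {
  dl <- vapply(seq(0, 60, by = 5),
               function(l) as.numeric(day_length(as.Date("2015-12-21"), l)),
               numeric(1))
  expect_true(all(diff(dl) < 0))
})

test_that("maximum solar elevation follows the closed form", {
  expect_lt(abs(max_solar_elevation(172, 23.44) - 90), 0.1)
  expect_lt(abs(max_solar_elevation(172, 52.6) - 60.8), 0.1)
  expect_lt(abs(max_solar_elevation(355, 52.6) - 13.96), 0.1)
  # lower latitude, higher sun on the same date
  expect_gt(max_solar_elevation(355, 41.4), max_solar_elevation(355, 52.6))
})
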