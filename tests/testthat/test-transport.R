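# Water-mass classification and section transport diagnostics.

test_that("water-mass classification follows the printed criteria", {
  crit <- water_mass_criteria()
  expect_equal(classify_water_mass(5, 35.0, 71, crit), "AW")
  expect_equal(classify_water_mass(2, 35.0, 71, crit), "OTHER")
  expect_equal(classify_water_mass(8, 34.0, 71, crit), "CW")
  expect_equal(classify_water_mass(8, 34.0, 73, crit), "OTHER")
  # values exactly at a threshold go to OTHER (strict inequalities)
  expect_equal(classify_water_mass(3, 35.0, 71, crit), "OTHER")
  expect_equal(classify_water_mass(5, 34.9, 71, crit), "OTHER")
  expect_error(classify_water_mass(NaN, 35, 71, crit), "non-finite")
})

test_that("classification agrees with an exhaustive rule-table oracle", {
  crit <- water_mass_criteria()
  grid <- expand.grid(temp = c(-1, 2, 3, 3.5, 8),
                      salt = c(33, 34.8, 34.9, 34.95, 35.2),
                      lat = c(70, 72.5, 74))
  oracle <- with(grid, ifelse(temp > 3 & salt > 34.9, "AW",
                       ifelse(salt < 34.9 & lat < 72.5, "CW", "OTHER")))
  got <- classify_water_mass(grid$temp, grid$salt, grid$lat, crit)
  expect_identical(got, oracle)
  # partition: every parcel gets exactly one label
  expect_true(all(got %in% c("AW", "CW", "OTHER")))
})

test_that("section transport recovers the closed-form jet transport", {
  f <- generate_ocean_fields(jet_oracle_config(grid_km = 8))
  sec <- section_across_coast(1172, length_km = 260)
  tr <- section_transport(f, sec)
  expect_equal(tr$aw_sv[1], 1.0, tolerance = 0.01)
  expect_equal(tr$total_sv[1], tr$aw_sv[1])
})

test_that("transport is antisymmetric and linear in the velocities", {
  f <- generate_ocean_fields(jet_oracle_config(grid_km = 10))
  sec <- section_across_coast(1172, length_km = 260)
  t1 <- section_transport(f, sec)
  fneg <- ocean_fields(f$lon, f$lat, f$depth, f$time, f$temp, f$salt,
                       -f$u, -f$v, f$kz, f$land_mask)
  expect_equal(section_transport(fneg, sec)$aw_sv, -t1$aw_sv)
  fdbl <- ocean_fields(f$lon, f$lat, f$depth, f$time, f$temp, f$salt,
                       2 * f$u, 2 * f$v, f$kz, f$land_mask)
  expect_equal(section_transport(fdbl, sec)$aw_sv, 2 * t1$aw_sv,
               tolerance = 1e-10)
})

test_that("halving the grid spacing changes the jet transport < 0.5%", {
  sec <- section_across_coast(1172, length_km = 260)
  t8 <- section_transport(generate_ocean_fields(jet_oracle_config(8)), sec)
  t4 <- section_transport(generate_ocean_fields(jet_oracle_config(4)), sec)
  expect_lt(abs(t4$aw_sv - t8$aw_sv) / abs(t8$aw_sv), 0.005)
})

test_that("inflow-only accumulation never reports less than the net", {
  f <- generate_ocean_fields(jet_oracle_config(grid_km = 10))
  sec <- section_across_coast(1172, length_km = 260)
  net <- section_transport(f, sec)
  pos <- section_transport(f, sec, inflow_only = TRUE)
  expect_gte(pos$aw_sv[1] + 1e-12, net$aw_sv[1])
})

test_that("a section outside the domain or on land is rejected", {
  f <- generate_ocean_fields(jet_oracle_config(grid_km = 10))
  expect_error(section_transport(
    f, section_definition(10, 69.5, 20, 71)), "exits")
})

test_that("period_mean averages the requested months", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  const <- structure(data.frame(date = dates, aw_sv = 1.8, cw_sv = 0.9,
                                total_sv = 2.7),
                     class = c("section_transport", "data.frame"))
  pm <- period_mean(const, months = c(6, 7))
  expect_equal(unname(pm$overall["aw_sv"]), 1.8)
  expect_equal(pm$per_year$aw_sv, 1.8)
  expect_error(period_mean(const, months = integer(0)), "empty")
  expect_error(period_mean(const[1:31, ], months = 6), "cover")

  # sinusoid: annual mean recovered within discretisation error
  doy <- as.integer(format(dates, "%j"))
  m <- 1.5
  sin_tr <- structure(data.frame(date = dates,
                                 aw_sv = m + 0.7 * sin(2 * pi * doy / 366),
                                 cw_sv = 0, total_sv = 0),
                      class = c("section_transport", "data.frame"))
  expect_equal(unname(period_mean(sin_tr, 1:12)$overall["aw_sv"]), m,
               tolerance = 0.01)

  # winter-peaked cycle: June-July mean below the annual mean
  wint <- structure(data.frame(date = dates,
                               aw_sv = m + 0.7 * cos(2 * pi * (doy - 15) / 366),
                               cw_sv = 0, total_sv = 0),
                    class = c("section_transport", "data.frame"))
  expect_lt(unname(period_mean(wint, c(6, 7))$overall["aw_sv"]),
            unname(period_mean(wint, 1:12)$overall["aw_sv"]))
})
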