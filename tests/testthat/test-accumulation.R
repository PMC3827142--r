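# Foraging-box membership, daily accumulation, fraction-from-south and
# arrival curves.

test_that("box membership matches offsets and a polygon-containment oracle", {
  box <- foraging_box()  # 100 km box at the colony
  expect_true(in_box(box$centre_lon, box$centre_lat, box))
  # 49 km due east in, 51 km out
  lon49 <- box$centre_lon + 49 / larvadrift:::km_per_deg_lon(box$centre_lat)
  lon51 <- box$centre_lon + 51 / larvadrift:::km_per_deg_lon(box$centre_lat)
  expect_true(in_box(lon49, box$centre_lat, box))
  expect_false(in_box(lon51, box$centre_lat, box))

  # brute-force oracle on random points: point-in-square via the four
  # half-plane tests in the local projection
  set.seed(8)
  lon <- runif(1000, box$centre_lon - 2, box$centre_lon + 2)
  lat <- runif(1000, box$centre_lat - 1, box$centre_lat + 1)
  km <- lonlat_to_km(lon, lat, box$centre_lon, box$centre_lat)
  h <- box$side_km / 2
  oracle <- km$x >= -h & km$x <= h & km$y >= -h & km$y <= h
  expect_identical(in_box(lon, lat, box), oracle)

  # colony-to-edge distance in the plausible coastal range
  expect_gte(box$side_km / 2, 46)
  expect_lte(box$side_km / 2 * sqrt(2), 72)
})

toy_traj <- function() {
  box <- foraging_box()
  d1 <- as.Date("2000-06-09"); d2 <- as.Date("2000-06-10")
  data.table::data.table(
    id = c(1L, 2L, 3L, 1L, 2L, 3L),
    date = c(d1, d1, d1, d2, d2, d2),
    lon = c(box$centre_lon, box$centre_lon, 20,
            20, 20, box$centre_lon),
    lat = c(box$centre_lat, box$centre_lat, 65,
            65, 65, box$centre_lat),
    depth_m = 10, stage = "larva",
    age_d = c(80L, 90L, 40L, 81L, 91L, 41L),
    length_mm = c(20, 21, 12, 20.2, 21.2, 12.3),
    weight_mg = 5, origin = c(5L, 7L, 14L, 5L, 7L, 14L),
    status = "active")
}

test_that("daily accumulation matches the hand-computed toy fixture", {
  acc <- daily_accumulation(toy_traj(), foraging_box())
  expect_equal(acc$count_south, c(2L, 0L))
  expect_equal(acc$count_north, c(0L, 1L))
  expect_equal(acc$mean_length_south[1], 20.5)
  expect_equal(acc$mean_age_south[1], 85)
  expect_true(is.na(acc$mean_length_south[2]))
  expect_equal(acc$mean_age_north[2], 41)
})

test_that("eggs, inactive particles and out-of-box larvae are not counted", {
  tr <- toy_traj()
  tr$stage[1] <- "egg"
  tr$status[2] <- "beached"
  acc <- daily_accumulation(tr, foraging_box())
  expect_equal(acc$count_south, c(0L, 0L))
  expect_equal(acc$count_north, c(0L, 1L))
})

test_that("fraction_south: toy arithmetic, bounds, scaling invariance", {
  acc <- daily_accumulation(toy_traj(), foraging_box())
  expect_equal(fraction_south(acc), 2 / 3)
  # only southern -> 1; equal counts -> 0.5
  s_only <- data.table::data.table(date = as.Date("2000-06-09") + 0:1,
                                   count_south = c(3L, 4L),
                                   count_north = 0L)
  expect_equal(fraction_south(s_only), 1)
  eq <- data.table::data.table(date = as.Date("2000-06-09") + 0:1,
                               count_south = c(2L, 5L),
                               count_north = c(2L, 5L))
  expect_equal(fraction_south(eq), 0.5)
  # invariant under uniform scaling of all counts
  sc <- data.table::copy(eq)
  sc$count_south <- sc$count_south * 17L
  sc$count_north <- sc$count_north * 17L
  expect_equal(fraction_south(sc), fraction_south(eq))
  # zero total: undefined, not silently 0
  z <- data.table::data.table(date = as.Date("2000-06-09"),
                              count_south = 0L, count_north = 0L)
  expect_warning(fs <- fraction_south(z), "undefined")
  expect_true(is.na(fs))
})

test_that("arrival curves are cumulative, conserved and quartile-flagged", {
  set.seed(3)
  years <- 1996:2011
  acc_by_year <- lapply(years, function(y) {
    dates <- seq(as.Date(paste0(y, "-06-09")), as.Date(paste0(y, "-07-07")),
                 by = "day")
    data.table::data.table(date = dates,
                           count_south = rpois(length(dates), 3),
                           count_north = rpois(length(dates), 5))
  })
  names(acc_by_year) <- years
  body_size <- stats::setNames(rnorm(16, 60, 3), years)
  cv <- arrival_curves(acc_by_year, body_size)
  for (y in years) {
    cy <- cv[cv$year == y, ]
    expect_true(all(diff(cy$cum_south) >= 0))
    expect_equal(cy$cum_south[nrow(cy)],
                 sum(acc_by_year[[as.character(y)]]$count_south))
  }
  # 16 years -> 4 upper + 4 lower quartile years
  per_year <- unique(cv[, c("year", "size_group")])
  expect_equal(sum(per_year$size_group == "upper"), 4L)
  expect_equal(sum(per_year$size_group == "lower"), 4L)
  expect_error(arrival_curves(acc_by_year, body_size = c(a = 1)), "every year")
})
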