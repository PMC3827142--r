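# Individual-based model: release bookkeeping, vertical physics, growth,
# advection and the daily driver.

test_that("default release schedule yields 21 events and 94500 eggs", {
  g <- spawning_grounds()
  ev <- build_release_schedule(release_schedule(), g, year = 2000)
  expect_equal(length(unique(ev$date)), 21L)
  expect_equal(sum(ev$count), 94500L)
  # equal allocation: 300 per ground per event
  expect_true(all(ev$count == 300L))
  # single event when the interval exceeds the window
  one <- build_release_schedule(release_schedule(interval_d = 61), g, 2000)
  expect_equal(length(unique(one$date)), 1L)
  expect_equal(sum(one$count), 4500L)
})

test_that("weighted allocation conserves eggs and rejects bad weights", {
  g <- spawning_grounds()
  w <- g$index  # south-light, north-heavy weights
  ev <- build_release_schedule(release_schedule(allocation = w), g, 2000)
  per_event <- tapply(ev$count, ev$date, sum)
  expect_true(all(per_event == 4500L))
  expect_error(build_release_schedule(
    release_schedule(allocation = rep(-1, 15)), g, 2000), "weights")
})

test_that("egg buoyancy physics: ascent, equilibrium, steady state", {
  cfg <- ibm_config()
  zg <- 0:50
  # uniformly saltier than neutral, kz -> 0: egg ascends to the surface
  z <- rep(40, 20)
  for (s in 1:4000) {
    z <- egg_depth_step(z, rep(31.25, 20), zg, rep(33.75, 51),
                        rep(1e-9, 51), dt = 30, config = cfg, bottom = 50)
  }
  expect_lt(max(z), 0.5)
  # stratified column crossing neutral salinity: equilibrium at the
  # zero-buoyancy depth (salt = 30 + 0.1 z crosses 31.25 at z* = 12.5)
  z <- rep(40, 50)
  for (s in 1:4000) {
    z <- egg_depth_step(z, rep(31.25, 50), zg, 30 + 0.1 * zg,
                        rep(1e-9, 51), dt = 30, config = cfg, bottom = 50)
  }
  expect_equal(mean(z), 12.5, tolerance = 0.05)
  expect_error(egg_depth_step(10, 31, numeric(0), numeric(0), numeric(0),
                              30, cfg), "profile")
})

test_that("constant-kz egg ensemble matches the exponential steady state", {
  # w = 1 mm/s up, kz = 1e-3 m^2/s -> stationary depth ~ Exp(rate w/kz = 1)
  cfg <- ibm_config()
  zg <- 0:50
  set.seed(2)
  n <- 2000  # desk-scale; the acceptance suite runs the full 1e4 ensemble
  z <- rep(25, n)
  for (s in 1:1500) {
    z <- egg_depth_step(z, rep(31.25, n), zg, rep(33.75, 51), rep(1e-3, 51),
                        dt = 25, config = cfg, bottom = 50)
  }
  ks <- suppressWarnings(stats::ks.test(z, "pexp", rate = 1))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("larval vertical migration targets the preferred isolume", {
  cfg <- ibm_config()
  zp <- preferred_light_depth(cfg, bottom = 300)
  # already at the preferred depth: no move
  expect_equal(larva_depth_step(zp, 10, 600, cfg, bottom = 300), zp)
  # displacement per step never exceeds the swim-speed cap
  dt <- 600
  for (z0 in c(0, 50, 150, 290)) {
    moved <- abs(larva_depth_step(z0, 8, dt, cfg, bottom = 300) - z0)
    expect_lte(moved, cfg$swim_bl_s * 8 / 1000 * dt + 1e-12)
  }
  # polar-day constant light: convergence within 48 h from anywhere
  z <- c(0, 40, 120, 299)
  for (s in 1:(48 * 6)) z <- larva_depth_step(z, rep(5, 4), 600, cfg,
                                              bottom = 300)
  expect_equal(z, rep(zp, 4), tolerance = 1e-6)
})

test_that("growth is exponential, warm-favoured, and step-consistent", {
  cfg <- ibm_config()
  g0 <- growth_step(5, 0.2, 8, 0, cfg)
  expect_equal(g0$weight_mg, 0.2)
  expect_equal(g0$length_mm, 5)
  # warmer water grows larvae faster over 4-12 degC
  for (w in c(0.06, 0.5, 5, 40)) {
    gr <- vapply(c(4, 6, 8, 10, 12), function(tt) {
      growth_step(5, w, tt, 1, cfg)$weight_mg
    }, numeric(1))
    expect_true(all(diff(gr) >= 0))
  }
  # one 24 h step vs 24 one-hour steps within 0.1%
  big <- growth_step(5, 0.2, 8, 1, cfg)$weight_mg
  w <- 0.2
  for (i in 1:24) w <- growth_step(5, w, 8, 1 / 24, cfg)$weight_mg
  expect_equal(w, big, tolerance = 1e-3)
  expect_error(growth_step(5, -1, 8, 1, cfg), "weight")
})

test_that("advection oracles: uniform flow, stillness, solid-body rotation", {
  days <- seq(as.Date("2000-06-01"), by = "day", length.out = 6)
  f <- make_uv_fields(function(lo, la) 0.1 + 0 * lo, function(lo, la) 0 * lo)
  p <- list(lon = 20, lat = 70)
  for (i in 1:24) p <- advect_step(p$lon, p$lat, 10, f, days[1], 3600)
  dx_km <- (p$lon - 20) * larvadrift:::km_per_deg_lon(p$lat)
  expect_equal(dx_km, 8.64, tolerance = 0.01)
  expect_equal(p$lat, 70)

  f0 <- make_uv_fields(function(lo, la) 0 * lo, function(lo, la) 0 * lo)
  q <- advect_step(20, 70, 10, f0, days[1], 86400)
  expect_equal(q$lon, 20)
  expect_equal(q$lat, 70)

  # solid-body rotation: back to start after one period within 1% of radius
  om <- 2 * pi / (4 * 86400)
  fr <- make_uv_fields(
    function(lo, la) -om * (la - 70) * 110574,
    function(lo, la) om * (lo - 20) * 111320 * cos(la * pi / 180))
  p <- list(lon = 20, lat = 70.05)
  for (i in 1:(4 * 48)) p <- advect_step(p$lon, p$lat, 10, fr, days[1], 1800)
  r0_km <- 0.05 * 110.574
  err_km <- sqrt(((p$lon - 20) * larvadrift:::km_per_deg_lon(70))^2 +
                   ((p$lat - 70.05) * 110.574)^2)
  expect_lt(err_km / r0_km, 0.01)
})

test_that("run_ibm: stage transition, conservation, stillness, determinism", {
  days <- seq(as.Date("2000-03-01"), by = "day", length.out = 30)
  f <- make_uv_fields(function(lo, la) 0 * lo, function(lo, la) 0 * lo,
                      days = days, kz = 1e-4)
  g <- data.frame(index = c(1L, 13L), name = c("S", "N"),
                  lon = c(19.8, 20.2), lat = c(69.8, 70.2),
                  radius_km = c(2, 2))
  cfg <- ibm_config(dt_hours = 6, seed = 5)
  sched <- release_schedule(start = "03-01", end = "03-10", interval_d = 3,
                            eggs_per_event = 40)
  traj <- run_ibm(f, g, cfg, sched)

  # stage flips exactly at the configured egg duration, for every particle
  expect_true(all(traj$stage[traj$age_d < 21] == "egg"))
  expect_true(all(traj$stage[traj$age_d >= 21] == "larva"))
  expect_true(all(traj$age_d >= 0))

  # conservation: released particles all accounted for every day
  per_day <- traj[, .N, by = date]
  released <- traj[, .(first = min(date)), by = id]
  for (d in unique(per_day$date)) {
    expect_equal(per_day$N[per_day$date == d], sum(released$first <= d))
  }
  expect_equal(length(unique(traj$id)), 4 * 40)
  expect_true(all(traj$status %in% c("active", "beached", "left_domain")))

  # still ocean: no horizontal motion
  drift <- traj[, .(dlon = diff(range(lon)), dlat = diff(range(lat))),
                by = id]
  expect_true(all(drift$dlon == 0))
  expect_true(all(drift$dlat == 0))

  # age monotone; particles reaching age 21 flip egg->larva exactly once
  flips <- traj[order(id, date),
                .(nflip = sum(diff(stage == "larva") != 0),
                  max_age = max(age_d),
                  mono = all(diff(age_d) == 1)), by = id]
  expect_true(all(flips$nflip[flips$max_age >= 21] == 1))
  expect_true(all(flips$nflip[flips$max_age < 21] == 0))
  expect_true(all(flips$mono))

  # determinism under the same seed
  traj2 <- run_ibm(f, g, cfg, sched)
  expect_identical(traj$lon, traj2$lon)
  expect_identical(traj$depth_m, traj2$depth_m)

  expect_error(run_ibm(f, g, cfg, sched, end_date = max(days) + 30),
               "cover")
})

test_that("length never decreases along any trajectory", {
  days <- seq(as.Date("2000-03-01"), by = "day", length.out = 35)
  f <- make_uv_fields(function(lo, la) 0 * lo, function(lo, la) 0 * lo,
                      days = days, temp = 7)
  g <- data.frame(index = 1L, name = "S", lon = 20, lat = 70, radius_km = 2)
  traj <- run_ibm(f, g, ibm_config(dt_hours = 6, seed = 3),
                  release_schedule(start = "03-01", end = "03-01",
                                   eggs_per_event = 25))
  mono <- traj[order(id, date), .(ok = all(diff(length_mm) >= 0)), by = id]
  expect_true(all(mono$ok))
  # larvae grow in 7 degC water
  expect_gt(max(traj$length_mm), ibm_config()$hatch_length_mm)
})
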