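# Bespoke analytic ocean fields for oracle tests, plus a cache for the
# expensive coupled-scenario runs shared across test files.

# constant-in-time fields from u(lon,lat), v(lon,lat) functions
make_uv_fields <- function(ufun, vfun,
                           lon = seq(19.4, 20.6, by = 0.02),
                           lat = seq(69.6, 70.4, by = 0.01),
                           depth = c(0, 50),
                           days = seq(as.Date("2000-06-01"), by = "day",
                                      length.out = 6),
                           temp = 5, salt = 34, kz = 1e-4,
                           land_mask = NULL) {
  nx <- length(lon); ny <- length(lat); nz <- length(depth); nt <- length(days)
  g <- expand.grid(lon = lon, lat = lat)
  u2 <- matrix(ufun(g$lon, g$lat), nx, ny)
  v2 <- matrix(vfun(g$lon, g$lat), nx, ny)
  if (is.null(land_mask)) land_mask <- matrix(FALSE, nx, ny)
  u2[land_mask] <- 0; v2[land_mask] <- 0
  mk4 <- function(m2) array(rep(m2, nz * nt), c(nx, ny, nz, nt))
  ocean_fields(lon, lat, depth, days,
               temp = array(temp, c(nx, ny, nz, nt)),
               salt = array(salt, c(nx, ny, nz, nt)),
               u = mk4(u2), v = mk4(v2),
               kz = array(kz, c(nx, ny, nz, nt)),
               land_mask = land_mask)
}

# single-jet scenario with closed-form 1 Sv transport and all-AW water
jet_oracle_config <- function(grid_km = 8, core_speed = 0.1,
                              width_km = 100, depth_m = 100) {
  ocean_scenario_config(
    lon_range = c(15, 25), lat_range = c(69, 73), grid_km = grid_km,
    depth_max = 300, dz = 10,
    start_date = "2000-03-01", end_date = "2000-03-01",
    atlantic = list(core_speed = core_speed, width_km = width_km,
                    center_km = 110, depth_m = depth_m, taper_m = 0),
    coastal = list(core_speed = 0, fresh_anom = 0),
    background = list(temp = 4, temp_season_amp = 0),
    seasonal_amp = 0)
}

# cached coupled-scenario runs (~6 s each), keyed by jet multiplier
.coupled_cache <- new.env(parent = emptyenv())
coupled_run_cached <- function(m, keep_traj = FALSE) {
  key <- paste0("m", m, if (keep_traj) "_traj")
  if (is.null(.coupled_cache[[key]])) {
    .coupled_cache[[key]] <-
      coupled_fraction_south(jet_multiplier = m, seed = 7,
                             keep_traj = keep_traj)
  }
  .coupled_cache[[key]]
}
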