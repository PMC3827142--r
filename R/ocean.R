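# Synthetic ocean fields: a coastal (fresh, nearshore) jet and an Atlantic
# (warm, salty, offshore) jet on a regular lon/lat grid, with seasonal and
# interannual modulation. Velocities derive from a streamfunction, so the
# flow is non-divergent, the cross-stream Gaussian integrates exactly to
# core_speed * width * depth, and the Atlantic branch can migrate onto the
# shelf downstream with particles following it.

#' Configuration for the synthetic coastal-ocean scenario
#'
#' Builds the parameter set consumed by [generate_ocean_fields()]. The
#' defaults describe a Norwegian-coast analogue: a fresh nearshore coastal
#' jet (salinity < 34.9 at core) and a warm, salty offshore Atlantic jet
#' (T > 3 degC, S > 34.9 at core), both flowing along the coast toward the
#' Barents Sea entrance, with a weaker summer inflow and per-year
#' multiplicative anomalies on the Atlantic branch.
#'
#' Cross-stream jet profiles are Gaussian with sigma = width/sqrt(2*pi), so
#' the depth-integrated along-coast transport of a jet is exactly
#' `core_speed * width_km * effective_depth` (see
#' [analytic_jet_transport()]). Vertical structure is uniform over the top
#' `depth_m` metres, then decays exponentially with scale `taper_m`
#' (`taper_m = 0` gives a sharp cut-off).
#'
#' @param lon_range,lat_range numeric length-2 domain bounds (degrees)
#' @param grid_km target horizontal grid spacing, km (default 4, the
#'   resolution of the ocean archive being emulated; coarser values are used
#'   for desk-scale runs)
#' @param depth_max,dz vertical axis: 0..`depth_max` m at `dz` m spacing
#' @param start_date,end_date first/last day (Date or "YYYY-MM-DD"); daily
#'   fields, 1-day step
#' @param coast coastline polyline, see [coastline_default()]
#' @param atlantic,coastal named lists of jet parameters:
#'   `core_speed` (m/s), `width_km`, `center_km` (cross-shore distance of
#'   the core), `depth_m`, `taper_m`; the Atlantic list additionally takes
#'   `center_end_km`, `migrate_from_s`, `migrate_to_s` (the core migrates
#'   linearly from `center_km` to `center_end_km` between those along-coast
#'   arcs), `temp_anom` (degC), `salt_anom` (psu); the coastal list takes
#'   `fresh_anom` (psu, surface freshening at the coast), `fresh_scale_km`,
#'   `fresh_zscale_m`, `temp_anom`.
#' @param background list: `temp` (degC, far-field), `salt` (psu, far-field,
#'   just above the Atlantic threshold so off-jet water classifies OTHER),
#'   `temp_season_amp` (degC), `temp_season_peak_doy`
#' @param seasonal_amp amplitude of the inflow seasonal cycle (multiplier
#'   `1 + amp*cos(2*pi*(doy - peak)/365.25)`, peak day of year `seasonal_peak_doy`;
#'   winter maximum means the summer inflow is weaker than the annual mean)
#' @param seasonal_peak_doy day of year of the inflow maximum (default 15)
#' @param year_mult named numeric vector of per-year multipliers applied to
#'   the Atlantic jet (names are calendar years); unlisted years get 1
#' @param eddy_amp stream-function eddy perturbation amplitude (m^2/s); 0
#'   (default) disables eddies
#' @param eddy_n,eddy_scale_km number and spatial scale of eddy Gaussians
#' @param kz_surface,kz_scale_m,kz_floor vertical diffusivity profile
#'   `kz(z) = kz_floor + kz_surface*exp(-z/kz_scale_m)` (m^2/s)
#' @param seed integer RNG seed (only used when `eddy_amp > 0`)
#' @return an `ocean_scenario_config` list
#' @export
ocean_scenario_config <- function(lon_range = c(16, 24),
                                  lat_range = c(69, 72.4),
                                  grid_km = 4,
                                  depth_max = 300, dz = 10,
                                  start_date = "2000-03-01",
                                  end_date = "2000-03-31",
                                  coast = coastline_default(),
                                  atlantic = list(),
                                  coastal = list(),
                                  background = list(),
                                  seasonal_amp = 0.25,
                                  seasonal_peak_doy = 15,
                                  year_mult = c(),
                                  eddy_amp = 0, eddy_n = 12,
                                  eddy_scale_km = 60,
                                  kz_surface = 5e-3, kz_scale_m = 50,
                                  kz_floor = 1e-5,
                                  seed = 1L) {
  atl <- utils::modifyList(list(
    core_speed = 0.10, width_km = 100, center_km = 110,
    center_end_km = NULL, migrate_from_s = 1100, migrate_to_s = 1500,
    depth_m = 50, taper_m = 100,
    temp_anom = 4.0, salt_anom = 0.17
  ), atlantic)
  if (is.null(atl$center_end_km)) atl$center_end_km <- atl$center_km
  cst <- utils::modifyList(list(
    core_speed = 0.055, width_km = 40, center_km = 20,
    depth_m = 50, taper_m = 100,
    fresh_anom = 1.8, fresh_scale_km = 25, fresh_zscale_m = 30,
    temp_anom = 1.5
  ), coastal)
  bg <- utils::modifyList(list(
    temp = 2.5, salt = 34.95,
    temp_season_amp = 2.0, temp_season_peak_doy = 210
  ), background)
  cfg <- list(
    lon_range = lon_range, lat_range = lat_range, grid_km = grid_km,
    depth_max = depth_max, dz = dz,
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    coast = coast, atlantic = atl, coastal = cst, background = bg,
    seasonal_amp = seasonal_amp, seasonal_peak_doy = seasonal_peak_doy,
    year_mult = year_mult,
    eddy_amp = eddy_amp, eddy_n = eddy_n, eddy_scale_km = eddy_scale_km,
    kz_surface = kz_surface, kz_scale_m = kz_scale_m, kz_floor = kz_floor,
    seed = as.integer(seed)
  )
  stopifnot(cfg$start_date <= cfg$end_date, dz > 0, depth_max > dz,
            grid_km > 0)
  class(cfg) <- "ocean_scenario_config"
  cfg
}

#' Closed-form along-coast volume transport of a configured jet
#'
#' The Gaussian cross-stream profile integrates to `core_speed * width_km`;
#' the vertical profile contributes `depth_m + taper_m*(1 - exp(-(H -
#' depth_m)/taper_m))` metres with `H` the bottom depth. Transport is
#' reported in Sverdrup (1 Sv = 1e6 m^3/s).
#'
#' @param jet jet parameter list (`atlantic` or `coastal` element of a
#'   config)
#' @param depth_max bottom depth, m
#' @return transport in Sv
#' @export
analytic_jet_transport <- function(jet, depth_max = 300) {
  eff_depth <- if (jet$taper_m > 0) {
    jet$depth_m + jet$taper_m * (1 - exp(-(depth_max - jet$depth_m) / jet$taper_m))
  } else {
    jet$depth_m
  }
  jet$core_speed * jet$width_km * 1000 * eff_depth / 1e6
}

# seasonal inflow multiplier, winter-peaked by default
season_factor <- function(doy, amp, peak) {
  1 + amp * cos(2 * pi * (doy - peak) / 365.25)
}

# vertical velocity structure: uniform to depth_m, exponential taper below.
# With a sharp cutoff (taper 0) the boundary level carries the half-cell
# value so the trapezoidal depth integral of the gridded profile equals
# depth_m exactly.
vertical_profile <- function(z, depth_m, taper_m) {
  out <- as.numeric(z <= depth_m)
  below <- z > depth_m
  if (any(below)) {
    out[below] <- if (taper_m > 0) exp(-(z[below] - depth_m) / taper_m) else 0
  }
  if (taper_m == 0) out[z == depth_m] <- 0.5
  out
}

# separable 3x3 binomial smoother with replicated edges; applied to the
# streamfunction so the kinks of the distance-to-polyline field at concave
# coastline vertices do not alias into spurious finite-difference
# velocities (the current rounds capes smoothly instead)
smooth2d <- function(m, passes = 2L) {
  nx <- nrow(m); ny <- ncol(m)
  for (p in seq_len(passes)) {
    ix0 <- c(1, seq_len(nx - 1)); ix1 <- c(seq.int(2, nx), nx)
    m <- 0.25 * m[ix0, ] + 0.5 * m + 0.25 * m[ix1, ]
    iy0 <- c(1, seq_len(ny - 1)); iy1 <- c(seq.int(2, ny), ny)
    m <- 0.25 * m[, iy0] + 0.5 * m + 0.25 * m[, iy1]
  }
  m
}

#' Generate synthetic daily ocean fields
#'
#' Evaluates the scenario of an [ocean_scenario_config()] on a regular
#' lon/lat/depth/time grid and returns an [ocean_fields()] object. The two
#' jets are built from a streamfunction in coast-following coordinates, so
#' discrete velocities are non-divergent on the grid; temperature and
#' salinity carry the water-mass signatures (Atlantic core T > 3, S > 34.9;
#' coastal core S < 34.9 with salinity increasing with depth nearshore).
#'
#' @param config an `ocean_scenario_config`
#' @return an `ocean_fields` object
#' @export
generate_ocean_fields <- function(config) {
  stopifnot(inherits(config, "ocean_scenario_config"))
  cfg <- config
  mid_lat <- mean(cfg$lat_range)
  dlat <- cfg$grid_km / KM_PER_DEG_LAT
  dlon <- cfg$grid_km / km_per_deg_lon(mid_lat)
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], by = dlon)
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], by = dlat)
  depth <- seq(0, cfg$depth_max, by = cfg$dz)
  time <- seq(cfg$start_date, cfg$end_date, by = "day")
  nx <- length(lon); ny <- length(lat); nz <- length(depth); nt <- length(time)
  if (nx < 4 || ny < 4) {
    stop("ocean domain too small to contain both jets at this grid spacing")
  }

  g <- expand.grid(lon = lon, lat = lat)
  pr <- coast_project(g$lon, g$lat, cfg$coast)
  s_km <- matrix(pr$s, nx, ny)
  d_km <- matrix(pr$d, nx, ny)
  land <- d_km < 0

  atl <- cfg$atlantic; cst <- cfg$coastal; bg <- cfg$background
  # Atlantic core migrates onto the shelf downstream of migrate_from_s
  frac <- pmin(pmax((s_km - atl$migrate_from_s) /
                      max(atl$migrate_to_s - atl$migrate_from_s, 1e-9), 0), 1)
  atl_center <- atl$center_km + frac * (atl$center_end_km - atl$center_km)

  # per-jet streamfunctions (m^2/s per unit vertical profile); d in km -> m
  sig_a <- atl$width_km / sqrt(2 * pi) * 1000
  sig_c <- cst$width_km / sqrt(2 * pi) * 1000
  psi <- matrix(0, nx, ny)   # Atlantic (+ eddies)
  psi_c <- matrix(0, nx, ny) # coastal
  if (atl$core_speed != 0) {
    psi <- psi - atl$core_speed * sig_a * sqrt(2 * pi) *
      (stats::pnorm((d_km - atl_center) * 1000 / sig_a) - 0.5)
  }
  if (cst$core_speed != 0) {
    psi_c <- psi_c - cst$core_speed * sig_c * sqrt(2 * pi) *
      (stats::pnorm((d_km - cst$center_km) * 1000 / sig_c) - 0.5)
  }
  if (cfg$eddy_amp > 0) {
    set.seed(cfg$seed)
    for (e in seq_len(cfg$eddy_n)) {
      elon <- stats::runif(1, cfg$lon_range[1], cfg$lon_range[2])
      elat <- stats::runif(1, cfg$lat_range[1], cfg$lat_range[2])
      amp <- stats::rnorm(1, 0, cfg$eddy_amp)
      ex <- outer((lon - elon) * km_per_deg_lon(elat), rep(1, ny))
      ey <- outer(rep(1, nx), (lat - elat) * KM_PER_DEG_LAT)
      psi <- psi + amp * exp(-(ex^2 + ey^2) / (2 * cfg$eddy_scale_km^2))
    }
  }

  # u = -dpsi/dy, v = +dpsi/dx, central differences in metres
  dx_m <- outer(rep(dlon, nx), km_per_deg_lon(lat)) * 1000
  dy_m <- dlat * KM_PER_DEG_LAT * 1000
  ddx <- function(m) {
    out <- matrix(0, nx, ny)
    out[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / (2 * dx_m[2:(nx - 1), ])
    out[1, ] <- (m[2, ] - m[1, ]) / dx_m[1, ]
    out[nx, ] <- (m[nx, ] - m[nx - 1, ]) / dx_m[nx, ]
    out
  }
  ddy <- function(m) {
    out <- matrix(0, nx, ny)
    out[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / (2 * dy_m)
    out[, 1] <- (m[, 2] - m[, 1]) / dy_m
    out[, ny] <- (m[, ny] - m[, ny - 1]) / dy_m
    out
  }
  psi <- smooth2d(psi)
  psi_c <- smooth2d(psi_c)
  u2a <- -ddy(psi); v2a <- ddx(psi)
  u2c <- -ddy(psi_c); v2c <- ddx(psi_c)
  u2a[land] <- 0; v2a[land] <- 0
  u2c[land] <- 0; v2c[land] <- 0

  # hydrography in (d, z): gaussians about the jet axes
  ga <- exp(-((d_km - atl_center) * 1000)^2 / (2 * sig_a^2))
  gc_fresh <- exp(-pmax(d_km, 0)^2 / (2 * cst$fresh_scale_km^2))
  gc_jet <- exp(-((d_km - cst$center_km) * 1000)^2 / (2 * sig_c^2))

  vz_a <- vertical_profile(depth, atl$depth_m, atl$taper_m)
  vz_c <- vertical_profile(depth, cst$depth_m, cst$taper_m)
  t_zscale_a <- exp(-depth / 150)
  t_zscale_c <- exp(-depth / 50)
  s_zscale <- exp(-depth / cst$fresh_zscale_m)

  temp3 <- array(bg$temp, c(nx, ny, nz))
  salt3 <- array(bg$salt, c(nx, ny, nz))
  u3a <- array(0, c(nx, ny, nz)); v3a <- array(0, c(nx, ny, nz))
  u3c <- array(0, c(nx, ny, nz)); v3c <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    temp3[, , k] <- bg$temp + atl$temp_anom * ga * t_zscale_a[k] +
      cst$temp_anom * gc_jet * t_zscale_c[k]
    salt3[, , k] <- bg$salt + atl$salt_anom * ga -
      cst$fresh_anom * gc_fresh * s_zscale[k]
    u3a[, , k] <- u2a * vz_a[k]; v3a[, , k] <- v2a * vz_a[k]
    u3c[, , k] <- u2c * vz_c[k]; v3c[, , k] <- v2c * vz_c[k]
  }
  kz1 <- cfg$kz_floor + cfg$kz_surface * exp(-depth / cfg$kz_scale_m)

  years <- as.integer(format(time, "%Y"))
  doy <- as.integer(format(time, "%j"))
  ym <- rep(1, nt)
  if (length(cfg$year_mult)) {
    hit <- match(as.character(years), names(cfg$year_mult))
    ym[!is.na(hit)] <- cfg$year_mult[hit[!is.na(hit)]]
  }
  # seasonal cycle scales both jets; the interannual multiplier only the
  # Atlantic branch (the inflow anomaly of the scenario)
  sf <- season_factor(doy, cfg$seasonal_amp, cfg$seasonal_peak_doy)
  sfa <- sf * ym
  tf <- bg$temp_season_amp *
    cos(2 * pi * (doy - bg$temp_season_peak_doy) / 365.25)

  temp <- array(0, c(nx, ny, nz, nt))
  salt <- array(0, c(nx, ny, nz, nt))
  u <- array(0, c(nx, ny, nz, nt))
  v <- array(0, c(nx, ny, nz, nt))
  kz <- array(0, c(nx, ny, nz, nt))
  kz3 <- array(rep(kz1, each = nx * ny), c(nx, ny, nz))
  for (it in seq_len(nt)) {
    temp[, , , it] <- temp3 + tf[it]
    salt[, , , it] <- salt3
    u[, , , it] <- u3a * sfa[it] + u3c * sf[it]
    v[, , , it] <- v3a * sfa[it] + v3c * sf[it]
    kz[, , , it] <- kz3
  }

  ocean_fields(lon = lon, lat = lat, depth = depth, time = time,
               temp = temp, salt = salt, u = u, v = v, kz = kz,
               land_mask = land, config = cfg)
}

#' Construct an ocean-fields object from raw arrays
#'
#' Container used by every downstream stage: CF-style coordinate vectors
#' plus 4-D arrays dimensioned `(lon, lat, depth, time)`. Validates the
#' axis monotonicity, non-negativity and land-velocity invariants, so tests
#' can build bespoke analytic fields (uniform flows, solid-body rotation)
#' directly.
#'
#' @param lon,lat,depth,time strictly increasing axes (depth in m positive
#'   down, time a Date vector with 1-day step)
#' @param temp,salt,u,v,kz 4-D arrays `(lon, lat, depth, time)`; degC, psu,
#'   m/s, m/s, m^2/s
#' @param land_mask logical matrix `(lon, lat)`
#' @param config optional generating configuration, carried for provenance
#' @return an object of class `ocean_fields`
#' @export
ocean_fields <- function(lon, lat, depth, time, temp, salt, u, v, kz,
                         land_mask, config = NULL) {
  dims <- c(length(lon), length(lat), length(depth), length(time))
  for (nm in c("temp", "salt", "u", "v", "kz")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims))) {
      stop(nm, " must have dim (lon, lat, depth, time)")
    }
  }
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0), all(diff(depth) > 0))
  if (length(time) > 1) {
    stopifnot(all(diff(as.numeric(time)) == 1))
  }
  stopifnot(all(salt >= 0), all(kz >= 0), all(is.finite(u)), all(is.finite(v)))
  if (any(land_mask)) {
    lm <- which(land_mask, arr.ind = TRUE)
    for (k in seq_along(depth)) for (it in seq_along(time)) {
      if (any(u[, , k, it][land_mask] != 0) ||
          any(v[, , k, it][land_mask] != 0)) {
        stop("velocities must be zero on land cells")
      }
    }
  }
  structure(list(lon = lon, lat = lat, depth = depth, time = as.Date(time),
                 temp = temp, salt = salt, u = u, v = v, kz = kz,
                 land_mask = land_mask, config = config),
            class = "ocean_fields")
}

#' @export
print.ocean_fields <- function(x, ...) {
  cat("ocean_fields:",
      length(x$lon), "lon x", length(x$lat), "lat x",
      length(x$depth), "depth x", length(x$time), "days\n")
  cat("  lon", range(x$lon), " lat", range(x$lat),
      " depth 0-", max(x$depth), "m\n")
  cat("  dates", format(min(x$time)), "to", format(max(x$time)), "\n")
  invisible(x)
}
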