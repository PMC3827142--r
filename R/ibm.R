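# Individual-based model of cod egg and larva drift. Particles are
# released on a fixed schedule at the spawning grounds, spend a fixed
# 3-week egg stage positioned vertically by buoyancy and turbulent mixing,
# then hatch into larvae that migrate toward a preferred light depth, grow
# as a function of temperature and size, and are advected horizontally by
# the daily current fields. State is recorded daily. No mortality.

#' Release schedule configuration
#'
#' Eggs are released every `interval_d` days from `start` through `end`
#' (first event on `start`; the default 1 March - 30 April window at a
#' 3-day interval gives 21 events), `eggs_per_event` eggs per event shared
#' across grounds by the allocation rule. The default 4500 eggs per event
#' over 21 events totals 94500 eggs.
#'
#' @param start,end first/last release day ("MM-DD" strings, resolved
#'   against the simulation year, or Dates)
#' @param interval_d days between release events
#' @param eggs_per_event eggs released per event (total over all grounds)
#' @param allocation "equal" (eggs_per_event split evenly over grounds,
#'   remainders to the lowest indices) or a numeric vector of per-ground
#'   weights
#' @return a `release_schedule` list
#' @export
release_schedule <- function(start = "03-01", end = "04-30",
                             interval_d = 3L, eggs_per_event = 4500L,
                             allocation = "equal") {
  stopifnot(interval_d >= 1, eggs_per_event >= 1)
  structure(list(start = start, end = end,
                 interval_d = as.integer(interval_d),
                 eggs_per_event = as.integer(eggs_per_event),
                 allocation = allocation),
            class = "release_schedule")
}

resolve_date <- function(x, year) {
  if (inherits(x, "Date")) return(x)
  if (grepl("^\\d{4}-", x)) return(as.Date(x))
  as.Date(paste0(year, "-", x))
}

#' Expand a release schedule into dated per-ground release events
#'
#' @param schedule a [release_schedule()]
#' @param grounds spawning-ground data.frame (see [spawning_grounds()])
#' @param year simulation year used to resolve "MM-DD" dates
#' @return data.frame: date, ground (index), count; total count equals
#'   eggs_per_event times the number of events
#' @export
build_release_schedule <- function(schedule, grounds, year = 2000L) {
  stopifnot(inherits(schedule, "release_schedule"), nrow(grounds) >= 1)
  d0 <- resolve_date(schedule$start, year)
  d1 <- resolve_date(schedule$end, year)
  stopifnot(d0 <= d1)
  dates <- seq(d0, d1, by = schedule$interval_d)
  ng <- nrow(grounds)
  if (identical(schedule$allocation, "equal")) {
    w <- rep(1, ng)
  } else {
    w <- as.numeric(schedule$allocation)
    if (length(w) != ng || any(w < 0) || sum(w) <= 0) {
      stop("allocation weights must be non-negative, one per ground")
    }
  }
  # largest-remainder allocation: exact conservation of eggs_per_event
  exact <- schedule$eggs_per_event * w / sum(w)
  base <- floor(exact)
  rem <- schedule$eggs_per_event - sum(base)
  extra <- integer(ng)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    extra[ord[seq_len(rem)]] <- 1L
  }
  counts <- as.integer(base + extra)
  if (sum(counts) != schedule$eggs_per_event) {
    stop("allocation rule lost eggs")  # defensive; cannot happen above
  }
  out <- data.frame(
    date = rep(dates, each = ng),
    ground = rep(grounds$index, times = length(dates)),
    count = rep(counts, times = length(dates))
  )
  out[out$count > 0, , drop = FALSE]
}

#' IBM configuration
#'
#' @param egg_duration_d fixed egg-stage duration, days (default 21; the
#'   particle is an egg while age < duration, a larva from that age on)
#' @param buoy_mean,buoy_sd neutral-buoyancy salinity distribution of eggs
#'   (psu; drawn once per egg at release)
#' @param buoy_coef terminal-velocity coefficient, m/s per psu of
#'   (ambient - neutral) salinity difference
#' @param w_max terminal-velocity cap, m/s
#' @param hatch_length_mm,hatch_weight_mg larval size at hatch
#' @param growth_coef coefficients (b0, bT, c1, c2, c3) of the specific
#'   growth rate polynomial SGR% = b0 + bT*T + T*(c1*lnw + c2*lnw^2 +
#'   c3*lnw^3), T in degC, w dry weight in mg
#' @param lw_a,lw_b length-weight power law `weight_mg = lw_a * length_mm^lw_b`
#' @param swim_bl_s maximum larval swim speed, body lengths per second
#' @param light_atten diffuse light attenuation coefficient, 1/m
#' @param pref_light preferred light level relative to surface light 1
#' @param surface_light relative surface irradiance (1 = polar-day
#'   daylight; held constant, appropriate for the high-latitude summer)
#' @param dt_hours inner time step for advection and vertical dynamics
#' @param spawn_depth_m length-2 range of initial egg depths, m
#' @param temp_range validity range of the growth model, degC; ambient
#'   temperature is clamped into it before the growth update
#' @param seed RNG seed for buoyancy draws and the vertical random walk
#' @return an `ibm_config` list
#' @export
ibm_config <- function(egg_duration_d = 21L,
                       buoy_mean = 31.25, buoy_sd = 0.69,
                       buoy_coef = 4e-4, w_max = 2e-3,
                       hatch_length_mm = 4, hatch_weight_mg = 0.06,
                       growth_coef = c(1.08, 1.79, -0.074, -0.0965, 0.0112),
                       lw_a = NULL, lw_b = 4,
                       swim_bl_s = 1, light_atten = 0.12, pref_light = 0.09,
                       surface_light = 1,
                       dt_hours = 1, spawn_depth_m = c(10, 40),
                       temp_range = c(0, 14),
                       seed = 1L) {
  stopifnot(egg_duration_d > 0, buoy_sd > 0, 24 %% dt_hours == 0,
            hatch_weight_mg > 0, hatch_length_mm > 0)
  if (is.null(lw_a)) lw_a <- hatch_weight_mg / hatch_length_mm^lw_b
  structure(list(egg_duration_d = as.integer(egg_duration_d),
                 buoy_mean = buoy_mean, buoy_sd = buoy_sd,
                 buoy_coef = buoy_coef, w_max = w_max,
                 hatch_length_mm = hatch_length_mm,
                 hatch_weight_mg = hatch_weight_mg,
                 growth_coef = growth_coef, lw_a = lw_a, lw_b = lw_b,
                 swim_bl_s = swim_bl_s, light_atten = light_atten,
                 pref_light = pref_light, surface_light = surface_light,
                 dt_hours = dt_hours, spawn_depth_m = spawn_depth_m,
                 temp_range = temp_range, seed = as.integer(seed)),
            class = "ibm_config")
}

# terminal velocity (m/s, positive up) from the salinity difference
egg_terminal_velocity <- function(salt_ambient, neutral_salt, config) {
  w <- config$buoy_coef * (salt_ambient - neutral_salt)
  pmin(pmax(w, -config$w_max), config$w_max)
}

# core vertical increment: buoyancy drift + random walk with the standard
# correction for spatially varying diffusivity (kz gradient drift,
# diffusivity evaluated at the offset midpoint). depth positive down;
# reflecting at surface and bottom.
egg_depth_increment <- function(depth, w_up, kz_grad, kz_star, dt, bottom,
                                noise) {
  z <- depth + (-w_up + kz_grad) * dt + noise * sqrt(2 * pmax(kz_star, 0) * dt)
  z <- abs(z)                      # reflect at the surface
  over <- z > bottom
  z[over] <- 2 * bottom - z[over]  # reflect at the bottom
  pmin(pmax(z, 0), bottom)
}

#' One buoyancy/random-walk step for pelagic eggs in a water column
#'
#' Updates egg depths from the local salinity (buoyancy sign follows
#' ambient minus neutral salinity) and vertical diffusivity profile.
#' Profiles are supplied on a depth grid and interpolated linearly. With
#' constant `kz` and constant upward terminal velocity `w`, iterating this
#' step converges to the exponential boundary-layer distribution
#' `p(z) ~ exp(-w z / kz)`.
#'
#' @param depth egg depths, m (vector)
#' @param neutral_salt per-egg neutral-buoyancy salinity, psu
#' @param z_grid depth grid of the profiles, m (increasing, from 0)
#' @param salt_profile,kz_profile salinity (psu) and diffusivity (m^2/s)
#'   on `z_grid`
#' @param dt time step, s
#' @param config an [ibm_config()]
#' @param bottom reflecting bottom depth, m (default: deepest grid point)
#' @return updated depths, m
#' @export
egg_depth_step <- function(depth, neutral_salt, z_grid, salt_profile,
                           kz_profile, dt, config = ibm_config(),
                           bottom = max(z_grid)) {
  if (length(z_grid) < 2 || length(salt_profile) != length(z_grid) ||
      length(kz_profile) != length(z_grid)) {
    stop("salinity/diffusivity profiles must cover the water column")
  }
  s_amb <- stats::approx(z_grid, salt_profile, xout = depth, rule = 2)$y
  kz_here <- stats::approx(z_grid, kz_profile, xout = depth, rule = 2)$y
  eps <- max(diff(z_grid)[1] / 2, 0.5)
  kz_up <- stats::approx(z_grid, kz_profile, xout = pmax(depth - eps, 0),
                         rule = 2)$y
  kz_dn <- stats::approx(z_grid, kz_profile, xout = pmin(depth + eps, bottom),
                         rule = 2)$y
  kz_grad <- (kz_dn - kz_up) / (2 * eps)
  z_star <- pmin(pmax(depth + 0.5 * kz_grad * dt, 0), bottom)
  kz_star <- stats::approx(z_grid, kz_profile, xout = z_star, rule = 2)$y
  w_up <- egg_terminal_velocity(s_amb, neutral_salt, config)
  egg_depth_increment(depth, w_up, kz_grad, kz_star, dt, bottom,
                      stats::rnorm(length(depth)))
}

#' Preferred depth of a larva under the light rule
#'
#' Light decays exponentially with depth; the larva prefers the isolume
#' `pref_light` relative to the surface level, i.e. depth
#' `log(surface_light/pref_light)/light_atten`, clamped to the water
#' column.
#'
#' @param config an [ibm_config()]
#' @param surface_light relative surface irradiance
#' @param bottom water-column depth, m
#' @return preferred depth, m
#' @export
preferred_light_depth <- function(config, surface_light = config$surface_light,
                                  bottom = Inf) {
  if (surface_light <= 0) return(bottom)  # darkness: no shallower target
  z <- log(surface_light / config$pref_light) / config$light_atten
  min(max(z, 0), bottom)
}

#' One vertical-migration step for larvae
#'
#' The larva swims toward its preferred light depth at a speed capped by
#' `swim_bl_s` body lengths per second; displacement per step never
#' exceeds the cap times `dt`. Deterministic (swimming dominates mixing at
#' larval sizes in this scheme).
#'
#' @param depth larval depths, m
#' @param length_mm larval lengths, mm
#' @param dt time step, s
#' @param config an [ibm_config()]
#' @param surface_light relative surface irradiance
#' @param bottom water-column depth, m
#' @return updated depths, m
#' @export
larva_depth_step <- function(depth, length_mm, dt, config = ibm_config(),
                             surface_light = config$surface_light,
                             bottom = Inf) {
  z_pref <- preferred_light_depth(config, surface_light, bottom)
  vmax <- config$swim_bl_s * length_mm / 1000  # m/s
  step <- pmin(abs(z_pref - depth), vmax * dt)
  z <- depth + sign(z_pref - depth) * step
  pmin(pmax(z, 0), bottom)
}

#' Temperature- and size-dependent growth update
#'
#' Multiplies dry weight by `exp(SGR(T, w)/100 * dt_d)` with the specific
#' growth rate (% per day) a polynomial in temperature and log weight,
#' evaluated at the midpoint weight (RK2) so long and subdivided steps
#' agree; the rate is floored at zero (no shrinkage). Length scales with
#' the weight gain through the length-weight exponent and never decreases.
#'
#' @param length_mm,weight_mg current size (vectors)
#' @param temp_c ambient temperature, degC
#' @param dt_d time step, days
#' @param config an [ibm_config()]
#' @return list with updated `length_mm`, `weight_mg`
#' @export
growth_step <- function(length_mm, weight_mg, temp_c, dt_d,
                        config = ibm_config()) {
  if (any(weight_mg <= 0)) stop("growth_step: non-positive weight")
  tc <- pmin(pmax(temp_c, config$temp_range[1]), config$temp_range[2])
  b <- config$growth_coef
  sgr_of <- function(w) {
    lnw <- log(w)
    pmax(b[1] + b[2] * tc + tc * (b[3] * lnw + b[4] * lnw^2 + b[5] * lnw^3),
         0)
  }
  # midpoint (RK2) update of log weight: the growth rate depends on the
  # evolving weight, so a midpoint evaluation keeps long and subdivided
  # steps consistent
  w_half <- weight_mg * exp(sgr_of(weight_mg) / 100 * dt_d / 2)
  w2 <- weight_mg * exp(sgr_of(w_half) / 100 * dt_d)
  # length follows the weight gain through the allometric exponent and
  # never shrinks
  l2 <- length_mm * pmax(w2 / weight_mg, 1)^(1 / config$lw_b)
  list(length_mm = l2, weight_mg = w2)
}

#' One horizontal advection step (4th-order Runge-Kutta)
#'
#' Displaces positions through the bilinear-in-space interpolated velocity
#' slab at the particles' depth. Velocities are frozen over the step
#' (nearest-in-time daily fields).
#'
#' @param lon,lat positions, degrees
#' @param depth particle depths, m
#' @param fields an `ocean_fields` object
#' @param date day whose velocity slab to use (Date)
#' @param dt time step, s
#' @return list with updated `lon`, `lat`
#' @export
advect_step <- function(lon, lat, depth, fields, date, dt) {
  it <- time_index(fields, date)
  u_slab <- fields$u[, , , it, drop = TRUE]
  v_slab <- fields$v[, , , it, drop = TRUE]
  dim(u_slab) <- dim(fields$u)[1:3]
  dim(v_slab) <- dim(fields$v)[1:3]
  advect_rk4(lon, lat, depth, u_slab, v_slab,
             fields$lon, fields$lat, fields$depth, dt)
}

advect_rk4 <- function(lon, lat, depth, u_slab, v_slab,
                       lon_ax, lat_ax, z_ax, dt) {
  vel <- function(lo, la) {
    u <- interp3(u_slab, lon_ax, lat_ax, z_ax, lo, la, depth)
    v <- interp3(v_slab, lon_ax, lat_ax, z_ax, lo, la, depth)
    # m/s -> deg/s at the particle latitude
    list(dlon = u / (km_per_deg_lon(la) * 1000),
         dlat = v / (KM_PER_DEG_LAT * 1000))
  }
  k1 <- vel(lon, lat)
  k2 <- vel(lon + k1$dlon * dt / 2, lat + k1$dlat * dt / 2)
  k3 <- vel(lon + k2$dlon * dt / 2, lat + k2$dlat * dt / 2)
  k4 <- vel(lon + k3$dlon * dt, lat + k3$dlat * dt)
  list(
    lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
    lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  )
}

#' Run the egg/larva drift model
#'
#' Releases eggs per the schedule, advances all particles with the inner
#' time step (horizontal advection; buoyancy random walk for eggs; light-
#' directed swimming for larvae), applies the daily growth update to
#' larvae, and records every particle's state once per day. Particles
#' hitting land are shelved as `beached`, particles leaving the grid as
#' `left_domain`; both stop moving but remain in the bookkeeping, so
#' active + beached + left_domain always equals the number released.
#'
#' @param fields an `ocean_fields` object covering the simulation window
#' @param grounds spawning-ground data.frame (index, lon, lat, radius_km)
#' @param config an [ibm_config()]
#' @param schedule a [release_schedule()]
#' @param end_date last simulated day (default: last field day)
#' @return `data.table` with one row per particle-day: id, date, lon, lat,
#'   depth_m, stage, age_d, length_mm, weight_mg, origin, status
#' @export
run_ibm <- function(fields, grounds, config = ibm_config(),
                    schedule = release_schedule(),
                    end_date = max(fields$time)) {
  stopifnot(inherits(fields, "ocean_fields"))
  year <- as.integer(format(fields$time[1], "%Y"))
  events <- build_release_schedule(schedule, grounds, year)
  end_date <- as.Date(end_date)
  if (min(events$date) < min(fields$time) || end_date > max(fields$time)) {
    stop("ocean fields do not cover the simulation window")
  }
  set.seed(config$seed)
  days <- seq(min(events$date), end_date, by = "day")
  nsub <- as.integer(24 / config$dt_hours)
  dt <- config$dt_hours * 3600
  bottom <- max(fields$depth)

  # state vectors, grown at each release
  id <- integer(0); origin <- integer(0); rel_date <- as.Date(character(0))
  lon <- lat <- depth <- numeric(0)
  neutral <- len <- wt <- numeric(0)
  age <- integer(0)
  status <- character(0)   # active / beached / left_domain
  next_id <- 1L
  gidx <- match(events$ground, grounds$index)

  rec <- vector("list", length(days))
  for (di in seq_along(days)) {
    day <- days[di]
    # releases due today
    ev <- which(events$date == day)
    for (e in ev) {
      n <- events$count[e]
      gi <- gidx[e]
      r_km <- if (!is.null(grounds$radius_km)) grounds$radius_km[gi] else 10
      theta <- stats::runif(n, 0, 2 * pi)
      rad <- r_km * sqrt(stats::runif(n))
      glon <- grounds$lon[gi] + rad * cos(theta) / km_per_deg_lon(grounds$lat[gi])
      glat <- grounds$lat[gi] + rad * sin(theta) / KM_PER_DEG_LAT
      id <- c(id, seq.int(next_id, length.out = n)); next_id <- next_id + n
      origin <- c(origin, rep(grounds$index[gi], n))
      rel_date <- c(rel_date, rep(day, n))
      lon <- c(lon, glon); lat <- c(lat, glat)
      depth <- c(depth, stats::runif(n, config$spawn_depth_m[1],
                                     config$spawn_depth_m[2]))
      neutral <- c(neutral, stats::rnorm(n, config$buoy_mean, config$buoy_sd))
      len <- c(len, rep(config$hatch_length_mm, n))
      wt <- c(wt, rep(config$hatch_weight_mg, n))
      age <- c(age, rep(0L, n))
      status <- c(status, rep("active", n))
      # immediately beached releases (misconfigured ground on land)
      bad <- on_land(fields, glon, glat)
      if (any(bad)) {
        status[(length(status) - n + 1L):length(status)][bad] <- "beached"
      }
    }

    if (length(id)) {
      it <- time_index(fields, day)
      u_slab <- fields$u[, , , it]; dim(u_slab) <- dim(fields$u)[1:3]
      v_slab <- fields$v[, , , it]; dim(v_slab) <- dim(fields$v)[1:3]
      s_slab <- fields$salt[, , , it]; dim(s_slab) <- dim(fields$salt)[1:3]
      k_slab <- fields$kz[, , , it]; dim(k_slab) <- dim(fields$kz)[1:3]
      t_slab <- fields$temp[, , , it]; dim(t_slab) <- dim(fields$temp)[1:3]
      is_egg <- age < config$egg_duration_d

      for (ss in seq_len(nsub)) {
        act <- status == "active"
        if (!any(act)) break
        p <- advect_rk4(lon[act], lat[act], depth[act], u_slab, v_slab,
                        fields$lon, fields$lat, fields$depth, dt)
        out <- off_domain(fields, p$lon, p$lat)
        beach <- !out & on_land(fields, p$lon, p$lat)
        ok <- !out & !beach
        ai <- which(act)
        lon[ai[ok]] <- p$lon[ok]; lat[ai[ok]] <- p$lat[ok]
        status[ai[out]] <- "left_domain"
        status[ai[beach]] <- "beached"

        act <- status == "active"
        # vertical dynamics
        ae <- act & is_egg
        if (any(ae)) {
          s_amb <- interp3(s_slab, fields$lon, fields$lat, fields$depth,
                           lon[ae], lat[ae], depth[ae])
          kz_h <- function(zq) interp3(k_slab, fields$lon, fields$lat,
                                       fields$depth, lon[ae], lat[ae],
                                       pmin(pmax(zq, 0), bottom))
          eps <- max(diff(fields$depth)[1] / 2, 0.5)
          kzg <- (kz_h(depth[ae] + eps) - kz_h(depth[ae] - eps)) / (2 * eps)
          kzs <- kz_h(depth[ae] + 0.5 * kzg * dt)
          w_up <- egg_terminal_velocity(s_amb, neutral[ae], config)
          depth[ae] <- egg_depth_increment(depth[ae], w_up, kzg, kzs, dt,
                                           bottom,
                                           stats::rnorm(sum(ae)))
        }
        al <- act & !is_egg
        if (any(al)) {
          depth[al] <- larva_depth_step(depth[al], len[al], dt, config,
                                        bottom = bottom)
        }
      }

      # daily growth for larvae, ageing, stage bookkeeping
      larv <- status != "" & age >= config$egg_duration_d
      grow <- larv & status == "active"
      if (any(grow)) {
        tc <- interp3(t_slab, fields$lon, fields$lat, fields$depth,
                      lon[grow], lat[grow], depth[grow])
        g <- growth_step(len[grow], wt[grow], tc, 1, config)
        len[grow] <- g$length_mm; wt[grow] <- g$weight_mg
      }
    }

    if (length(id)) {
      rec[[di]] <- data.table::data.table(
        id = id, date = day, lon = lon, lat = lat, depth_m = depth,
        stage = ifelse(age < config$egg_duration_d, "egg", "larva"),
        age_d = age, length_mm = len, weight_mg = wt,
        origin = origin, status = status
      )
      age <- age + 1L
    }
  }
  out <- data.table::rbindlist(rec[!vapply(rec, is.null, logical(1))])
  data.table::setattr(out, "egg_duration_d", config$egg_duration_d)
  out[]
}
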