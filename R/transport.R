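# Volume transport through a hydrographic section, classified by water
# mass. The section is sampled along the straight A->B line at roughly the
# native grid spacing; velocity is projected onto the section normal and
# integrated cell-by-cell, accumulating Atlantic Water (AW), Coastal Water
# (CW) and total transport separately.

#' Water-mass classification criteria
#'
#' Atlantic Water (AW) is warm, salty water carried by the Norwegian
#' Atlantic Current: `T > temp_aw` and `S > salt_aw` (defaults 3 degC and
#' 34.9; the salinity threshold is configurable because biased archives may
#' need a value below the climatological 35). Coastal Water (CW) is the
#' fresher Norwegian Coastal Current water: `S < salt_cw` south of
#' `lat_cw` (defaults 34.9 and 72.5 degN, i.e. 72 deg 30'). Inequalities
#' are strict; values exactly at a threshold classify OTHER.
#'
#' @param temp_aw,salt_aw AW thresholds (both must be exceeded)
#' @param salt_cw,lat_cw CW thresholds (salinity below, latitude south of)
#' @return a `water_mass_criteria` list
#' @export
water_mass_criteria <- function(temp_aw = 3, salt_aw = 34.9,
                                salt_cw = 34.9, lat_cw = 72.5) {
  stopifnot(is.finite(temp_aw), is.finite(salt_aw), is.finite(salt_cw),
            is.finite(lat_cw))
  if (salt_cw > salt_aw) {
    stop("salt_cw must not exceed salt_aw: AW and CW would overlap")
  }
  structure(list(temp_aw = temp_aw, salt_aw = salt_aw,
                 salt_cw = salt_cw, lat_cw = lat_cw),
            class = "water_mass_criteria")
}

#' Classify water parcels as AW, CW or OTHER
#'
#' @param temp temperature, degC
#' @param salt practical salinity
#' @param lat latitude, degrees north
#' @param criteria a [water_mass_criteria()] object
#' @return character vector in {"AW", "CW", "OTHER"}
#' @export
classify_water_mass <- function(temp, salt, lat,
                                criteria = water_mass_criteria()) {
  if (any(!is.finite(temp)) || any(!is.finite(salt)) || any(!is.finite(lat))) {
    stop("classify_water_mass: non-finite temperature, salinity or latitude")
  }
  out <- rep("OTHER", length(temp))
  out[temp > criteria$temp_aw & salt > criteria$salt_aw] <- "AW"
  out[salt < criteria$salt_cw & lat < criteria$lat_cw] <- "CW"
  out
}

#' Define a hydrographic section
#'
#' Straight line from endpoint A to endpoint B. Positive transport is flow
#' toward the left of the A->B direction (for a section laid coast-to-open
#' ocean across the Barents Sea entrance this is the inflowing direction);
#' set `flip_normal = TRUE` to reverse.
#'
#' @param lon_a,lat_a,lon_b,lat_b endpoints (degrees)
#' @param max_depth deepest level integrated, m
#' @param flip_normal reverse the positive-transport direction
#' @return a `section_definition` list
#' @export
section_definition <- function(lon_a, lat_a, lon_b, lat_b,
                               max_depth = Inf, flip_normal = FALSE) {
  if (lon_a == lon_b && lat_a == lat_b) stop("section endpoints coincide")
  structure(list(lon_a = lon_a, lat_a = lat_a, lon_b = lon_b, lat_b = lat_b,
                 max_depth = max_depth, flip_normal = flip_normal),
            class = "section_definition")
}

#' A cross-shelf section at a given along-coast position
#'
#' Convenience constructor: endpoint A sits on the coastline at arc
#' coordinate `s_km`, endpoint B `length_km` offshore along the local
#' coast normal. With land to the right of the coastline direction, the
#' positive normal of A->B points downstream (into the Barents Sea for the
#' default coastline).
#'
#' @param s_km along-coast arc of the coastal endpoint, km
#' @param length_km offshore extent, km
#' @param coast coastline polyline
#' @param max_depth deepest level integrated, m
#' @return a `section_definition`
#' @export
section_across_coast <- function(s_km, length_km = 250,
                                 coast = coastline_default(),
                                 max_depth = Inf) {
  a <- coast_unproject(s_km, 1, coast)
  b <- coast_unproject(s_km, length_km, coast)
  section_definition(a$lon, a$lat, b$lon, b$lat, max_depth = max_depth,
                     flip_normal = TRUE)
}

#' Water-mass-classified volume transport through a section
#'
#' For each day, samples temperature, salinity and velocity along the
#' section at approximately the native grid spacing, projects velocity on
#' the section normal, multiplies by cell width and layer thickness and
#' accumulates by water-mass class. Net transport is accumulated by
#' default; `inflow_only = TRUE` counts only positive (inflowing) normal
#' velocities.
#'
#' @param fields an `ocean_fields` object
#' @param section a [section_definition()]
#' @param criteria a [water_mass_criteria()]
#' @param inflow_only accumulate only positive normal velocities
#' @return `section_transport` data.frame: date, aw_sv, cw_sv, total_sv
#' @export
section_transport <- function(fields, section,
                              criteria = water_mass_criteria(),
                              inflow_only = FALSE) {
  stopifnot(inherits(fields, "ocean_fields"),
            inherits(section, "section_definition"))
  rng_lon <- range(fields$lon); rng_lat <- range(fields$lat)
  if (section$lon_a < rng_lon[1] || section$lon_a > rng_lon[2] ||
      section$lon_b < rng_lon[1] || section$lon_b > rng_lon[2] ||
      section$lat_a < rng_lat[1] || section$lat_a > rng_lat[2] ||
      section$lat_b < rng_lat[1] || section$lat_b > rng_lat[2]) {
    stop("section exits the model domain")
  }
  mid_lat <- (section$lat_a + section$lat_b) / 2
  dx_km <- (section$lon_b - section$lon_a) * km_per_deg_lon(mid_lat)
  dy_km <- (section$lat_b - section$lat_a) * KM_PER_DEG_LAT
  len_km <- sqrt(dx_km^2 + dy_km^2)
  # sample spacing ~ native grid
  native_km <- min(diff(fields$lat)) * KM_PER_DEG_LAT
  npt <- max(ceiling(len_km / native_km), 8)
  tfrac <- (seq_len(npt) - 0.5) / npt
  ds_m <- len_km * 1000 / npt
  plon <- section$lon_a + tfrac * (section$lon_b - section$lon_a)
  plat <- section$lat_a + tfrac * (section$lat_b - section$lat_a)
  # unit normal (left of A->B)
  tx <- dx_km / len_km; ty <- dy_km / len_km
  nx_ <- -ty; ny_ <- tx
  if (section$flip_normal) { nx_ <- -nx_; ny_ <- -ny_ }

  wet <- !on_land(fields, plon, plat)
  if (!any(wet)) stop("section lies entirely on land")

  depth <- fields$depth
  keep_z <- depth <= section$max_depth
  zc <- depth[keep_z]
  # layer thicknesses: midpoints between levels, half-cells at the ends
  edges <- c(depth[1], (depth[-1] + depth[-length(depth)]) / 2,
             depth[length(depth)])
  thick <- diff(edges)[keep_z]

  nt <- length(fields$time)
  aw <- cw <- tot <- numeric(nt)
  P <- expand.grid(p = seq_len(npt), z = seq_along(zc))
  lon_s <- plon[P$p]; lat_s <- plat[P$p]; z_s <- zc[P$z]
  w_s <- (ds_m * thick[P$z]) * wet[P$p]
  for (it in seq_len(nt)) {
    us <- interp3(fields$u[, , , it], fields$lon, fields$lat, depth,
                  lon_s, lat_s, z_s)
    vs <- interp3(fields$v[, , , it], fields$lon, fields$lat, depth,
                  lon_s, lat_s, z_s)
    ts <- interp3(fields$temp[, , , it], fields$lon, fields$lat, depth,
                  lon_s, lat_s, z_s)
    ss <- interp3(fields$salt[, , , it], fields$lon, fields$lat, depth,
                  lon_s, lat_s, z_s)
    vn <- us * nx_ + vs * ny_
    if (inflow_only) vn <- pmax(vn, 0)
    flux <- vn * w_s
    lab <- classify_water_mass(ts, ss, lat_s, criteria)
    aw[it] <- sum(flux[lab == "AW"]) / 1e6
    cw[it] <- sum(flux[lab == "CW"]) / 1e6
    tot[it] <- sum(flux) / 1e6
  }
  out <- data.frame(date = fields$time, aw_sv = aw, cw_sv = cw,
                    total_sv = tot)
  class(out) <- c("section_transport", "data.frame")
  out
}

#' Mean transport over selected months
#'
#' Arithmetic mean of the daily transport values falling in the given
#' months, reported per year and across all years. Months 6-7 give the
#' June-July (chick-rearing season) inflow; the summer inflow of the
#' default scenario is weaker than the annual mean.
#'
#' @param transport a `section_transport` data.frame
#' @param months integer months to average over (1-12)
#' @return list with `per_year` (data.frame: year, aw_sv, cw_sv, total_sv)
#'   and `overall` (named numeric)
#' @export
period_mean <- function(transport, months = c(6, 7)) {
  if (length(months) == 0) stop("empty month selection")
  stopifnot(all(months %in% 1:12))
  mo <- as.integer(format(transport$date, "%m"))
  keep <- mo %in% months
  if (!any(keep)) stop("transport series does not cover the requested months")
  tr <- transport[keep, ]
  yr <- as.integer(format(tr$date, "%Y"))
  per_year <- aggregate(tr[, c("aw_sv", "cw_sv", "total_sv")],
                        by = list(year = yr), FUN = mean)
  overall <- colMeans(tr[, c("aw_sv", "cw_sv", "total_sv")])
  list(per_year = per_year, overall = overall)
}
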