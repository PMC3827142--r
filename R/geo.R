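# Local-metric geographic helpers. The whole package works on a regular
# lon/lat grid with metric conversion via cos(lat) scaling; distances are
# short enough (< a few hundred km) that the equirectangular approximation
# is well inside the other model errors.

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Kilometres per degree of longitude at a given latitude
#' @param lat latitude, degrees north
#' @return numeric, km per degree east
#' @keywords internal
km_per_deg_lon <- function(lat) KM_PER_DEG_LON_EQ * cos(lat * pi / 180)

#' Convert lon/lat to local km offsets about a reference point
#'
#' Equirectangular projection about `(ref_lon, ref_lat)`: x is eastward km,
#' y northward km. Used for box membership, section geometry and the
#' synthetic coastline; adequate for the sub-degree scales involved.
#'
#' @param lon,lat coordinates (degrees)
#' @param ref_lon,ref_lat reference point (degrees)
#' @return list with numeric vectors `x`, `y` (km)
#' @export
lonlat_to_km <- function(lon, lat, ref_lon, ref_lat) {
  list(
    x = (lon - ref_lon) * km_per_deg_lon(ref_lat),
    y = (lat - ref_lat) * KM_PER_DEG_LAT
  )
}

#' Default smoothed coastline polyline for the Norwegian coast analogue
#'
#' Vertices (lon, lat) of a smoothed south-west to north-east coastline from
#' Moere to the Varanger area. Land lies on the right-hand side walking along
#' the polyline; the ocean (and both jets) on the left. This is a deliberate
#' idealisation: fjords and the Lofoten archipelago are smoothed away.
#'
#' @return matrix with columns `lon`, `lat`
#' @export
coastline_default <- function() {
  m <- rbind(
    c(5.5, 62.0),
    c(10.0, 64.2),
    c(12.5, 66.3),
    c(13.2, 67.8),
    c(15.0, 68.7),
    c(17.5, 69.5),
    c(21.0, 70.1),
    c(26.0, 70.6),
    c(31.5, 70.2),
    c(36.0, 70.2)
  )
  colnames(m) <- c("lon", "lat")
  m
}

#' Project points onto a coastline polyline
#'
#' For each point returns the along-coast arc coordinate `s` (km from the
#' first vertex) and the signed cross-shore distance `d` (km; positive on
#' the ocean side, i.e. left of the walking direction, negative over land).
#' The nearest segment (smallest unsigned distance) wins.
#'
#' @param lon,lat point coordinates (degrees), any length
#' @param coast coastline vertex matrix as from [coastline_default()]
#' @return list of numeric vectors `s`, `d` (km)
#' @export
coast_project <- function(lon, lat, coast = coastline_default()) {
  stopifnot(nrow(coast) >= 2, length(lon) == length(lat))
  n <- length(lon)
  best_d2 <- rep(Inf, n)
  s_out <- numeric(n)
  d_out <- numeric(n)
  s0 <- 0
  for (i in seq_len(nrow(coast) - 1L)) {
    a <- coast[i, ]
    b <- coast[i + 1L, ]
    mlat <- (a[2] + b[2]) / 2
    kx <- km_per_deg_lon(mlat)
    ax <- 0; ay <- 0
    bx <- (b[1] - a[1]) * kx
    by <- (b[2] - a[2]) * KM_PER_DEG_LAT
    px <- (lon - a[1]) * kx
    py <- (lat - a[2]) * KM_PER_DEG_LAT
    seg_len <- sqrt(bx^2 + by^2)
    tx <- bx / seg_len; ty <- by / seg_len
    t_along <- pmin(pmax(px * tx + py * ty, 0), seg_len)
    # signed distance: positive to the left of the tangent (ocean side)
    d_signed <- tx * py - ty * px
    dx <- px - t_along * tx
    dy <- py - t_along * ty
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    s_out[upd] <- s0 + t_along[upd]
    d_out[upd] <- d_signed[upd]
    s0 <- s0 + seg_len
  }
  list(s = s_out, d = d_out)
}

#' Total arc length of a coastline polyline (km)
#' @param coast coastline vertex matrix
#' @return numeric scalar, km
#' @export
coast_length <- function(coast = coastline_default()) {
  tot <- 0
  for (i in seq_len(nrow(coast) - 1L)) {
    a <- coast[i, ]; b <- coast[i + 1L, ]
    mlat <- (a[2] + b[2]) / 2
    tot <- tot + sqrt(((b[1] - a[1]) * km_per_deg_lon(mlat))^2 +
                        ((b[2] - a[2]) * KM_PER_DEG_LAT)^2)
  }
  tot
}

#' Invert the coast projection: (s, d) to lon/lat
#'
#' Walks the polyline to arc position `s` and steps `d` km to the left
#' (ocean side) of the local tangent. Used to place synthetic sections and
#' release sites in coast-following coordinates.
#'
#' @param s along-coast km; `d` cross-shore km (positive offshore)
#' @param d cross-shore km
#' @param coast coastline vertex matrix
#' @return list with `lon`, `lat`
#' @export
coast_unproject <- function(s, d, coast = coastline_default()) {
  stopifnot(length(s) == length(d))
  n <- length(s)
  lon_out <- numeric(n); lat_out <- numeric(n)
  # cumulative segment arcs
  nseg <- nrow(coast) - 1L
  seg_len <- numeric(nseg); seg_kx <- numeric(nseg)
  for (i in seq_len(nseg)) {
    a <- coast[i, ]; b <- coast[i + 1L, ]
    mlat <- (a[2] + b[2]) / 2
    seg_kx[i] <- km_per_deg_lon(mlat)
    seg_len[i] <- sqrt(((b[1] - a[1]) * seg_kx[i])^2 +
                         ((b[2] - a[2]) * KM_PER_DEG_LAT)^2)
  }
  cum0 <- c(0, cumsum(seg_len))
  for (j in seq_len(n)) {
    sj <- min(max(s[j], 0), cum0[nseg + 1L])
    i <- max(1L, min(nseg, findInterval(sj, cum0, rightmost.closed = TRUE)))
    a <- coast[i, ]; b <- coast[i + 1L, ]
    tx <- (b[1] - a[1]) * seg_kx[i] / seg_len[i]
    ty <- (b[2] - a[2]) * KM_PER_DEG_LAT / seg_len[i]
    t_along <- sj - cum0[i]
    # left normal of (tx, ty) is (-ty, tx)
    x_km <- t_along * tx - d[j] * ty
    y_km <- t_along * ty + d[j] * tx
    lon_out[j] <- a[1] + x_km / seg_kx[i]
    lat_out[j] <- a[2] + y_km / KM_PER_DEG_LAT
  }
  list(lon = lon_out, lat = lat_out)
}
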