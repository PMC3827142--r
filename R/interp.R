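# Vectorised field interpolation on the regular (lon, lat, depth) grid.
# Bilinear in the horizontal, linear in the vertical, nearest in time
# (callers extract the daily slab before interpolating).

# Locate x on a strictly increasing axis; returns integer lower index
# (clamped to [1, n-1]) and fractional position in [0, 1].
axis_locate <- function(ax, x) {
  n <- length(ax)
  i <- findInterval(x, ax, all.inside = TRUE)
  f <- (x - ax[i]) / (ax[i + 1L] - ax[i])
  list(i = i, f = pmin(pmax(f, 0), 1))
}

# Trilinear interpolation of a 3-D array arr[lon, lat, depth] at scattered
# points. Coordinates outside the grid are clamped to the boundary.
interp3 <- function(arr, lon_ax, lat_ax, z_ax, lon, lat, z) {
  li <- axis_locate(lon_ax, lon)
  lj <- axis_locate(lat_ax, lat)
  lk <- axis_locate(z_ax, z)
  nx <- length(lon_ax); ny <- length(lat_ax)
  v <- as.vector(arr)
  idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  i0 <- li$i; j0 <- lj$i; k0 <- lk$i
  fx <- li$f; fy <- lj$f; fz <- lk$f
  c000 <- v[idx(i0, j0, k0)]
  c100 <- v[idx(i0 + 1L, j0, k0)]
  c010 <- v[idx(i0, j0 + 1L, k0)]
  c110 <- v[idx(i0 + 1L, j0 + 1L, k0)]
  c001 <- v[idx(i0, j0, k0 + 1L)]
  c101 <- v[idx(i0 + 1L, j0, k0 + 1L)]
  c011 <- v[idx(i0, j0 + 1L, k0 + 1L)]
  c111 <- v[idx(i0 + 1L, j0 + 1L, k0 + 1L)]
  b0 <- (c000 * (1 - fx) + c100 * fx) * (1 - fy) +
    (c010 * (1 - fx) + c110 * fx) * fy
  b1 <- (c001 * (1 - fx) + c101 * fx) * (1 - fy) +
    (c011 * (1 - fx) + c111 * fx) * fy
  b0 * (1 - fz) + b1 * fz
}

# Bilinear interpolation of a 2-D array arr[lon, lat] at scattered points.
interp2 <- function(arr, lon_ax, lat_ax, lon, lat) {
  li <- axis_locate(lon_ax, lon)
  lj <- axis_locate(lat_ax, lat)
  nx <- length(lon_ax)
  v <- as.vector(arr)
  idx <- function(i, j) i + (j - 1L) * nx
  i0 <- li$i; j0 <- lj$i; fx <- li$f; fy <- lj$f
  c00 <- v[idx(i0, j0)]
  c10 <- v[idx(i0 + 1L, j0)]
  c01 <- v[idx(i0, j0 + 1L)]
  c11 <- v[idx(i0 + 1L, j0 + 1L)]
  (c00 * (1 - fx) + c10 * fx) * (1 - fy) + (c01 * (1 - fx) + c11 * fx) * fy
}

# TRUE where the nearest grid cell is land (or the point is off-grid).
on_land <- function(fields, lon, lat) {
  i <- pmin(pmax(round(approx(fields$lon, seq_along(fields$lon),
                              xout = lon, rule = 2)$y), 1L),
            length(fields$lon))
  j <- pmin(pmax(round(approx(fields$lat, seq_along(fields$lat),
                              xout = lat, rule = 2)$y), 1L),
            length(fields$lat))
  fields$land_mask[cbind(i, j)]
}

# TRUE where the point is outside the horizontal grid bounds.
off_domain <- function(fields, lon, lat) {
  lon < fields$lon[1] | lon > fields$lon[length(fields$lon)] |
    lat < fields$lat[1] | lat > fields$lat[length(fields$lat)]
}

# Index of the daily slab nearest to `date` on the field time axis.
time_index <- function(fields, date) {
  it <- findInterval(as.numeric(date), as.numeric(fields$time),
                     all.inside = FALSE)
  pmin(pmax(it, 1L), length(fields$time))
}
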